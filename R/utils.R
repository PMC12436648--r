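#' @keywords internal
"_PACKAGE"

## Internal validation helpers. Errors are classed "smtrack_validation_error"
## so callers (and the pipeline runner) can distinguish bad inputs from bugs.

stop_validation <- function(...) {
  msg <- paste0(...)
  cond <- structure(
    class = c("smtrack_validation_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
  stop(cond)
}

assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1) {
    stop_validation(name, " must be a single probability in [0, 1]")
  }
  invisible(x)
}

assert_pos <- function(x, name, strict = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    (if (strict) x > 0 else x >= 0)
  if (!ok) {
    stop_validation(name, if (strict) " must be a positive number"
                    else " must be a non-negative number")
  }
  invisible(x)
}

assert_count <- function(x, name, min = 0L) {
  ok <- is.numeric(x) && length(x) == 1L && !is.na(x) &&
    x >= min && x == floor(x)
  if (!ok) stop_validation(name, " must be an integer >= ", min)
  invisible(as.integer(x))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Robust standard deviation (MAD, normal-consistent)
#'
#' Median absolute deviation scaled to estimate the standard deviation of
#' Gaussian noise; used to set detection thresholds on filtered images.
#'
#' @param x numeric vector or array.
#' @return scalar robust SD estimate.
#' @export
robust_sd <- function(x) stats::mad(as.numeric(x), constant = 1.4826)

## Deterministic 32-bit FNV-1a hash of an R object (serialized); used to
## stamp pipeline outputs with a config fingerprint without extra deps.
config_hash <- function(x) {
  raw <- serialize(x, NULL, version = 2L)
  h <- 2166136261
  p <- 16777619
  for (b in as.integer(raw)) {
    ## xor into the low byte (h kept as a double in [0, 2^32))
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), b)
    ## multiply by the FNV prime mod 2^32 without exceeding 2^53
    h1 <- h %/% 65536
    h0 <- h %% 65536
    h <- (((h1 * p) %% 65536) * 65536 + h0 * p) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

## Derive a stream-specific seed below 2^31 from a base seed.
derive_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(stream)) %%
               2147483647)
}

## Consecutive-run helper: lengths/starts of TRUE runs in a logical vector.
true_runs <- function(x) {
  r <- rle(as.logical(x))
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & !is.na(r$values)
  data.frame(start = starts[keep], end = ends[keep], length = r$lengths[keep])
}

max_true_run <- function(x) {
  runs <- true_runs(x)
  if (nrow(runs) == 0L) 0L else max(runs$length)
}
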