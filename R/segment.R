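## Change-point segmentation of intensity traces, bound-state extraction,
## residence-time estimators and stoichiometry normalization.

## Max standardized mean-difference statistic over all admissible splits
## of x[l..r] (vectorized via cumulative sums), using a trace-global
## noise SD. Returns list(k, t, m): split after index k (local).
max_split_t <- function(x, min_seg, sigma) {
  n <- length(x)
  ks <- seq.int(min_seg, n - min_seg)
  if (n < 2L * min_seg || length(ks) == 0L) {
    return(list(k = NA, t = -Inf, m = 0L))
  }
  cs <- cumsum(x)
  n1 <- ks
  n2 <- n - ks
  dm <- abs(cs[ks] / n1 - (cs[n] - cs[ks]) / n2)
  if (sigma > 0) {
    tt <- dm / (sigma * sqrt(1 / n1 + 1 / n2))
    i <- which.max(tt)
  } else {
    ## noiseless: any exact mean difference is significant; place the
    ## boundary at the largest mean difference
    tt <- ifelse(dm > 1e-12, Inf, 0)
    i <- which.max(dm)
  }
  list(k = ks[i], t = tt[i], m = length(ks), dm = dm[i])
}

#' Detect change points in an intensity trace
#'
#' Recursive binary segmentation with a two-sample t-type statistic: at
#' each recursion the segment is split at the position maximizing the
#' standardized mean difference between the two sides, whenever that
#' statistic exceeds the Bonferroni-corrected normal critical value at
#' level `alpha` (corrected for the number of candidate splits in the
#' segment). The noise SD is estimated once per trace from the median
#' absolute first difference, which is insensitive to the steps
#' themselves — the usual choice in intensity step detection, and the
#' reason pulse trains do not inflate the variance estimate. For
#' noiseless traces any exact mean difference splits. Deterministic
#' given the input.
#'
#' @param trace numeric intensity series (uniform sampling).
#' @param alpha per-split significance level for accepting a change point.
#' @param min_seg_frames minimum segment length in frames (1 allows
#'   single-frame events to be isolated).
#' @param refine_pulses after the binary pass, scan each flat segment
#'   for short significant excursions (a two-boundary interval test,
#'   Bonferroni-corrected over all tested intervals). Binary splitting
#'   alone cannot isolate a brief pulse inside a long flat stretch —
#'   both half-means are diluted — so this pass is what recovers
#'   dwells of one or two frames.
#' @return integer vector of change-point positions: a boundary at `k`
#'   means frames `...k` and `k+1...` belong to different segments. A
#'   trace shorter than `2 * min_seg_frames` returns no boundaries with
#'   attribute `too_short = TRUE`.
#' @export
detect_change_points <- function(trace, alpha = 0.01, min_seg_frames = 1L,
                                 refine_pulses = TRUE) {
  if (!is.numeric(trace) || anyNA(trace) || any(!is.finite(trace))) {
    stop_validation("trace must be finite numeric")
  }
  assert_prob(alpha, "alpha")
  if (alpha <= 0) stop_validation("alpha must be > 0")
  min_seg_frames <- assert_count(min_seg_frames, "min_seg_frames", min = 1L)
  n <- length(trace)
  if (n < 2L * min_seg_frames || n < 2L) {
    return(structure(integer(0), too_short = TRUE))
  }
  ## step-robust noise estimate from first differences
  sigma <- stats::mad(diff(trace), constant = 1.4826) / sqrt(2)
  ## the binary pass and the pulse pass each get half the budget; t
  ## quantiles absorb the uncertainty of the estimated noise SD
  a2 <- alpha / (if (refine_pulses) 2 else 1)
  bounds <- integer(0)
  recurse <- function(l, r) {
    res <- max_split_t(trace[l:r], min_seg_frames, sigma)
    if (is.na(res$k)) return(invisible(NULL))
    crit <- stats::qt(1 - a2 / (2 * res$m), max(n - 2L, 1L))
    if (res$t >= crit) {
      k <- l + res$k - 1L
      bounds <<- c(bounds, k)
      recurse(l, k)
      recurse(k + 1L, r)
    }
    invisible(NULL)
  }
  recurse(1L, n)
  if (refine_pulses) {
    repeat {
      segs <- cbind(c(1L, sort(bounds) + 1L), c(sort(bounds), n))
      added <- FALSE
      for (s in seq_len(nrow(segs))) {
        p <- best_pulse(trace[segs[s, 1L]:segs[s, 2L]], sigma,
                        min_seg_frames)
        if (is.null(p)) next
        crit <- stats::qt(1 - a2 / (2 * p$m), max(n - 2L, 1L))
        if (p$z >= crit) {
          off <- segs[s, 1L] - 1L
          newb <- c(off + p$i - 1L, off + p$j)
          newb <- newb[newb >= 1L & newb < n]
          newb <- setdiff(newb, bounds)
          if (length(newb)) {
            bounds <- c(bounds, newb)
            added <- TRUE
          }
        }
      }
      if (!added) break
    }
  }
  sort(unique(bounds))
}

## Best sub-interval [i..j] of x whose mean deviates most (in z units)
## from the mean of the remaining frames. Vectorized over all O(n^2)
## intervals; returns NULL when no interval is admissible.
best_pulse <- function(x, sigma, min_seg) {
  n <- length(x)
  if (n < min_seg + 1L) return(NULL)
  cs <- c(0, cumsum(x))
  tot <- cs[n + 1L]
  ## interval sums S[i, j] = cs[j+1] - cs[i]; build via outer
  i <- rep(seq_len(n), times = n)
  j <- rep(seq_len(n), each = n)
  keep <- j >= i & !(i == 1L & j == n) & (j - i + 1L) >= min_seg
  i <- i[keep]
  j <- j[keep]
  m <- j - i + 1L
  keep2 <- (n - m) >= min_seg
  i <- i[keep2]; j <- j[keep2]; m <- m[keep2]
  if (length(i) == 0L) return(NULL)
  s <- cs[j + 1L] - cs[i]
  dm <- abs(s / m - (tot - s) / (n - m))
  if (sigma > 0) {
    z <- dm / (sigma * sqrt(1 / m + 1 / (n - m)))
    b <- which.max(z)
  } else {
    z <- ifelse(dm > 1e-12, Inf, 0)
    b <- which.max(dm)
  }
  list(i = i[b], j = j[b], z = z[b], m = length(i))
}

#' Extract bound-state segments from a segmented trace
#'
#' Contiguous segments whose mean intensity is at or above
#' `level_threshold` are merged and reported as bound states; bound
#' states shorter than `min_bound_s` are dropped (the paper's
#' eight-second rule at 2-s frames keeps states of four frames or more).
#' Segments touching either end of the trace are flagged censored.
#'
#' @param trace numeric intensity series.
#' @param boundaries change points from [detect_change_points()].
#' @param dt_s frame interval (s).
#' @param level_threshold intensity (units of one binder) separating
#'   bound from unbound levels.
#' @param min_bound_s minimum bound-state duration in seconds (8 s
#'   default). Use 0 to keep all bound segments.
#' @param t0 time of the first frame (s).
#' @return data.frame of bound segments: `t_start`, `t_end`,
#'   `duration_s`, `n_frames`, `mean_level`, `censored_start`,
#'   `censored_end`.
#' @export
segment_bound_states <- function(trace, boundaries, dt_s,
                                 level_threshold = 0.5, min_bound_s = 8,
                                 t0 = 0) {
  assert_pos(dt_s, "dt_s")
  n <- length(trace)
  starts <- c(1L, boundaries + 1L)
  ends <- c(boundaries, n)
  means <- mapply(function(a, b) mean(trace[a:b]), starts, ends)
  bound <- means >= level_threshold
  ## merge adjacent bound segments
  runs <- true_runs(bound)
  if (nrow(runs) == 0L) {
    return(data.frame(t_start = numeric(0), t_end = numeric(0),
                      duration_s = numeric(0), n_frames = integer(0),
                      mean_level = numeric(0), censored_start = logical(0),
                      censored_end = logical(0)))
  }
  f0 <- starts[runs$start]
  f1 <- ends[runs$end]
  nfr <- f1 - f0 + 1L
  out <- data.frame(
    t_start = t0 + (f0 - 1L) * dt_s,
    t_end = t0 + (f0 - 1L) * dt_s + nfr * dt_s,
    duration_s = nfr * dt_s,
    n_frames = nfr,
    mean_level = mapply(function(a, b) mean(trace[a:b]), f0, f1),
    censored_start = f0 == 1L,
    censored_end = f1 == n
  )
  out[out$duration_s >= min_bound_s, , drop = FALSE]
}

## Convenience: segment one trace end to end.
segment_trace <- function(trace, dt_s, alpha = 0.01, min_seg_frames = 1L,
                          level_threshold = 0.5, min_bound_s = 8, t0 = 0) {
  b <- detect_change_points(trace, alpha, min_seg_frames)
  segment_bound_states(trace, b, dt_s, level_threshold, min_bound_s, t0)
}

#' Segment every protein trace of a binding cohort
#'
#' Runs change-point detection and bound-state extraction on each mRNA's
#' protein trace and pools the segments, carrying the bookkeeping needed
#' by the cohort-level residence-time estimators.
#'
#' @param cohort a `binding_cohort`.
#' @param alpha change-point significance level.
#' @param min_bound_s minimum bound duration (s); 0 keeps everything.
#' @param level_threshold bound/unbound intensity threshold.
#' @return list with `segments` (pooled data.frame with an `mrna`
#'   column), `total_frames`, `n_traces`, `dt_s`.
#' @export
segment_binding_cohort <- function(cohort, alpha = 0.01, min_bound_s = 8,
                                   level_threshold = 0.5) {
  n <- ncol(cohort$protein)
  nf <- nrow(cohort$protein)
  segs <- vector("list", n)
  for (i in seq_len(n)) {
    s <- segment_trace(cohort$protein[, i], cohort$dt_s, alpha = alpha,
                       level_threshold = level_threshold,
                       min_bound_s = min_bound_s)
    if (nrow(s)) s$mrna <- i
    segs[[i]] <- s
  }
  segs <- segs[vapply(segs, nrow, 1L) > 0]
  segments <- if (length(segs)) do.call(rbind, segs) else
    segment_bound_states(numeric(2), integer(0), cohort$dt_s,
                         min_bound_s = Inf)
  rownames(segments) <- NULL
  list(segments = segments, total_frames = n * nf, n_traces = n,
       dt_s = cohort$dt_s)
}

#' Residence-time statistics over a cohort of bound segments
#'
#' Summarizes bound-state ("on") durations. Four policies are available,
#' differing in how they treat the finite frame interval and censoring:
#'
#' * `"mean"` — arithmetic mean of uncensored durations. Simple, but
#'   biased for on-times comparable to the frame interval, because
#'   sub-frame episodes are missed and durations are quantized.
#' * `"exp_mle"` — maximum-likelihood mean of an exponential on-time
#'   observed through frame sampling: the number of consecutive bound
#'   frames per episode is geometric with ratio `q = exp(-dt/tau)`, so
#'   `tau = -dt / log(1 - 1/nbar)` with `nbar` the mean frames per
#'   segment. Corrects the frame-sampling bias.
#' * `"markov"` — inverts the frame-sampled two-state Markov chain:
#'   transition counts between bound/unbound frames give the sampled
#'   transition matrix, whose matrix logarithm yields the underlying
#'   off-rate. Additionally corrects for unbinding-and-rebinding within
#'   one frame interval (which merges adjacent episodes in the sampled
#'   trace). Requires `total_frames` and `n_traces`.
#' * `"exp_censored"` — right-censoring-aware exponential MLE: total
#'   observed time (above `min_duration_s`) divided by the number of
#'   uncensored segments, plus `min_duration_s`. Appropriate for long
#'   dwells truncated by the observation window.
#'
#' @param segments data.frame from [segment_bound_states()] (pooled).
#' @param dt_s frame interval (s).
#' @param policy estimator choice (see Details).
#' @param total_frames total frames across all traces (markov policy).
#' @param n_traces number of traces (markov policy).
#' @param min_duration_s known lower bound of episode durations
#'   (exp_censored policy); 0 for none.
#' @return list with `mean_s`, `n` (segments used), `n_censored`,
#'   `policy`, `cdf` (ecdf of uncensored durations, or NULL), and
#'   `defined` (FALSE when all input segments are censored).
#' @export
residence_time_stats <- function(segments, dt_s,
                                 policy = c("mean", "exp_mle", "markov",
                                            "exp_censored"),
                                 total_frames = NULL, n_traces = NULL,
                                 min_duration_s = 0) {
  policy <- match.arg(policy)
  assert_pos(dt_s, "dt_s")
  cens <- segments$censored_start | segments$censored_end
  unc <- segments[!cens, , drop = FALSE]
  out <- list(policy = policy, n = nrow(unc), n_censored = sum(cens),
              cdf = if (nrow(unc)) stats::ecdf(unc$duration_s) else NULL)
  if (policy %in% c("mean", "exp_mle") && nrow(unc) == 0L) {
    out$mean_s <- NA_real_
    out$defined <- FALSE
    return(out)
  }
  out$defined <- TRUE
  if (policy == "mean") {
    out$mean_s <- mean(unc$duration_s)
  } else if (policy == "exp_mle") {
    nbar <- mean(unc$n_frames)
    if (nbar <= 1) {
      out$mean_s <- NA_real_
      out$defined <- FALSE
    } else {
      out$mean_s <- -dt_s / log(1 - 1 / nbar)
    }
  } else if (policy == "markov") {
    if (is.null(total_frames) || is.null(n_traces)) {
      stop_validation("markov policy needs total_frames and n_traces")
    }
    R <- nrow(segments)
    n_on <- sum(segments$n_frames)
    n_oo <- n_on - R
    n_of <- R - sum(segments$censored_end)
    n_fo <- R - sum(segments$censored_start)
    off_transitions <- (total_frames - n_traces) - (n_oo + n_of)
    n_ff <- off_transitions - n_fo
    if (n_oo + n_of == 0L || n_ff + n_fo == 0L) {
      out$mean_s <- NA_real_
      out$defined <- FALSE
      return(out)
    }
    p_oo <- n_oo / (n_oo + n_of)
    p_ff <- n_ff / (n_ff + n_fo)
    lam <- p_oo + p_ff - 1
    if (lam <= 0 || lam >= 1) {
      out$mean_s <- NA_real_
      out$defined <- FALSE
      return(out)
    }
    s <- -log(lam) / dt_s
    koff <- s * (1 - p_oo) / ((1 - p_oo) + (1 - p_ff))
    out$mean_s <- 1 / koff
  } else { # exp_censored
    end_cens <- segments$censored_end
    n_events <- sum(!end_cens)
    if (n_events == 0L) {
      out$mean_s <- NA_real_
      out$defined <- FALSE
      return(out)
    }
    excess <- pmax(segments$duration_s - min_duration_s, 0)
    out$mean_s <- min_duration_s + sum(excess) / n_events
    out$n <- n_events
    out$n_censored <- sum(end_cens)
  }
  out
}

#' Normalize integrated intensities to single-binder units
#'
#' Divides integrated spot intensities by the mean bound-state intensity
#' of the single-site calibration construct, turning intensities into
#' binder counts (stoichiometries).
#'
#' @param samples numeric integrated intensities.
#' @param calibration_mean mean single-binder intensity (> 0).
#' @return numeric vector of normalized stoichiometries.
#' @export
normalize_stoichiometry <- function(samples, calibration_mean) {
  if (!is.numeric(calibration_mean) || length(calibration_mean) != 1L ||
      is.na(calibration_mean) || calibration_mean <= 0) {
    stop_validation("calibration_mean must be a single positive number")
  }
  samples / calibration_mean
}

#' Compare two samples by KS or pooled-variance t test
#'
#' @param a,b numeric samples.
#' @param test `"ks"` for the exact two-sample Kolmogorov-Smirnov test
#'   (statistic `D = sup |F_a - F_b|`), or `"t_equal_var"` for the
#'   two-tailed pooled-variance t test.
#' @return list with `statistic` and `p_value`.
#' @export
compare_distributions <- function(a, b, test = c("ks", "t_equal_var")) {
  test <- match.arg(test)
  if (test == "ks") {
    h <- suppressWarnings(stats::ks.test(a, b))
    list(statistic = unname(h$statistic), p_value = h$p.value)
  } else {
    h <- stats::t.test(a, b, var.equal = TRUE)
    list(statistic = unname(h$statistic), p_value = h$p.value)
  }
}
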