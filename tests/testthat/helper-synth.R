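## Shared fixtures for the test suite; everything is generated in code.

## A small noiseless image with one pixel-integrated Gaussian spot.
spot_image <- function(x0, y0, intensity = 1000, sigma = 1.3,
                       size = 32, background = 5) {
  img <- matrix(background, size, size)
  smtrack:::add_spot_2d(img, x0, y0, intensity, sigma)
}

## A square trace with given on-intervals (frame index ranges, 1-based).
pulse_trace <- function(n, on_ranges, amplitude = 1, noise_sd = 0,
                        seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  x <- numeric(n)
  for (r in on_ranges) x[r[1]:r[2]] <- amplitude
  if (noise_sd > 0) x <- x + rnorm(n, 0, noise_sd)
  x
}

## Minimal track table builder: one row per frame.
make_track <- function(id, channel, frames, x, y, cell = 1L,
                       intensity = 1, t_s = frames * 2) {
  data.frame(track_id = id, channel = channel, cell = cell,
             frame = frames, t_s = t_s,
             x = rep_len(x, length(frames)),
             y = rep_len(y, length(frames)),
             intensity = rep_len(intensity, length(frames)),
             status = "kept", reason = "none")
}

## Exhaustive least-squares segmentation with exactly two change points:
## minimizes the residual sum of squares over all split pairs (i < j),
## fitting a constant per segment. Independent oracle for the
## change-point detector.
ls_two_changepoints <- function(x) {
  n <- length(x)
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  sse <- function(a, b) {
    s <- cs[b + 1] - cs[a]
    q <- cs2[b + 1] - cs2[a]
    q - s^2 / (b - a + 1)
  }
  best <- c(NA, NA)
  best_sse <- Inf
  for (i in 1:(n - 2)) {
    for (j in (i + 1):(n - 1)) {
      v <- sse(1, i) + sse(i + 1, j) + sse(j + 1, n)
      if (v < best_sse) {
        best_sse <- v
        best <- c(i, j)
      }
    }
  }
  best
}

## Brute-force minimal-cost perfect matching over all permutations.
brute_force_assignment <- function(cost) {
  n <- nrow(cost)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    do.call(c, lapply(seq_along(v), function(i) {
      lapply(perms(v[-i]), function(p) c(v[i], p))
    }))
  }
  best <- Inf
  for (p in perms(seq_len(n))) {
    best <- min(best, sum(cost[cbind(seq_len(n), p)]))
  }
  best
}
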