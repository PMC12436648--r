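## Spot detection: Laplacian-of-Gaussian band-pass, candidate picking and
## sub-pixel Gaussian fitting with integrated intensities.
##
## Coordinate convention: 0-based, pixel-center. A matrix element
## [r, c] is the pixel at (x, y) = (c - 1, r - 1).

#' Detection parameters
#'
#' @param log_sigma_px scale of the Laplacian-of-Gaussian band-pass (px),
#'   matched to the PSF sigma.
#' @param min_amplitude detection threshold on the filtered image; when
#'   `NULL` it is set per frame to `thresh_k` robust noise SDs of the
#'   filtered image.
#' @param thresh_k threshold in robust-SD units when `min_amplitude` is
#'   NULL (default 5, controlling false positives over a full frame).
#' @param fit_window_px half-width of the fitting window (window is
#'   `2 * fit_window_px + 1` pixels); must be >= `2 * log_sigma_px`.
#' @param dims 2 for time-lapse frames, 3 for z-stacks.
#' @param log_sigma_z_px axial band-pass scale for 3D.
#' @return list of class `detection_params`.
#' @export
detection_params <- function(log_sigma_px = 1.3, min_amplitude = NULL,
                             thresh_k = 5, fit_window_px = 4L, dims = 2L,
                             log_sigma_z_px = 1.2) {
  assert_pos(log_sigma_px, "log_sigma_px")
  if (!is.null(min_amplitude)) assert_pos(min_amplitude, "min_amplitude")
  assert_pos(thresh_k, "thresh_k")
  fit_window_px <- assert_count(fit_window_px, "fit_window_px", min = 1L)
  if (fit_window_px < 2 * log_sigma_px) {
    stop_validation("fit_window_px must be >= 2 * log_sigma_px")
  }
  dims <- assert_count(dims, "dims", min = 2L)
  if (dims > 3L) stop_validation("dims must be 2 or 3")
  structure(list(log_sigma_px = log_sigma_px, min_amplitude = min_amplitude,
                 thresh_k = thresh_k, fit_window_px = fit_window_px,
                 dims = dims, log_sigma_z_px = log_sigma_z_px),
            class = "detection_params")
}

## 1D Gaussian kernel, radius 4 sigma, normalized.
gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

## Filter the columns of a matrix with a symmetric kernel, replicating
## edges.
filter_cols <- function(m, k) {
  r <- (length(k) - 1L) %/% 2L
  n <- nrow(m)
  padded <- rbind(m[rep(1L, r), , drop = FALSE], m,
                  m[rep(n, r), , drop = FALSE])
  f <- stats::filter(padded, k, sides = 2L)
  matrix(f[(r + 1L):(r + n), ], nrow = n)
}

gauss_smooth_2d <- function(m, sigma) {
  k <- gauss_kernel(sigma)
  t(filter_cols(t(filter_cols(m, k)), k))
}

gauss_smooth_3d <- function(a, sigma_xy, sigma_z) {
  d <- dim(a)
  out <- a
  for (z in seq_len(d[3L])) out[, , z] <- gauss_smooth_2d(a[, , z], sigma_xy)
  ## smooth along z: reshape so z runs down columns
  kz <- gauss_kernel(sigma_z)
  m <- matrix(aperm(out, c(3L, 1L, 2L)), nrow = d[3L])
  m <- filter_cols(m, kz)
  aperm(array(m, dim = c(d[3L], d[1L], d[2L])), c(2L, 3L, 1L))
}

## Negative discrete Laplacian along each array axis (replicated edges),
## so diffraction-limited spots become positive peaks.
neg_laplacian <- function(a) {
  if (is.matrix(a)) {
    n <- nrow(a); m <- ncol(a)
    up <- a[c(1L, seq_len(n - 1L)), , drop = FALSE]
    dn <- a[c(seq_len(n - 1L) + 1L, n), , drop = FALSE]
    lf <- a[, c(1L, seq_len(m - 1L)), drop = FALSE]
    rt <- a[, c(seq_len(m - 1L) + 1L, m), drop = FALSE]
    -(up + dn + lf + rt - 4 * a)
  } else {
    d <- dim(a)
    out <- array(0, d)
    for (ax in 1:3) {
      idx1 <- c(1L, seq_len(d[ax] - 1L))
      idx2 <- c(seq_len(d[ax] - 1L) + 1L, d[ax])
      sh1 <- switch(ax, a[idx1, , , drop = FALSE],
                    a[, idx1, , drop = FALSE], a[, , idx1, drop = FALSE])
      sh2 <- switch(ax, a[idx2, , , drop = FALSE],
                    a[, idx2, , drop = FALSE], a[, , idx2, drop = FALSE])
      out <- out + sh1 + sh2 - 2 * a
    }
    -out
  }
}

#' Laplacian-of-Gaussian band-pass filter
#'
#' Gaussian smoothing followed by a negative discrete Laplacian: a linear
#' band-pass that suppresses flat background and pixel noise while
#' turning diffraction-limited spots into positive peaks. Constant images
#' map to zero.
#'
#' @param image 2D matrix or 3D array of finite values.
#' @param log_sigma_px lateral filter scale (px).
#' @param log_sigma_z_px axial scale for 3D input.
#' @return filtered array of the same shape.
#' @export
bandpass_log <- function(image, log_sigma_px, log_sigma_z_px = 1.2) {
  assert_pos(log_sigma_px, "log_sigma_px")
  if (anyNA(image) || any(!is.finite(image))) {
    stop_validation("image must be finite-valued")
  }
  if (is.matrix(image)) {
    neg_laplacian(gauss_smooth_2d(image, log_sigma_px))
  } else if (length(dim(image)) == 3L) {
    neg_laplacian(gauss_smooth_3d(image, log_sigma_px, log_sigma_z_px))
  } else {
    stop_validation("image must be a 2D matrix or 3D array")
  }
}

## Logical array of strict-or-equal local maxima (8/26-neighborhood),
## requiring strict superiority over at least one neighbor side to avoid
## plateaus double-reporting (ties resolved by the separation rule).
local_maxima <- function(a) {
  if (is.matrix(a)) {
    n <- nrow(a); m <- ncol(a)
    res <- matrix(TRUE, n, m)
    for (dy in -1:1) for (dx in -1:1) {
      if (dy == 0 && dx == 0) next
      ys <- pmin(pmax(seq_len(n) + dy, 1L), n)
      xs <- pmin(pmax(seq_len(m) + dx, 1L), m)
      res <- res & (a >= a[ys, xs])
    }
    res
  } else {
    d <- dim(a)
    res <- array(TRUE, d)
    for (dy in -1:1) for (dx in -1:1) for (dz in -1:1) {
      if (dy == 0 && dx == 0 && dz == 0) next
      ys <- pmin(pmax(seq_len(d[1L]) + dy, 1L), d[1L])
      xs <- pmin(pmax(seq_len(d[2L]) + dx, 1L), d[2L])
      zs <- pmin(pmax(seq_len(d[3L]) + dz, 1L), d[3L])
      res <- res & (a >= a[ys, xs, zs])
    }
    res
  }
}

#' Find candidate spot locations in a filtered image
#'
#' Local maxima of the band-passed image above `min_amplitude`; when two
#' candidates fall within `min_sep` pixels of each other only the
#' brighter is kept.
#'
#' @param filtered output of [bandpass_log()].
#' @param min_amplitude detection threshold (> 0).
#' @param min_sep minimum separation in pixels (about one PSF radius).
#' @return data.frame of 0-based integer pixel coordinates `x`, `y`
#'   (and `z` for 3D) with the filtered `value`.
#' @export
find_candidates <- function(filtered, min_amplitude, min_sep = 2.6) {
  assert_pos(min_amplitude, "min_amplitude")
  is3d <- !is.matrix(filtered)
  lm <- local_maxima(filtered) & (filtered > min_amplitude)
  idx <- which(lm, arr.ind = TRUE)
  if (nrow(idx) == 0L) {
    out <- data.frame(x = integer(0), y = integer(0), value = numeric(0))
    if (is3d) out$z <- integer(0)
    return(out)
  }
  vals <- filtered[lm]
  ord <- order(-vals, idx[, 1L], idx[, 2L])
  idx <- idx[ord, , drop = FALSE]
  vals <- vals[ord]
  keep <- logical(length(vals))
  kept_pos <- NULL
  for (i in seq_along(vals)) {
    p <- idx[i, ]
    if (is.null(kept_pos)) {
      keep[i] <- TRUE
      kept_pos <- matrix(p, nrow = 1L)
    } else {
      d2 <- rowSums((kept_pos - matrix(p, nrow(kept_pos), length(p),
                                       byrow = TRUE))^2)
      if (all(d2 > min_sep^2)) {
        keep[i] <- TRUE
        kept_pos <- rbind(kept_pos, p)
      }
    }
  }
  idx <- idx[keep, , drop = FALSE]
  out <- data.frame(x = idx[, 2L] - 1L, y = idx[, 1L] - 1L,
                    value = vals[keep])
  if (is3d) out$z <- idx[, 3L] - 1L
  out
}

## Residuals of the pixel-integrated Gaussian model (2D).
## par = (b, V, x0, y0, sx, sy); data over a window grid.
fit_gaussian_window <- function(win, x_off, y_off, z_off = NULL,
                                start_xyz, sigma0, sigma_z0 = NULL) {
  is3d <- !is.null(z_off)
  b0 <- min(win)
  v0 <- max(sum(win - b0), 1e-6)
  if (is3d) {
    par0 <- c(b = b0, V = v0, x0 = start_xyz[1L], y0 = start_xyz[2L],
              z0 = start_xyz[3L], sx = sigma0, sy = sigma0, sz = sigma_z0)
    resid_fn <- function(p) {
      wx <- diff(stats::pnorm(c(x_off - 0.5, x_off[length(x_off)] + 0.5),
                              p[3L], p[6L]))
      wy <- diff(stats::pnorm(c(y_off - 0.5, y_off[length(y_off)] + 0.5),
                              p[4L], p[7L]))
      wz <- diff(stats::pnorm(c(z_off - 0.5, z_off[length(z_off)] + 0.5),
                              p[5L], p[8L]))
      mod <- p[1L] + p[2L] * outer(outer(wy, wx), wz)
      as.numeric(win - mod)
    }
    lower <- c(-Inf, 0, min(x_off), min(y_off), min(z_off), 0.3, 0.3, 0.3)
    upper <- c(Inf, Inf, max(x_off), max(y_off), max(z_off),
               diff(range(x_off)), diff(range(y_off)),
               max(diff(range(z_off)), 1))
  } else {
    par0 <- c(b = b0, V = v0, x0 = start_xyz[1L], y0 = start_xyz[2L],
              sx = sigma0, sy = sigma0)
    resid_fn <- function(p) {
      wx <- diff(stats::pnorm(c(x_off - 0.5, x_off[length(x_off)] + 0.5),
                              p[3L], p[5L]))
      wy <- diff(stats::pnorm(c(y_off - 0.5, y_off[length(y_off)] + 0.5),
                              p[4L], p[6L]))
      mod <- p[1L] + p[2L] * outer(wy, wx)
      as.numeric(win - mod)
    }
    lower <- c(-Inf, 0, min(x_off), min(y_off), 0.3, 0.3)
    upper <- c(Inf, Inf, max(x_off), max(y_off),
               diff(range(x_off)), diff(range(y_off)))
  }
  fit <- try(minpack.lm::nls.lm(
    par = par0, lower = lower, upper = upper, fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 200)), silent = TRUE)
  if (inherits(fit, "try-error")) return(list(ok = FALSE,
                                              reason = "fit_error"))
  if (fit$info %in% c(0L, 9L)) return(list(ok = FALSE,
                                           reason = "no_convergence"))
  p <- fit$par
  if (p[2L] <= 0) return(list(ok = FALSE, reason = "negative_amplitude"))
  list(ok = TRUE, par = p, deviance = fit$deviance)
}

#' Fit a sub-pixel Gaussian to one candidate spot
#'
#' Least-squares fit of a constant offset plus an elliptical
#' pixel-integrated Gaussian inside the fitting window around the
#' candidate. The integrated intensity is the fitted Gaussian volume
#' (equivalently `2 pi * amplitude * sigma_x * sigma_y`, times
#' `sqrt(2 pi) * sigma_z` in 3D). Windows that would cross the image
#' edge are shrunk and the spot flagged `edge`. Fit failures return a
#' rejected spot with a reason.
#'
#' @param image 2D matrix or 3D array (raw, not filtered).
#' @param candidate one row of [find_candidates()] output (0-based
#'   `x`, `y` and optionally `z`).
#' @param params a [detection_params()] list.
#' @return one-row data.frame (a Spot): `x`, `y`, (`z`,) `amplitude`,
#'   `sigma_x`, `sigma_y`, (`sigma_z`,) `background`,
#'   `integrated_intensity`, `edge`, `rejected`, `reason`.
#' @export
fit_gaussian <- function(image, candidate, params = detection_params()) {
  is3d <- !is.matrix(image)
  d <- if (is3d) dim(image) else c(nrow(image), ncol(image))
  w <- params$fit_window_px
  if (2L * w + 1L < 3L) stop_validation("fit window smaller than 3 px")
  cx <- candidate$x
  cy <- candidate$y
  xr <- max(0L, cx - w):min(d[2L] - 1L, cx + w)
  yr <- max(0L, cy - w):min(d[1L] - 1L, cy + w)
  edge <- length(xr) < 2L * w + 1L || length(yr) < 2L * w + 1L
  reject <- function(reason) {
    out <- data.frame(x = NA_real_, y = NA_real_, amplitude = NA_real_,
                      sigma_x = NA_real_, sigma_y = NA_real_,
                      background = NA_real_,
                      integrated_intensity = NA_real_,
                      edge = edge, rejected = TRUE, reason = reason,
                      stringsAsFactors = FALSE)
    if (is3d) {
      out$z <- NA_real_
      out$sigma_z <- NA_real_
    }
    out
  }
  if (min(length(xr), length(yr)) < 3L) return(reject("window_too_small"))
  if (is3d) {
    cz <- candidate$z
    wz <- max(2L, ceiling(2 * params$log_sigma_z_px))
    zr <- max(0L, cz - wz):min(d[3L] - 1L, cz + wz)
    edge <- edge || length(zr) < 2L * wz + 1L
    win <- image[yr + 1L, xr + 1L, zr + 1L, drop = FALSE]
    win <- array(win, dim = c(length(yr), length(xr), length(zr)))
    if (max(win) - min(win) <= 0) return(reject("no_signal"))
    f <- fit_gaussian_window(win, xr, yr, zr, c(cx, cy, cz),
                             params$log_sigma_px, params$log_sigma_z_px)
    if (!f$ok) return(reject(f$reason))
    p <- f$par
    amp <- p[2L] / (2 * pi * p[6L] * p[7L] * sqrt(2 * pi) * p[8L])
    data.frame(x = p[3L], y = p[4L], z = p[5L], amplitude = amp,
               sigma_x = p[6L], sigma_y = p[7L], sigma_z = p[8L],
               background = p[1L], integrated_intensity = p[2L],
               edge = edge, rejected = FALSE, reason = "none",
               stringsAsFactors = FALSE)
  } else {
    win <- image[yr + 1L, xr + 1L, drop = FALSE]
    if (max(win) - min(win) <= 0) return(reject("no_signal"))
    f <- fit_gaussian_window(win, xr, yr, NULL, c(cx, cy),
                             params$log_sigma_px)
    if (!f$ok) return(reject(f$reason))
    p <- f$par
    amp <- p[2L] / (2 * pi * p[5L] * p[6L])
    data.frame(x = p[3L], y = p[4L], amplitude = amp,
               sigma_x = p[5L], sigma_y = p[6L], background = p[1L],
               integrated_intensity = p[2L], edge = edge,
               rejected = FALSE, reason = "none",
               stringsAsFactors = FALSE)
  }
}

#' Detect and fit spots in an image stack
#'
#' Per frame (2D) or for a whole volume (3D): band-pass with
#' [bandpass_log()], pick candidates with [find_candidates()] (threshold
#' `min_amplitude`, or `thresh_k` robust SDs of the filtered data), and
#' fit each with [fit_gaussian()]. Deterministic given inputs.
#'
#' @param stack 3D array `[y, x, frame]` of 2D frames when
#'   `params$dims == 2`; a single 3D volume `[y, x, z]` when
#'   `params$dims == 3`. A single matrix is treated as one 2D frame.
#' @param params a [detection_params()] list.
#' @return data.frame of accepted spots with a `frame` column (0-based;
#'   0 for a 3D volume).
#' @export
detect_spots <- function(stack, params = detection_params()) {
  if (is.matrix(stack)) {
    stack <- array(stack, dim = c(dim(stack), 1L))
  }
  frames <- if (params$dims == 3L) 1L else dim(stack)[3L]
  out <- list()
  k <- 0L
  for (f in seq_len(frames)) {
    img <- if (params$dims == 3L) stack else stack[, , f]
    filt <- bandpass_log(img, params$log_sigma_px, params$log_sigma_z_px)
    thr <- params$min_amplitude %||% (params$thresh_k * robust_sd(filt))
    ## noiseless input: fall back to a small fraction of the peak
    if (thr <= 0) thr <- max(1e-9, 1e-6 * max(abs(filt)))
    cand <- find_candidates(filt, thr,
                            min_sep = 2 * params$log_sigma_px)
    if (nrow(cand) == 0L) next
    for (i in seq_len(nrow(cand))) {
      sp <- fit_gaussian(img, cand[i, ], params)
      if (sp$rejected) next
      sp$frame <- f - 1L
      k <- k + 1L
      out[[k]] <- sp
    }
  }
  if (k == 0L) {
    res <- data.frame(x = numeric(0), y = numeric(0),
                      amplitude = numeric(0), sigma_x = numeric(0),
                      sigma_y = numeric(0), background = numeric(0),
                      integrated_intensity = numeric(0), edge = logical(0),
                      rejected = logical(0), reason = character(0),
                      frame = integer(0))
    if (params$dims == 3L) {
      res$z <- numeric(0)
      res$sigma_z <- numeric(0)
    }
    return(res)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Match detected spots to ground-truth positions
#'
#' Greedy nearest-neighbor matching within a radius; each truth position
#' matches at most one detection. Used to score precision/recall of the
#' detection stage against the generator's truth.
#'
#' @param detected data.frame with `x`, `y` (and `z`).
#' @param truth data.frame with `x`, `y` (and `z`).
#' @param radius matching radius (px).
#' @return list with `matches` (data.frame `det`, `truth`, `dist`),
#'   `precision`, `recall`.
#' @export
match_spots <- function(detected, truth, radius = 1) {
  if (nrow(detected) == 0L || nrow(truth) == 0L) {
    return(list(matches = data.frame(det = integer(0), truth = integer(0),
                                     dist = numeric(0)),
                precision = if (nrow(detected)) 0 else NA_real_,
                recall = if (nrow(truth)) 0 else NA_real_))
  }
  use_z <- !is.null(detected$z) && !is.null(truth$z)
  d2 <- outer(detected$x, truth$x, "-")^2 + outer(detected$y, truth$y, "-")^2
  if (use_z) d2 <- d2 + outer(detected$z, truth$z, "-")^2
  d <- sqrt(d2)
  pairs <- which(d <= radius, arr.ind = TRUE)
  if (nrow(pairs) == 0L) {
    return(list(matches = data.frame(det = integer(0), truth = integer(0),
                                     dist = numeric(0)),
                precision = 0, recall = 0))
  }
  ord <- order(d[pairs])
  pairs <- pairs[ord, , drop = FALSE]
  used_d <- used_t <- integer(0)
  res <- list()
  k <- 0L
  for (i in seq_len(nrow(pairs))) {
    di <- pairs[i, 1L]
    ti <- pairs[i, 2L]
    if (di %in% used_d || ti %in% used_t) next
    k <- k + 1L
    res[[k]] <- data.frame(det = di, truth = ti, dist = d[di, ti])
    used_d <- c(used_d, di)
    used_t <- c(used_t, ti)
  }
  matches <- do.call(rbind, res)
  list(matches = matches,
       precision = nrow(matches) / nrow(detected),
       recall = nrow(matches) / nrow(truth))
}
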