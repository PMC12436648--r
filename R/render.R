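## Rendering of synthetic movies and 3D smFISH fields through an
## integrated-Gaussian PSF with Poisson photon noise and Gaussian read
## noise. Coordinates are 0-based, pixel-center: pixel i spans
## [i - 0.5, i + 0.5]; matrices are indexed [row = y + 1, col = x + 1].

## Fraction of a unit-volume Gaussian centered at c (sd s) falling into
## each of n pixels along one axis.
pixel_weights <- function(c, s, n) {
  edges <- seq(-0.5, n - 0.5)
  diff(stats::pnorm(edges, mean = c, sd = s))
}

## Add one spot's expected photons into a 2D image (in place-ish).
add_spot_2d <- function(img, x, y, photons, sigma) {
  n <- nrow(img)
  wx <- pixel_weights(x, sigma, ncol(img))
  wy <- pixel_weights(y, sigma, n)
  r <- ceiling(6 * sigma)
  xi <- max(1, floor(x + 1 - r)):min(ncol(img), ceiling(x + 1 + r))
  yi <- max(1, floor(y + 1 - r)):min(nrow(img), ceiling(y + 1 + r))
  img[yi, xi] <- img[yi, xi] + photons * outer(wy[yi], wx[xi])
  img
}

add_spot_3d <- function(vol, x, y, z, photons, sigma_xy, sigma_z) {
  d <- dim(vol)
  wx <- pixel_weights(x, sigma_xy, d[2L])
  wy <- pixel_weights(y, sigma_xy, d[1L])
  wz <- pixel_weights(z, sigma_z, d[3L])
  r <- ceiling(6 * sigma_xy)
  rz <- ceiling(6 * sigma_z)
  xi <- max(1, floor(x + 1 - r)):min(d[2L], ceiling(x + 1 + r))
  yi <- max(1, floor(y + 1 - r)):min(d[1L], ceiling(y + 1 + r))
  zi <- max(1, floor(z + 1 - rz)):min(d[3L], ceiling(z + 1 + rz))
  w <- outer(wy[yi], wx[xi])
  for (k in seq_along(zi)) {
    vol[yi, xi, zi[k]] <- vol[yi, xi, zi[k]] + photons * w * wz[zi[k]]
  }
  vol
}

apply_camera_noise <- function(expected, cfg) {
  if (!cfg$noise) return(expected)
  d <- dim(expected)
  counts <- stats::rpois(length(expected), lambda = as.numeric(expected))
  counts <- counts + stats::rnorm(length(expected), 0, cfg$read_noise_sd)
  array(counts, dim = d)
}

#' Render a simulated binding cohort as a multi-channel movie
#'
#' Renders the mRNA and protein channels of a `binding_cohort` (and the
#' translation-site channel when present) through an integrated-Gaussian
#' PSF: each visible molecule contributes `intensity * photons_per_unit`
#' expected photons distributed over pixels by the exact Gaussian pixel
#' integral; pixel values are Poisson draws plus Gaussian read noise on
#' top of a constant background. Identical `(cohort, cfg)` give an
#' identical stack.
#'
#' @param cohort a `binding_cohort` (trace-level simulation output).
#' @param cfg a [render_config()]; its `field_px` must accommodate the
#'   cohort's molecule positions.
#' @return object of class `image_stack`: list of per-channel arrays
#'   `[y, x, frame]` plus `cfg`.
#' @export
render_movie <- function(cohort, cfg = render_config()) {
  if (!inherits(cohort, "binding_cohort")) {
    stop_validation("cohort must be a binding_cohort")
  }
  nf <- length(cohort$times)
  n <- ncol(cohort$protein)
  fp <- cfg$field_px
  if (n > 0L) {
    bad <- which(apply(cohort$x, 2, max) > fp - 1.5 |
                 apply(cohort$x, 2, min) < 0.5 |
                 apply(cohort$y, 2, max) > fp - 1.5 |
                 apply(cohort$y, 2, min) < 0.5)
    if (length(bad)) {
      stop_validation("molecule position(s) outside the field: mRNA ",
                      paste(bad, collapse = ", "),
                      "; increase cfg$field_px (cohort field was ",
                      cohort$field_px %||% NA, ")")
    }
  }
  set.seed(derive_seed(cfg$seed, 4L))
  occ <- cohort$occupancy
  channels <- list()
  for (ch in c("mrna", "protein", "tls")) {
    src <- switch(ch, mrna = function(i) 1,
                  protein = function(i) occ[, i],
                  tls = if (!is.null(cohort$tls))
                    function(i) as.numeric(cohort$truth$mrna$translating[i])
                  else NULL)
    if (is.null(src)) next
    stack <- array(0, dim = c(fp, fp, nf))
    for (f in seq_len(nf)) {
      img <- matrix(cfg$background_mean, fp, fp)
      for (i in seq_len(n)) {
        inten <- src(i)
        inten <- if (length(inten) > 1L) inten[f] else inten
        if (inten <= 0) next
        img <- add_spot_2d(img, cohort$x[f, i], cohort$y[f, i],
                           inten * cfg$photons_per_unit, cfg$psf_sigma_px)
      }
      stack[, , f] <- img
    }
    channels[[ch]] <- apply_camera_noise(stack, cfg)
  }
  structure(list(channels = channels, cfg = cfg, n_frames = nf),
            class = "image_stack")
}

#' Simulate a two-channel 3D smFISH-IF field with ground truth
#'
#' Places `n_single` mature single proteins (unit intensity) and one
#' translation site per entry of `nap_counts` (intensity
#' `nap_counts[i]` units, within a fraction of a pixel of an
#' mRNA-channel spot), splits them across `n_cells` rectangular cell
#' masks, and renders both channels as 3D stacks through a separable
#' Gaussian PSF with Poisson + read noise.
#'
#' @param n_single number of single mature proteins (total).
#' @param nap_counts positive numeric vector of true nascent-peptide
#'   counts, one per translation site.
#' @param cfg a [render_config()]; `n_z` should be >= 5 for 3D fitting.
#' @param seed integer seed.
#' @param n_cells number of cell masks (vertical strips of the field).
#' @return list with `mrna`, `protein` (3D arrays `[y, x, z]`), `mask`
#'   (integer matrix of cell labels), `truth` (per-spot table) and `cfg`.
#' @export
simulate_smfish_field <- function(n_single, nap_counts,
                                  cfg = render_config(n_z = 9L,
                                                      field_px = 128L),
                                  seed = 1L, n_cells = 2L) {
  n_single <- assert_count(n_single, "n_single")
  if (length(nap_counts) && any(!is.finite(nap_counts) | nap_counts <= 0)) {
    stop_validation("nap_counts must all be positive")
  }
  n_cells <- assert_count(n_cells, "n_cells", min = 1L)
  set.seed(derive_seed(seed, 5L))
  fp <- cfg$field_px
  n_tls <- length(nap_counts)
  n_total <- n_single + n_tls
  ## cell = vertical strip; place each spot in its strip with separation
  strip_w <- fp %/% n_cells
  cell_of <- rep(seq_len(n_cells), length.out = n_total)
  ## interleave so singles and TLS spread over cells
  xy <- matrix(NA_real_, n_total, 2L)
  sep <- 7
  for (cl in seq_len(n_cells)) {
    idx <- which(cell_of == cl)
    x0 <- (cl - 1L) * strip_w
    cx <- seq(x0 + 4, x0 + strip_w - 5, by = sep)
    cyv <- seq(4, fp - 5, by = sep)
    grid <- expand.grid(x = cx, y = cyv)
    if (nrow(grid) < length(idx)) {
      stop_validation("field too small to place ", length(idx),
                      " spots in cell ", cl, " without overlap")
    }
    g <- grid[sample.int(nrow(grid), length(idx)), ]
    xy[idx, 1L] <- g$x + stats::runif(length(idx), -0.5, 0.5)
    xy[idx, 2L] <- g$y + stats::runif(length(idx), -0.5, 0.5)
  }
  zlim <- c(2, max(cfg$n_z - 3, 2))
  zz <- stats::runif(n_total, zlim[1L], zlim[2L])
  type <- rep(c("tls", "single"), c(n_tls, n_single))
  inten <- c(nap_counts, rep(1, n_single))
  truth <- data.frame(id = seq_len(n_total), cell = cell_of, type = type,
                      x = xy[, 1L], y = xy[, 2L], z = zz,
                      intensity = inten)
  mrna_exp <- array(cfg$background_mean, dim = c(fp, fp, cfg$n_z))
  prot_exp <- array(cfg$background_mean, dim = c(fp, fp, cfg$n_z))
  for (i in seq_len(n_total)) {
    prot_exp <- add_spot_3d(prot_exp, truth$x[i], truth$y[i], truth$z[i],
                            truth$intensity[i] * cfg$photons_per_unit,
                            cfg$psf_sigma_px, cfg$psf_sigma_z_px)
    if (truth$type[i] == "tls") {
      ## the translating mRNA sits within a fraction of a pixel
      mx <- truth$x[i] + stats::runif(1, -0.2, 0.2)
      my <- truth$y[i] + stats::runif(1, -0.2, 0.2)
      mrna_exp <- add_spot_3d(mrna_exp, mx, my, truth$z[i],
                              cfg$photons_per_unit,
                              cfg$psf_sigma_px, cfg$psf_sigma_z_px)
    }
  }
  mask <- matrix(0L, fp, fp)
  for (cl in seq_len(n_cells)) {
    xcols <- ((cl - 1L) * strip_w + 1L):(if (cl == n_cells) fp
                                         else cl * strip_w)
    mask[, xcols] <- cl
  }
  list(mrna = apply_camera_noise(mrna_exp, cfg),
       protein = apply_camera_noise(prot_exp, cfg),
       mask = mask, truth = truth, cfg = cfg)
}
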