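test_that("LoG band-pass is linear and kills constants", {
  const <- matrix(7, 24, 24)
  expect_equal(max(abs(bandpass_log(const, 1.3))), 0)
  set.seed(1)
  a <- matrix(rnorm(24 * 24), 24, 24)
  b <- matrix(rnorm(24 * 24), 24, 24)
  expect_equal(bandpass_log(a + b, 1.3),
               bandpass_log(a, 1.3) + bandpass_log(b, 1.3),
               tolerance = 1e-12)
  expect_error(bandpass_log(a, -1), class = "smtrack_validation_error")
  ## the filtered maximum sits on the spot's nearest pixel
  img <- spot_image(17.3, 22.7, 1000, 1.3, size = 40)
  filt <- bandpass_log(img, 1.3)
  peak <- which(filt == max(filt), arr.ind = TRUE)
  expect_equal(unname(peak[1, ]), c(23, 17) + 1L)  # row = y+1, col = x+1
})

test_that("candidate picking respects threshold, separation, monotonicity", {
  ## blank noise at 10 sigma: no candidates
  set.seed(2)
  noise <- matrix(rnorm(64 * 64), 64, 64)
  filt <- bandpass_log(noise, 1.3)
  expect_equal(nrow(find_candidates(filt, 10 * robust_sd(filt))), 0L)
  ## two spots 10 px apart -> 2 candidates; 1 px apart -> 1
  img2 <- spot_image(10, 16, 1000, 1.3, 32) |>
    smtrack:::add_spot_2d(20, 16, 1000, 1.3)
  f2 <- bandpass_log(img2, 1.3)
  expect_equal(nrow(find_candidates(f2, 5)), 2L)
  img1 <- spot_image(15, 16, 1000, 1.3, 32) |>
    smtrack:::add_spot_2d(16, 16, 1000, 1.3)
  f1 <- bandpass_log(img1, 1.3)
  expect_equal(nrow(find_candidates(f1, 5)), 1L)
  ## raising the threshold never increases the candidate count
  set.seed(3)
  noisy <- img2 + matrix(rnorm(32 * 32, 0, 3), 32, 32)
  fn <- bandpass_log(noisy, 1.3)
  counts <- vapply(c(1, 2, 5, 10, 20),
                   function(th) nrow(find_candidates(fn, th)), 0L)
  expect_true(all(diff(counts) <= 0))
})

test_that("noiseless spots re-fit to sub-centipixel accuracy", {
  img <- spot_image(17.30, 22.70, 1000, 1.3, size = 40)
  sp <- fit_gaussian(img, data.frame(x = 17, y = 23), detection_params())
  expect_false(sp$rejected)
  expect_lt(abs(sp$x - 17.30), 0.02)
  expect_lt(abs(sp$y - 22.70), 0.02)
  expect_lt(abs(sp$integrated_intensity - 1000) / 1000, 0.01)
  ## integrated intensity identity and window-sum agreement
  expect_equal(sp$integrated_intensity,
               2 * pi * sp$amplitude * sp$sigma_x * sp$sigma_y,
               tolerance = 1e-6)
  win <- img[(23 - 4):(23 + 4) + 1, (17 - 4):(17 + 4) + 1]
  expect_lt(abs((sum(win) - length(win) * sp$background) -
                  sp$integrated_intensity) / sp$integrated_intensity, 0.02)
  ## flat window is rejected with a reason
  flat <- matrix(3, 21, 21)
  spf <- fit_gaussian(flat, data.frame(x = 10, y = 10), detection_params())
  expect_true(spf$rejected)
  expect_equal(spf$reason, "no_signal")
})

test_that("localization error at moderate SNR is at the expected scale", {
  set.seed(4)
  errs <- replicate(100, {
    x0 <- 15.5 + runif(1, -0.3, 0.3)
    y0 <- 15.5 + runif(1, -0.3, 0.3)
    ## peak about 5x the background shot noise
    img <- spot_image(x0, y0, 400, 1.3, 32, background = 20)
    noisy <- matrix(rpois(length(img), img), nrow(img))
    sp <- fit_gaussian(noisy, data.frame(x = 15, y = 15),
                       detection_params())
    if (sp$rejected) NA else abs(sp$x - x0)
  })
  expect_lt(mean(is.na(errs)), 0.05)
  expect_lt(median(errs, na.rm = TRUE), 0.15)
})

test_that("detection is translation-equivariant and intensity-linear", {
  co <- simulate_binding_cohort(preset_kinetic("pbs_0x"), 5, seed = 6,
                                field_px = 40, window_s = 2)
  cfg1 <- render_config(field_px = 56L, n_frames = length(co$times),
                        photons_per_unit = 1000, seed = 6)
  mv <- render_movie(co, cfg1)
  img <- mv$channels$mrna[, , 1]
  det <- detect_spots(img, detection_params())
  ## integer shift moves coordinates exactly: every interior spot must
  ## reappear 3 px up-left
  shifted <- img[c(4:nrow(img), rep(nrow(img), 3)),
                 c(4:ncol(img), rep(ncol(img), 3))]
  det_s <- detect_spots(shifted, detection_params())
  interior <- det[det$x > 8 & det$y > 8 &
                    det$x < ncol(img) - 9 & det$y < nrow(img) - 9, ]
  expect_gt(nrow(interior), 0)
  for (i in seq_len(nrow(interior))) {
    d <- sqrt((det_s$x - (interior$x[i] - 3))^2 +
                (det_s$y - (interior$y[i] - 3))^2)
    expect_lt(min(d), 1e-3)
  }
  ## doubling the photon yield doubles fitted intensities (+-2%)
  cfg2 <- render_config(field_px = 56L, n_frames = length(co$times),
                        photons_per_unit = 2000, noise = FALSE, seed = 6)
  cfg1b <- render_config(field_px = 56L, n_frames = length(co$times),
                         photons_per_unit = 1000, noise = FALSE, seed = 6)
  i1 <- detect_spots(render_movie(co, cfg1b)$channels$mrna[, , 1],
                     detection_params())
  i2 <- detect_spots(render_movie(co, cfg2)$channels$mrna[, , 1],
                     detection_params())
  expect_equal(nrow(i1), nrow(i2))
  r <- sort(i2$integrated_intensity) / sort(i1$integrated_intensity)
  expect_true(all(abs(r - 2) < 0.04))
  ## empty stack -> empty result
  blank <- array(10, dim = c(24, 24, 2))
  expect_equal(nrow(detect_spots(blank, detection_params())), 0L)
})
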