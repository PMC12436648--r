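test_that("noiseless steps are found at the exact frame", {
  x <- c(rep(0, 50), rep(10, 50))
  expect_equal(detect_change_points(x), 50L)
  ## two-step pulse
  y <- c(rep(0, 30), rep(1, 20), rep(0, 40))
  expect_equal(detect_change_points(y), c(30L, 50L))
  ## constant trace: nothing to split
  expect_length(detect_change_points(rep(2, 80)), 0L)
  ## invariance to adding a constant
  set.seed(30)
  z <- pulse_trace(100, list(c(40, 60)), noise_sd = 0.1)
  expect_equal(detect_change_points(z), detect_change_points(z + 100))
  ## too-short trace is flagged
  b <- detect_change_points(c(1), min_seg_frames = 1L)
  expect_true(isTRUE(attr(b, "too_short")))
})

test_that("null traces split with probability at most alpha", {
  set.seed(31)
  splits <- replicate(300, {
    length(detect_change_points(rnorm(80), alpha = 0.01)) > 0
  })
  ## Bonferroni gating is conservative; allow binomial slack on alpha
  expect_lte(mean(splits), 0.01 + 3 * sqrt(0.01 * 0.99 / 300))
})

test_that("detected boundaries match exhaustive least squares at SNR 5", {
  set.seed(32)
  hits <- replicate(80, {
    n <- sample(40:60, 1)
    i <- sample(8:(n - 20), 1)
    j <- sample((i + 6):(n - 8), 1)
    x <- pulse_trace(n, list(c(i + 1, j)), amplitude = 1, noise_sd = 0.2)
    ls <- ls_two_changepoints(x)
    cp <- detect_change_points(x, alpha = 0.01)
    length(cp) == 2 && all(abs(cp - ls) <= 1)
  })
  expect_gte(mean(hits), 0.9)
})

test_that("bound states obey the eight-second rule and censoring flags", {
  dt <- 2
  ## 3 frames (6 s) above threshold: rejected; 4 frames (8 s): accepted
  x6 <- pulse_trace(40, list(c(10, 12)))
  b6 <- detect_change_points(x6)
  expect_equal(nrow(segment_bound_states(x6, b6, dt)), 0L)
  x8 <- pulse_trace(40, list(c(10, 13)))
  s8 <- segment_bound_states(x8, detect_change_points(x8), dt)
  expect_equal(nrow(s8), 1L)
  expect_equal(s8$duration_s, 8)
  expect_equal(s8$t_start, 9 * dt)
  ## all below threshold -> empty
  expect_equal(nrow(segment_bound_states(rep(0.2, 30), integer(0), dt)), 0L)
  ## boundary-touching segments are censored
  xc <- pulse_trace(30, list(c(1, 6), c(25, 30)))
  sc <- segment_bound_states(xc, detect_change_points(xc), dt,
                             min_bound_s = 0)
  expect_equal(sc$censored_start, c(TRUE, FALSE))
  expect_equal(sc$censored_end, c(FALSE, TRUE))
})

test_that("residence-time policies behave as documented", {
  segs <- data.frame(duration_s = c(2, 4, 6), n_frames = c(1L, 2L, 3L),
                     censored_start = FALSE, censored_end = FALSE)
  expect_equal(residence_time_stats(segs, 2, "mean")$mean_s, 4)
  ## all-censored input is flagged undefined
  cens <- data.frame(duration_s = 10, n_frames = 5L,
                     censored_start = TRUE, censored_end = TRUE)
  r <- residence_time_stats(cens, 2, "mean")
  expect_false(r$defined)
  expect_true(is.na(r$mean_s))
  ## censoring-aware exponential MLE: (sum of exposures) / (events)
  cs <- data.frame(duration_s = c(5, 10, 20), n_frames = c(1L, 2L, 4L),
                   censored_start = FALSE,
                   censored_end = c(FALSE, FALSE, TRUE))
  expect_equal(residence_time_stats(cs, 5, "exp_censored")$mean_s,
               (5 + 10 + 20) / 2)
  ## frame-sampling MLE inverts the geometric run-length law
  set.seed(33)
  tau <- 3.6; dt <- 2
  q <- exp(-dt / tau)
  nfr <- rgeom(4000, 1 - q) + 1L
  segs2 <- data.frame(duration_s = nfr * dt, n_frames = nfr,
                      censored_start = FALSE, censored_end = FALSE)
  est <- residence_time_stats(segs2, dt, "exp_mle")$mean_s
  expect_lt(abs(est - tau), 3 * tau / sqrt(4000))
})

test_that("the markov policy corrects frame sampling and rebinding", {
  co <- simulate_binding_cohort(preset_kinetic("pbs_1x"), 250, seed = 34)
  occ <- co$occupancy > 0
  segs <- do.call(rbind, lapply(seq_len(ncol(occ)), function(i) {
    r <- smtrack:::true_runs(occ[, i])
    if (!nrow(r)) return(NULL)
    data.frame(n_frames = r$length, duration_s = r$length * co$dt_s,
               censored_start = r$start == 1,
               censored_end = r$end == nrow(occ))
  }))
  est <- residence_time_stats(segs, co$dt_s, "markov",
                              total_frames = length(occ),
                              n_traces = ncol(occ))
  expect_lt(abs(est$mean_s - 3.6), 3 * 3.6 / sqrt(nrow(segs)))
})

test_that("stoichiometry normalization is exact and scale-invariant", {
  expect_equal(normalize_stoichiometry(5, 5), 1)
  x <- c(1, 2.5, 36)
  expect_equal(normalize_stoichiometry(x * 7, 2 * 7),
               normalize_stoichiometry(x, 2))
  expect_error(normalize_stoichiometry(x, 0),
               class = "smtrack_validation_error")
  ## multi-binder spots: normalized level near the binder count
  co3 <- simulate_binding_cohort(preset_kinetic("pbs_3x"), 150, seed = 35)
  seg <- segment_binding_cohort(co3, min_bound_s = 8)
  lv <- normalize_stoichiometry(seg$segments$mean_level, 1)
  expect_gt(max(lv), 1.5)   # multi-binder levels present
})

test_that("distribution comparisons match hand-enumerated values", {
  id <- compare_distributions(1:20, 1:20, "ks")
  expect_equal(id$statistic, 0)
  expect_equal(id$p_value, 1)
  ## sup|F_a - F_b| for {1,2,3} vs {1,2,3,4} is 0.25 at x = 3
  ks <- suppressWarnings(compare_distributions(c(1, 2, 3), c(1, 2, 3, 4),
                                               "ks"))
  expect_equal(ks$statistic, 0.25)
  tt <- compare_distributions(c(1, 2, 3, 4), c(2, 3, 4, 5), "t_equal_var")
  ref <- t.test(c(1, 2, 3, 4), c(2, 3, 4, 5), var.equal = TRUE)
  expect_equal(tt$p_value, ref$p.value)
})
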