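test_that("degenerate cohorts behave as documented", {
  co <- simulate_binding_cohort(preset_kinetic("pbs_1x"), 0)
  expect_equal(ncol(co$protein), 0L)
  expect_equal(nrow(co$truth$episodes), 0L)

  ## no binding sites: pure noise protein traces, zero episodes
  co0 <- simulate_binding_cohort(preset_kinetic("pbs_0x"), 20, seed = 3,
                                 noise_sd = 0.1)
  expect_equal(nrow(co0$truth$episodes), 0L)
  expect_lt(max(abs(co0$protein)), 0.1 * 6)
  expect_false(any(co0$truth$mrna$engaged))

  expect_error(simulate_binding_cohort(preset_kinetic("pbs_1x"), -1),
               class = "smtrack_validation_error")
  expect_error(simulate_binding_cohort(preset_kinetic("pbs_1x"), 5,
                                       window_s = 1, dt_s = 2),
               class = "smtrack_validation_error")
})

test_that("generated on-times match the preset by the law of large numbers", {
  co <- simulate_binding_cohort(preset_kinetic("pbs_1x"), 400, seed = 7)
  ep <- co$truth$episodes
  unc <- ep[!ep$censored_start & !ep$censored_end, ]
  d <- unc$end_s - unc$start_s
  expect_gt(length(d), 1500)
  se <- sd(d) / sqrt(length(d))
  expect_lt(abs(mean(d) - 3.6), 3.5 * se)
})

test_that("cohorts are reproducible and window truncation preserves truth", {
  a <- simulate_binding_cohort(preset_kinetic("pbs_1x"), 15, seed = 5)
  b <- simulate_binding_cohort(preset_kinetic("pbs_1x"), 15, seed = 5)
  expect_identical(a$protein, b$protein)
  expect_identical(a$truth$episodes, b$truth$episodes)
  cc <- simulate_binding_cohort(preset_kinetic("pbs_1x"), 15, seed = 6)
  expect_false(identical(a$truth$episodes, cc$truth$episodes))

  ## truncated window: episodes are a prefix of the longer window's
  ## (at a fixed binding rate; the calibrated 1x rate depends on the
  ## window, so fix duty_or_kon explicitly)
  pk <- kinetic_preset("fixed_kon", p_engaged = 0.5, n_sites = 1L,
                       mean_on_s = 3.6, duty_or_kon = 0.0286,
                       engagement = "kinetic")
  long <- simulate_binding_cohort(pk, 10, seed = 9, window_s = 300)
  short <- simulate_binding_cohort(pk, 10, seed = 9, window_s = 150)
  es <- short$truth$episodes
  el <- long$truth$episodes
  for (i in seq_len(nrow(es))) {
    j <- which(el$mrna == es$mrna[i] & el$site == es$site[i] &
                 abs(el$start_s - es$start_s[i]) < 1e-9)
    expect_length(j, 1L)
    expect_equal(min(el$end_s[j], 150), es$end_s[i])
  }
})

test_that("episode-model cohorts honor the engagement gate", {
  pz <- preset_kinetic("polyA60_znf")
  co <- simulate_binding_cohort(pz, 400, seed = 11)
  tab <- table(co$truth$mrna$gate,
               co$truth$mrna$mrna %in% co$truth$episodes$mrna)
  ## gated-off mRNAs draw no episodes; gated-on draw at least one
  expect_equal(sum(co$truth$mrna$gate & !(co$truth$mrna$mrna %in%
                                            co$truth$episodes$mrna)), 0L)
  expect_equal(nrow(co$truth$episodes), sum(co$truth$mrna$gate))
  ## engaged fraction near the preset probability
  p <- mean(co$truth$mrna$engaged)
  expect_lt(abs(p - 0.8), 3 * sqrt(0.8 * 0.2 / 400))
  ## per-site episodes are disjoint in time
  ep <- co$truth$episodes
  by_site <- split(ep, list(ep$mrna, ep$site), drop = TRUE)
  overlaps <- vapply(by_site, function(d) {
    d <- d[order(d$start_s), ]
    nrow(d) > 1 && any(d$start_s[-1] < d$end_s[-nrow(d)])
  }, logical(1))
  expect_false(any(overlaps))
})

test_that("runoff cohorts encode clearance, damage and censoring", {
  pr <- preset_runoff("runoff_damaged")
  co <- simulate_runoff_cohort(pr, 200, seed = 13)
  tr <- co$truth
  ## damaged mRNAs persist: last-frame TLS still near plateau
  expect_true(all(co$tls[nrow(co$tls), tr$damaged] > 0.5))
  ## forced persistence when damaged_frac = 1
  all_dmg <- simulate_runoff_cohort(
    runoff_preset("x", damaged_frac = 1), 30, seed = 1)
  expect_true(all(all_dmg$tls[nrow(all_dmg$tls), ] > 0.5))
  ## window shorter than all clearance times: everything censored
  cens <- simulate_runoff_cohort(preset_runoff("runoff_wt"), 30,
                                 window_s = 60, seed = 2)
  expect_true(all(cens$truth$censored))
  ## scale ratio of true medians near the preset ratio
  wt <- simulate_runoff_cohort(preset_runoff("runoff_wt"), 400, seed = 3)
  oe <- simulate_runoff_cohort(preset_runoff("runoff_oe"), 400, seed = 4)
  ratio <- median(wt$truth$clearance_s) / median(oe$truth$clearance_s)
  expect_lt(abs(ratio - 1.5), 0.15)
  expect_error(runoff_preset("x", clearance_scale = -2),
               class = "smtrack_validation_error")
})

test_that("trace-to-track bridge conserves molecules and channels", {
  co <- simulate_binding_cohort(preset_kinetic("pbs_1x"), 25, seed = 15,
                                n_cells = 5L)
  tracks <- cohort_to_tracks(co, seed = 15)
  expect_setequal(unique(tracks$channel), c("mrna", "protein"))
  ## one mRNA track per molecule
  m <- tracks[tracks$channel == "mrna", ]
  expect_equal(length(unique(m$track_id)), 25L)
  ## protein tracks only on frames where the binder is present
  p <- tracks[tracks$channel == "protein", ]
  if (nrow(p)) {
    occ <- co$occupancy[cbind(p$frame + 1L, p$truth_mrna)]
    expect_true(mean(occ > 0) > 0.99)
  }
})
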