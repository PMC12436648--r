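test_that("track association honors the temporal-overlap linkage rule", {
  rules <- link_rules("steady_state")
  m <- make_track(1L, "mrna", 0:50, 10, 10)
  ## zero temporal intersection: not linked
  p0 <- make_track(10L, "protein", 60:70, 10, 10)
  r0 <- associate_tracks(rbind(m, p0), rules)
  expect_equal(nrow(r0$links), 0L)
  ## 3 within-radius frames: not linked; 4 frames: linked
  p3 <- make_track(11L, "protein", 0:2, 10.1, 10)
  expect_equal(nrow(associate_tracks(rbind(m, p3), rules)$links), 0L)
  p4 <- make_track(12L, "protein", 0:3, 10.1, 10)
  l4 <- associate_tracks(rbind(m, p4), rules)$links
  expect_equal(nrow(l4), 1L)
  expect_equal(l4$mrna_track, 1L)
  ## far spots never link even with full temporal overlap
  pfar <- make_track(13L, "protein", 0:50, 30, 30)
  expect_equal(nrow(associate_tracks(rbind(m, pfar), rules)$links), 0L)
  ## each protein track is assigned to exactly one mRNA (no double count)
  m2 <- make_track(2L, "mrna", 0:50, 11.5, 10)
  both <- associate_tracks(rbind(m, m2, p4), rules)$links
  expect_equal(nrow(both), 1L)
  expect_equal(both$mrna_track, 1L)  # nearer mRNA wins
})

test_that("colocalization events need the mode's consecutive-frame run", {
  ss <- link_rules("steady_state")
  ru <- link_rules("runoff_uv")
  expect_false(call_colocalization(
    c(TRUE, TRUE, TRUE, TRUE, FALSE, TRUE), ss)$colocalized)
  r5 <- call_colocalization(rep(TRUE, 5), ss)
  expect_true(r5$colocalized)
  expect_equal(nrow(r5$events), 1L)
  expect_true(call_colocalization(c(TRUE, TRUE), ru)$colocalized)
  expect_false(call_colocalization(c(TRUE, FALSE, TRUE), ru)$colocalized)
  ## events outside the scoring window are ignored
  w <- rep(TRUE, 10)
  late <- call_colocalization(w, ss, t_s = seq(301, 320, length.out = 10))
  expect_false(late$colocalized)
})

test_that("relaxing the consecutive-frame rule never lowers a fraction", {
  set.seed(20)
  co <- simulate_binding_cohort(preset_kinetic("pbs_1x"), 120,
                                n_cells = 4L, seed = 20)
  fr <- vapply(c(7L, 5L, 3L, 1L), function(k) {
    rules <- link_rules("steady_state", min_consec_frames_coloc = k)
    analyze_binding_cohort(co, rules, seed = 20)$grand_mean_frac
  }, 0)
  expect_true(all(diff(fr) >= 0))
})

test_that("translating classification and cell eligibility follow the rules", {
  rules <- link_rules("steady_state")
  m <- make_track(1L, "mrna", 0:50, 10, 10)
  tls <- make_track(20L, "tls", 0:30, 10.05, 10)
  rec <- associate_tracks(rbind(m, tls), rules)
  expect_true(classify_translating(rec))
  m2 <- make_track(2L, "mrna", 0:50, 30, 30)
  rec2 <- associate_tracks(rbind(m, m2, tls), rules)
  expect_equal(classify_translating(rec2),
               c(TRUE, FALSE)[order(rec2$mrna$mrna_track)])

  ## cell with exactly 15 mRNAs is ineligible under "more than 15"
  tracks15 <- do.call(rbind, lapply(1:15, function(i)
    make_track(i, "mrna", 0:50, 6 * i, 10)))
  r15 <- colocalize_records(associate_tracks(tracks15, rules), rules)
  cs <- summarize_cells(r15, rules, has_tls = FALSE)
  expect_false(cs$eligible)
  tracks16 <- rbind(tracks15, make_track(16L, "mrna", 0:50, 6 * 16, 10))
  r16 <- colocalize_records(associate_tracks(tracks16, rules), rules)
  expect_true(summarize_cells(r16, rules, has_tls = FALSE)$eligible)

  ## all mRNAs colocalized -> fraction 1
  prot <- do.call(rbind, lapply(1:15, function(i)
    make_track(100L + i, "protein", 0:20, 6 * i + 0.1, 10)))
  rall <- colocalize_records(associate_tracks(rbind(tracks15, prot), rules),
                             rules)
  expect_equal(summarize_cells(rall, rules, has_tls = FALSE)$frac_coloc, 1)
})

test_that("per-cell fractions recover the preset engagement probability", {
  co <- simulate_binding_cohort(preset_kinetic("pbs_1x"), 600,
                                n_cells = 20L, seed = 21)
  ana <- analyze_binding_cohort(co, link_rules("steady_state"), seed = 21)
  expect_true(all(ana$cells$eligible))
  se <- sqrt(0.5 * 0.5 / 600)
  expect_lt(abs(ana$grand_mean_frac - 0.5), 3 * se)
  ## the measured per-mRNA call agrees with the generator truth
  mt <- ana$records$mrna
  truth <- co$truth$mrna$engaged[mt$truth_mrna]
  expect_gt(mean(mt$colocalized == truth), 0.98)
})
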