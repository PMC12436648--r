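## One rendered field shared across the smFISH tests (built once).
local_field <- local({
  field <- NULL
  function() {
    if (is.null(field)) {
      set.seed(50)
      naps <- rgamma(30, shape = 4, scale = 40.3 / 4)
      cfg <- render_config(field_px = 128L, n_z = 9L,
                           photons_per_unit = 2000, seed = 50)
      field <<- list(f = simulate_smfish_field(40, naps, cfg, seed = 50,
                                               n_cells = 2L),
                     naps = naps)
    }
    field
  }
})

test_that("blank channels yield no detections", {
  blank <- list(mrna = array(10, dim = c(48, 48, 5)),
                protein = array(10, dim = c(48, 48, 5)),
                mask = matrix(1L, 48, 48))
  expect_equal(nrow(detect_mrna_spots(blank)), 0L)
})

test_that("smFISH quantification recovers sites, units and NAP counts", {
  fx <- local_field()
  res <- analyze_smfish_field(fx$f)
  tru_t <- fx$f$truth[fx$f$truth$type == "tls", ]
  ## every translation site recovered and linked to an mRNA
  m <- match_spots(res$tls, tru_t, 1.5)
  expect_gte(m$recall, 0.95)
  expect_false(anyNA(res$tls$mrna_id))
  ## per-cell unit intensity within a few percent of the rendered unit
  expect_true(all(res$units$ok))
  expect_true(all(abs(res$units$unit_mean - 2000) / 2000 < 0.05))
  ## NAP counts match the generator truth
  est <- mean(res$tls$nap_count, na.rm = TRUE)
  expect_lt(abs(est - mean(fx$naps)), 3 * sd(fx$naps) / sqrt(30) + 1)
  ## mean absolute per-site error within 10%
  mm <- m$matches
  rel <- abs(res$tls$nap_count[mm$det] - tru_t$intensity[mm$truth]) /
    tru_t$intensity[mm$truth]
  expect_lt(mean(rel, na.rm = TRUE), 0.1)
})

test_that("NAP counting is per-cell scoped and scale-invariant", {
  tls <- data.frame(cell = c(1L, 2L), integrated_intensity = c(100, 100),
                    x = 0, y = 0, z = 0, sigma_x = 1, sigma_y = 1,
                    sigma_z = 1)
  units <- data.frame(cell = c(1L, 2L), unit_mean = c(10, 50),
                      n_single = c(9L, 9L), ok = TRUE, reason = "none")
  out <- nap_counts(tls, units)
  expect_equal(out$nap_count, c(10, 2))   # each cell uses its own unit
  ## identity: TLS equal to the unit mean -> exactly 1.0
  one <- nap_counts(data.frame(cell = 1L, integrated_intensity = 10),
                    units)
  expect_equal(one$nap_count, 1)
  ## global rescaling of the protein channel cancels exactly
  sc <- nap_counts(transform(tls, integrated_intensity =
                               integrated_intensity * 7.3),
                   transform(units, unit_mean = unit_mean * 7.3))
  expect_equal(sc$nap_count, out$nap_count)
  ## a cell without calibration is flagged
  units2 <- transform(units, ok = c(TRUE, FALSE))
  miss <- nap_counts(tls, units2)
  expect_true(is.na(miss$nap_count[2]))
  expect_equal(miss$nap_reason[2], "no_unit_calibration")
})

test_that("TLS classification respects the distance thresholds", {
  fx <- local_field()
  mr <- detect_mrna_spots(fx$f)
  d0 <- detect_translation_sites(fx$f, mr)
  ## shrinking the lateral radius never increases the TLS count
  counts <- vapply(c(3, 2, 1, 0.3), function(rr) {
    nrow(detect_translation_sites(fx$f, mr, max_dist_xy = rr,
                                  protein_spots = d0$protein_spots)$tls)
  }, 0L)
  expect_true(all(diff(counts) <= 0))
  ## an mRNA-free protein spot is not a TLS
  far <- d0$protein_spots[!d0$protein_spots$is_tls, ]
  expect_true(nrow(far) > 0)
})

test_that("single-protein calibration needs a minimum per-cell count", {
  spots <- data.frame(cell = 1L, is_tls = FALSE,
                      integrated_intensity = c(10, 11, 12),
                      x = c(1, 10, 20), y = 1, z = 1)
  tls <- data.frame(cell = 1L, x = 100, y = 100, z = 3,
                    sigma_x = 1, sigma_y = 1, sigma_z = 1)
  u <- single_protein_intensity(spots, tls, min_n = 5L)
  expect_false(u$ok)
  expect_equal(u$reason, "too_few_singles")
  u2 <- single_protein_intensity(spots, tls, min_n = 2L)
  expect_true(u2$ok)
  expect_equal(u2$unit_mean, 11)
  ## spots inside a TLS exclusion ellipsoid are removed from calibration
  near <- rbind(spots,
                data.frame(cell = 1L, is_tls = FALSE,
                           integrated_intensity = 500,
                           x = 100.5, y = 100.5, z = 3))
  u3 <- single_protein_intensity(near, tls, min_n = 2L)
  expect_equal(u3$unit_mean, 11)  # the bright neighbor was excluded
})

test_that("NAP distribution comparison applies the sqrt transform", {
  set.seed(51)
  a <- rgamma(60, 2, 0.05)
  b <- rgamma(60, 2, 0.04)
  ours <- compare_nap_distributions(a, b)
  ref <- t.test(sqrt(a), sqrt(b), var.equal = TRUE)
  expect_equal(ours$p_value, ref$p.value)
  raw <- t.test(a, b, var.equal = TRUE)
  expect_false(isTRUE(all.equal(ours$p_value, raw$p.value)))
  expect_error(compare_nap_distributions(c(-1, 2), b),
               class = "smtrack_validation_error")
})
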