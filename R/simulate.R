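## Synthetic-data generator: trace-level simulation of binding and runoff
## cohorts with exact ground truth. Rendering to images lives in render.R.

## Draw alternating unbound/bound episodes of a single site over [0, window],
## starting from the stationary distribution of the two-state chain
## (binding may be ongoing at t = 0; such episodes are start-censored).
sample_renewal_episodes <- function(kon, mean_on_s, window_s) {
  if (kon <= 0) {
    return(data.frame(start_s = numeric(0), end_s = numeric(0),
                      censored_start = logical(0), censored_end = logical(0)))
  }
  pi_on <- kon / (kon + 1 / mean_on_s)
  starts <- ends <- numeric(0)
  cstart <- logical(0)
  t <- 0
  if (stats::runif(1) < pi_on) {
    d <- stats::rexp(1, 1 / mean_on_s)   # residual on-time (memoryless)
    starts <- 0; ends <- d; cstart <- TRUE
    t <- d
  }
  while (t < window_s) {
    t <- t + stats::rexp(1, kon)         # unbound waiting time
    if (t >= window_s) break
    d <- stats::rexp(1, 1 / mean_on_s)
    starts <- c(starts, t); ends <- c(ends, t + d); cstart <- c(cstart, FALSE)
    t <- t + d
  }
  cend <- ends > window_s
  ends <- pmin(ends, window_s)
  data.frame(start_s = starts, end_s = ends,
             censored_start = cstart, censored_end = cend)
}

## Number of labeled binders bound at each sample time.
occupancy_at <- function(times, episodes) {
  occ <- integer(length(times))
  if (nrow(episodes) == 0L) return(occ)
  ## inclusive end: window-clipped (censored) episodes must still cover
  ## the final frame; for continuous durations exact equality elsewhere
  ## has probability zero
  for (j in seq_len(nrow(episodes))) {
    occ <- occ + as.integer(times >= episodes$start_s[j] &
                            times <= episodes$end_s[j])
  }
  occ
}

## Place n points in a square field with a minimum pairwise separation,
## by jittering a random subset of a regular grid.
place_positions <- function(n, field_px, min_sep = 8, margin = 5) {
  if (n == 0L) return(cbind(x = numeric(0), y = numeric(0)))
  centers <- seq(margin, field_px - 1 - margin, by = min_sep)
  grid <- expand.grid(x = centers, y = centers)
  if (nrow(grid) < n) {
    stop_validation("field too small to place ", n,
                    " molecules at separation ", min_sep)
  }
  idx <- sample.int(nrow(grid), n)
  cbind(x = grid$x[idx] + stats::runif(n, -0.5, 0.5),
        y = grid$y[idx] + stats::runif(n, -0.5, 0.5))
}

## Confined lateral wander: discrete Ornstein-Uhlenbeck around an anchor.
ou_path <- function(n, anchor, sd_px, tau_s, dt_s) {
  if (sd_px <= 0) return(rep(anchor, n))
  a <- exp(-dt_s / tau_s)
  innov <- stats::rnorm(n, 0, sd_px * sqrt(1 - a^2))
  dev <- stats::filter(innov, a, method = "recursive",
                       init = stats::rnorm(1, 0, sd_px))
  anchor + as.numeric(dev)
}

#' Simulate a cohort of mRNAs with stochastic protein binding
#'
#' Generates per-mRNA intensity traces (mRNA, protein and — for the
#' episode model — translation-site channels) together with the exact
#' episode-level ground truth. The protein trace equals the number of
#' concurrently bound, labeled binders times one intensity unit, plus
#' Gaussian noise; the mRNA trace is a constant unit plateau plus noise.
#'
#' @param preset a [kinetic_preset()].
#' @param n_mrna number of mRNAs (>= 0).
#' @param window_s observation window in seconds.
#' @param dt_s frame interval in seconds.
#' @param seed integer seed; identical inputs give identical cohorts.
#' @param noise_sd Gaussian noise SD on the traces, in intensity units.
#' @param n_cells number of cells the mRNAs are split across (consecutive
#'   blocks of mRNAs share a cell id).
#' @param field_px synthetic field size used for molecule placement.
#' @param confinement_sd_px stationary SD of the tethered-mRNA wander (px).
#' @param confinement_tau_s relaxation time of the confined motion (s).
#' @return an object of class `binding_cohort`: a list with `times`,
#'   trace matrices (`n_frames x n_mrna`) per channel, position matrices
#'   `x`/`y`, and `truth` (`$mrna` per-molecule table, `$episodes` table).
#' @export
simulate_binding_cohort <- function(preset, n_mrna, window_s = 300,
                                    dt_s = 2, seed = 1L, noise_sd = 0.1,
                                    n_cells = 1L, field_px = 160L,
                                    confinement_sd_px = 0.6,
                                    confinement_tau_s = 10) {
  if (!inherits(preset, "kinetic_preset")) {
    stop_validation("preset must be a kinetic_preset")
  }
  n_mrna <- assert_count(n_mrna, "n_mrna")
  assert_pos(dt_s, "dt_s")
  if (window_s < dt_s) stop_validation("window_s must be >= dt_s")
  assert_pos(noise_sd, "noise_sd", strict = FALSE)
  n_cells <- assert_count(n_cells, "n_cells", min = 1L)
  set.seed(derive_seed(seed, 1L))

  times <- seq(0, window_s, by = dt_s)
  nf <- length(times)
  ## windows shorter than the qualification run cap the rule at the
  ## window length so short diagnostic simulations stay well-defined
  qual <- min(preset$qual_frames, nf)

  if (n_mrna == 0L) {
    empty <- matrix(numeric(0), nrow = nf, ncol = 0)
    return(structure(list(
      times = times,
      mrna = empty, protein = empty,
      tls = if (preset$model == "episode") empty else NULL,
      occupancy = empty, x = empty, y = empty,
      truth = list(
        mrna = data.frame(mrna = integer(0), cell = integer(0),
                          x0 = numeric(0), y0 = numeric(0),
                          translating = logical(0), engaged = logical(0)),
        episodes = data.frame(mrna = integer(0), site = integer(0),
                              start_s = numeric(0), end_s = numeric(0),
                              labeled = logical(0),
                              censored_start = logical(0),
                              censored_end = logical(0))),
      preset = preset, dt_s = dt_s, window_s = window_s,
      noise_sd = noise_sd, seed = seed, field_px = field_px),
      class = "binding_cohort"))
  }

  kon <- preset$duty_or_kon
  if (preset$model == "renewal" && preset$n_sites > 0L && is.na(kon)) {
    if (preset$engagement == "kinetic") {
      kon <- calibrate_kon(preset$mean_on_s, preset$p_engaged,
                           window_s, dt_s, qual)
    } else {
      kon <- calibrate_kon(preset$mean_on_s, 0.5, window_s, dt_s, qual)
    }
  }

  field_eff <- max(field_px, ceiling(sqrt(n_mrna)) * 8L + 12L)
  pos <- place_positions(n_mrna, field_eff)
  cell <- ((seq_len(n_mrna) - 1L) %/% ceiling(n_mrna / n_cells)) + 1L
  qual_s <- qual * dt_s

  ep_list <- vector("list", n_mrna)
  translating <- rep(TRUE, n_mrna)
  gate <- logical(n_mrna)
  for (i in seq_len(n_mrna)) {
    ## per-molecule stream: episode draws do not depend on how many
    ## draws other molecules (or other window lengths) consumed, so a
    ## truncated window yields a prefix of the longer window's truth
    set.seed(derive_seed(seed, 1000L + i))
    eps <- NULL
    if (preset$model == "episode") {
      translating[i] <- stats::runif(1) < preset$translating_frac
      gate[i] <- translating[i] && stats::runif(1) < preset$p_engaged
      if (gate[i]) {
        start <- stats::runif(1, 0, max(window_s - qual_s, 0))
        if (stats::runif(1) < preset$persistent_frac) {
          eps <- data.frame(start_s = start, end_s = window_s,
                            censored_start = FALSE, censored_end = TRUE,
                            site = 1L)
        } else {
          mean_s <- preset$transient_mean_min * 60
          dur <- qual_s + stats::rexp(1, 1 / (mean_s - qual_s))
          end <- start + dur
          eps <- data.frame(start_s = start, end_s = min(end, window_s),
                            censored_start = FALSE,
                            censored_end = end > window_s, site = 1L)
        }
      }
    } else if (preset$n_sites > 0L) {
      draw_sites <- function() {
        out <- lapply(seq_len(preset$n_sites), function(s) {
          e <- sample_renewal_episodes(kon, preset$mean_on_s, window_s)
          if (nrow(e)) e$site <- s
          e
        })
        do.call(rbind, out[vapply(out, nrow, 1L) > 0])
      }
      if (preset$engagement == "gated") {
        gate[i] <- stats::runif(1) < preset$p_engaged
        if (gate[i]) {
          ## engaged mRNAs are guaranteed a detectable (qualifying) run
          for (try in 1:200) {
            eps <- draw_sites()
            occ <- if (is.null(eps)) integer(nf)
                   else occupancy_at(times, eps)
            if (max_true_run(occ > 0) >= qual) break
          }
        }
      } else {
        eps <- draw_sites()
        gate[i] <- TRUE
      }
    }
    if (is.null(eps)) {
      eps <- data.frame(start_s = numeric(0), end_s = numeric(0),
                        censored_start = logical(0),
                        censored_end = logical(0), site = integer(0))
    }
    if (nrow(eps)) {
      eps$labeled <- stats::runif(nrow(eps)) < preset$label_eff
      eps$mrna <- i
      eps <- eps[order(eps$site, eps$start_s), ]
    } else {
      eps$labeled <- logical(0)
      eps$mrna <- integer(0)
    }
    ep_list[[i]] <- eps
  }
  episodes <- do.call(rbind, ep_list)
  rownames(episodes) <- NULL
  episodes <- episodes[, c("mrna", "site", "start_s", "end_s", "labeled",
                           "censored_start", "censored_end")]

  ## traces and positions
  protein <- matrix(0, nf, n_mrna)
  occupancy <- matrix(0L, nf, n_mrna)
  x <- matrix(0, nf, n_mrna)
  y <- matrix(0, nf, n_mrna)
  engaged <- logical(n_mrna)
  for (i in seq_len(n_mrna)) {
    set.seed(derive_seed(seed, 500000L + i))
    eps <- ep_list[[i]]
    occ <- occupancy_at(times, eps[eps$labeled, , drop = FALSE])
    occupancy[, i] <- occ
    engaged[i] <- max_true_run(occ > 0) >= qual
    protein[, i] <- occ + stats::rnorm(nf, 0, noise_sd)
    x[, i] <- ou_path(nf, pos[i, "x"], confinement_sd_px,
                      confinement_tau_s, dt_s)
    y[, i] <- ou_path(nf, pos[i, "y"], confinement_sd_px,
                      confinement_tau_s, dt_s)
  }
  mrna <- matrix(1 + stats::rnorm(nf * n_mrna, 0, noise_sd), nf, n_mrna)
  tls <- NULL
  if (preset$model == "episode") {
    tls <- matrix(stats::rnorm(nf * n_mrna, 0, noise_sd), nf, n_mrna)
    tls[, translating] <- tls[, translating] + 1
  }

  structure(list(
    times = times, mrna = mrna, protein = protein, tls = tls,
    occupancy = occupancy, x = x, y = y,
    truth = list(
      mrna = data.frame(mrna = seq_len(n_mrna), cell = cell,
                        x0 = pos[, "x"], y0 = pos[, "y"],
                        translating = translating, engaged = engaged,
                        gate = gate),
      episodes = episodes),
    preset = preset, kon = if (preset$model == "renewal") kon else NA_real_,
    dt_s = dt_s, window_s = window_s, noise_sd = noise_sd, seed = seed,
    field_px = field_eff),
    class = "binding_cohort")
}

#' Simulate a ribosome-runoff cohort after translation-initiation block
#'
#' Each mRNA's translation-site (TLS) trace holds a unit plateau for a
#' short uniform delay, then decays linearly, crossing 10% of its plateau
#' exactly at the true clearance time after the plateau maximum. Clearance
#' times are lognormal draws scaled by the preset's `clearance_scale`.
#' Damaged (runoff-resistant) mRNAs keep their plateau for the whole
#' window, and a preset-controlled fraction of them carry a persistent
#' protein (ZNF598) signal. The mRNA channel persists throughout.
#'
#' @param preset a [runoff_preset()].
#' @param n_mrna number of mRNAs.
#' @param dt_s frame interval (s), 10 s by default.
#' @param window_s observation window (s), 30 min by default.
#' @param seed integer seed.
#' @param noise_sd trace noise SD (intensity units).
#' @param baseline optional override of the preset baseline distribution.
#' @return object of class `runoff_cohort` with trace matrices `tls`,
#'   `mrna`, `protein` and `truth` (per-mRNA table with `damaged`,
#'   `znf_bound`, `clearance_s`, `t_max_s`, `censored`).
#' @export
simulate_runoff_cohort <- function(preset, n_mrna, dt_s = 10,
                                   window_s = 1800, seed = 1L,
                                   noise_sd = 0.05, baseline = NULL) {
  if (!inherits(preset, "runoff_preset")) {
    stop_validation("preset must be a runoff_preset")
  }
  n_mrna <- assert_count(n_mrna, "n_mrna")
  assert_pos(dt_s, "dt_s")
  if (window_s < dt_s) stop_validation("window_s must be >= dt_s")
  set.seed(derive_seed(seed, 2L))
  bl <- baseline %||% preset$baseline

  times <- seq(0, window_s, by = dt_s)
  nf <- length(times)
  damaged <- stats::runif(n_mrna) < preset$damaged_frac
  znf <- damaged & (stats::runif(n_mrna) < preset$znf_on_damaged)
  clearance <- stats::rlnorm(n_mrna, bl$meanlog, bl$sdlog) *
    preset$clearance_scale
  clearance[damaged] <- Inf
  t_max <- stats::runif(n_mrna, 0, preset$hold_max_s)

  tls <- matrix(0, nf, n_mrna)
  for (i in seq_len(n_mrna)) {
    if (damaged[i]) {
      sig <- rep(1, nf)
    } else {
      ## linear ramp from the plateau; hits 0.10 at t_max + clearance
      sig <- pmax(0, pmin(1, 1 - 0.9 * (times - t_max[i]) / clearance[i]))
    }
    tls[, i] <- sig + stats::rnorm(nf, 0, noise_sd)
  }
  mrna <- matrix(1 + stats::rnorm(nf * n_mrna, 0, noise_sd), nf, n_mrna)
  protein <- matrix(stats::rnorm(nf * n_mrna, 0, noise_sd), nf, n_mrna)
  protein[, znf] <- protein[, znf] + 1

  structure(list(
    times = times, tls = tls, mrna = mrna, protein = protein,
    truth = data.frame(mrna = seq_len(n_mrna), damaged = damaged,
                       znf_bound = znf, clearance_s = clearance,
                       t_max_s = t_max,
                       censored = t_max + clearance / 0.9 > window_s),
    preset = preset, dt_s = dt_s, window_s = window_s,
    noise_sd = noise_sd, seed = seed),
    class = "runoff_cohort")
}

#' Convert a simulated cohort into spot-level track tables
#'
#' Bridges the trace-level generator to the tracking/colocalization
#' stages without image rendering: the mRNA channel yields one track per
#' molecule at its (jittered) true positions; the protein and
#' translation-site channels yield one track per run of frames whose
#' noisy trace exceeds `threshold` (a frame-level detection), positioned
#' at the mRNA location plus localization jitter.
#'
#' @param cohort a `binding_cohort` or `runoff_cohort`.
#' @param threshold frame-level detection threshold, intensity units.
#' @param jitter_sd localization error SD in pixels.
#' @param seed integer seed for the jitter.
#' @return data.frame with columns `track_id`, `channel`, `cell`, `frame`
#'   (0-based), `t_s`, `x`, `y`, `intensity`, `truth_mrna`.
#' @export
cohort_to_tracks <- function(cohort, threshold = 0.5, jitter_sd = 0.05,
                             seed = 1L) {
  set.seed(derive_seed(seed, 3L))
  nf <- length(cohort$times)
  is_runoff <- inherits(cohort, "runoff_cohort")
  n <- if (is_runoff) nrow(cohort$truth) else nrow(cohort$truth$mrna)
  cells <- if (is_runoff) rep(1L, n) else cohort$truth$mrna$cell
  xs <- if (is_runoff) matrix(rep(seq_len(n) * 6, each = nf), nf, n)
        else cohort$x
  ys <- if (is_runoff) matrix(8, nf, n) else cohort$y

  out <- vector("list", 3L * n)
  k <- 0L
  next_id <- 1L
  emit <- function(channel, mrna_i, frames) {
    if (length(frames) == 0L) return(invisible(NULL))
    k <<- k + 1L
    out[[k]] <<- data.frame(
      track_id = next_id, channel = channel, cell = cells[mrna_i],
      frame = frames - 1L, t_s = cohort$times[frames],
      x = xs[frames, mrna_i] + stats::rnorm(length(frames), 0, jitter_sd),
      y = ys[frames, mrna_i] + stats::rnorm(length(frames), 0, jitter_sd),
      intensity = switch(channel,
        mrna = cohort$mrna[frames, mrna_i],
        protein = cohort$protein[frames, mrna_i],
        tls = cohort$tls[frames, mrna_i]),
      truth_mrna = mrna_i)
    next_id <<- next_id + 1L
    invisible(NULL)
  }
  for (i in seq_len(n)) {
    emit("mrna", i, which(cohort$mrna[, i] > threshold))
    for (ch in c("protein", "tls")) {
      tr <- cohort[[ch]]
      if (is.null(tr)) next
      runs <- true_runs(tr[, i] > threshold)
      for (r in seq_len(nrow(runs))) {
        emit(ch, i, seq.int(runs$start[r], runs$end[r]))
      }
    }
  }
  do.call(rbind, out[seq_len(k)])
}
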