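#' Kinetic preset describing protein binding to a tethered mRNA
#'
#' A kinetic preset bundles the ground-truth parameters from which the
#' synthetic generator draws binding episodes. Two episode models are
#' supported:
#'
#' * `"renewal"` — each binding site alternates between unbound and bound
#'   states as a two-state continuous-time Markov chain with per-site
#'   binding-initiation rate `duty_or_kon` (1/s) and exponentially
#'   distributed on-times with mean `mean_on_s`. This is the model for the
#'   PP7 coat-protein calibration constructs (1x/3x/12x binding sites).
#' * `"episode"` — an engaged mRNA receives a single recruitment episode
#'   that is persistent (lasts past the observation window) with
#'   probability `persistent_frac`, otherwise transient with mean duration
#'   `transient_mean_min` minutes. This is the model for ZNF598
#'   recruitment to reporter mRNAs.
#'
#' Engagement, the probability that an mRNA ever shows a *detectable*
#' colocalization (a run of at least `qual_frames` consecutive bound
#' frames), is controlled in one of two ways:
#'
#' * `engagement = "kinetic"` — every mRNA runs the renewal kinetics and
#'   `duty_or_kon` is calibrated (see [calibrate_kon()]) so that the
#'   expected engaged fraction equals `p_engaged`. Episode durations stay
#'   exactly exponential, so dwell-time statistics are unbiased.
#' * `engagement = "gated"` — a Bernoulli(`p_engaged`) gate decides
#'   whether an mRNA binds at all; engaged mRNAs are guaranteed at least
#'   one qualifying episode.
#'
#' @param name label.
#' @param p_engaged probability in \[0,1\] that an mRNA shows at least one
#'   qualifying recruitment during the observation window.
#' @param n_sites integer >= 0, binding sites per mRNA.
#' @param mean_on_s mean exponential on-time in seconds (single-site
#'   binding), required when `n_sites > 0` and `model = "renewal"`.
#' @param duty_or_kon per-site binding-initiation rate (1/s); `NA` requests
#'   calibration at simulation time for `engagement = "kinetic"`.
#' @param persistent_frac probability a recruitment episode outlasts the
#'   window (`model = "episode"` only).
#' @param transient_mean_min mean duration, in minutes, of non-persistent
#'   recruitment episodes (includes the qualification time).
#' @param label_eff probability that a binder is fluorescently labeled.
#' @param model `"renewal"` or `"episode"` (see above).
#' @param engagement `"kinetic"` or `"gated"` (see above).
#' @param qual_frames consecutive bound frames that make an engagement
#'   detectable under the steady-state colocalization rule.
#' @param translating_frac fraction of mRNAs that are translating; only
#'   translating mRNAs can recruit under the `"episode"` model.
#' @return an object of class `kinetic_preset`.
#' @seealso [preset_kinetic()] for the built-in presets,
#'   [simulate_binding_cohort()].
#' @export
kinetic_preset <- function(name,
                           p_engaged,
                           n_sites,
                           mean_on_s = NA_real_,
                           duty_or_kon = NA_real_,
                           persistent_frac = 0,
                           transient_mean_min = NA_real_,
                           label_eff = 1,
                           model = c("renewal", "episode"),
                           engagement = c("gated", "kinetic"),
                           qual_frames = 5L,
                           translating_frac = 1) {
  model <- match.arg(model)
  engagement <- match.arg(engagement)
  assert_prob(p_engaged, "p_engaged")
  n_sites <- assert_count(n_sites, "n_sites")
  assert_prob(persistent_frac, "persistent_frac")
  assert_prob(label_eff, "label_eff")
  assert_prob(translating_frac, "translating_frac")
  qual_frames <- assert_count(qual_frames, "qual_frames", min = 1L)
  if (n_sites > 0L && model == "renewal") {
    assert_pos(mean_on_s, "mean_on_s")
  }
  if (model == "episode" && persistent_frac < 1) {
    assert_pos(transient_mean_min, "transient_mean_min")
  }
  if (!is.na(duty_or_kon)) assert_pos(duty_or_kon, "duty_or_kon",
                                      strict = FALSE)
  structure(
    list(name = name, p_engaged = p_engaged, n_sites = n_sites,
         mean_on_s = mean_on_s, duty_or_kon = duty_or_kon,
         persistent_frac = persistent_frac,
         transient_mean_min = transient_mean_min,
         label_eff = label_eff, model = model, engagement = engagement,
         qual_frames = qual_frames, translating_frac = translating_frac),
    class = "kinetic_preset"
  )
}

#' @export
print.kinetic_preset <- function(x, ...) {
  cat("<kinetic_preset>", x$name, "\n")
  cat("  model:", x$model, "| engagement:", x$engagement,
      "| p_engaged:", x$p_engaged, "| sites:", x$n_sites, "\n")
  if (x$model == "renewal" && x$n_sites > 0L) {
    cat("  mean on-time:", x$mean_on_s, "s | k_on/site:",
        if (is.na(x$duty_or_kon)) "(calibrated at run time)"
        else signif(x$duty_or_kon, 4), "\n")
  }
  if (x$model == "episode") {
    cat("  persistent fraction:", x$persistent_frac,
        "| transient mean:", x$transient_mean_min, "min\n")
  }
  invisible(x)
}

#' Built-in kinetic presets
#'
#' Ground-truth presets mirroring the experimental conditions the package
#' analyzes:
#'
#' * `"pbs_0x"` — no binding sites (negative control).
#' * `"pbs_1x"` — single PP7 binding site; exponential on-times with mean
#'   3.6 s and a calibrated per-site on-rate such that half of the mRNAs
#'   show a qualifying colocalization in a 5-min movie at 2-s frames.
#' * `"pbs_3x"`, `"pbs_12x"` — 3 and 12 binding sites, engagement gated at
#'   0.8 and 0.95 respectively.
#' * `"polyA60_znf"` — ZNF598 recruitment to a stall reporter: engagement
#'   0.8, recruitment episodes persistent with probability 0.5, transient
#'   episodes with mean 3.5 min.
#' * `"noinsert_znf"` — ZNF598 recruitment to a normal message: as above
#'   with engagement 0.1.
#'
#' @param name preset name (see Details).
#' @return a [kinetic_preset()] object.
#' @export
preset_kinetic <- function(name = c("pbs_0x", "pbs_1x", "pbs_3x", "pbs_12x",
                                    "polyA60_znf", "noinsert_znf")) {
  name <- match.arg(name)
  switch(name,
    pbs_0x = kinetic_preset("pbs_0x", p_engaged = 0, n_sites = 0L,
                            mean_on_s = 3.6, duty_or_kon = 0),
    pbs_1x = kinetic_preset("pbs_1x", p_engaged = 0.5, n_sites = 1L,
                            mean_on_s = 3.6, engagement = "kinetic"),
    pbs_3x = kinetic_preset("pbs_3x", p_engaged = 0.8, n_sites = 3L,
                            mean_on_s = 3.6, engagement = "gated"),
    pbs_12x = kinetic_preset("pbs_12x", p_engaged = 0.95, n_sites = 12L,
                             mean_on_s = 3.6, engagement = "gated"),
    polyA60_znf = kinetic_preset("polyA60_znf", p_engaged = 0.8,
                                 n_sites = 1L, model = "episode",
                                 persistent_frac = 0.5,
                                 transient_mean_min = 3.5),
    noinsert_znf = kinetic_preset("noinsert_znf", p_engaged = 0.1,
                                  n_sites = 1L, model = "episode",
                                  persistent_frac = 0.5,
                                  transient_mean_min = 3.5)
  )
}

#' Frame-sampled engagement probability of a two-state binder
#'
#' Exact probability that a single-site binder, alternating between
#' unbound and bound states with rates `kon` (1/s) and `1/mean_on_s`,
#' shows at least one run of `qual_frames` consecutive bound frames when
#' the state is sampled every `dt_s` seconds over `n_frames` frames.
#' Computed by dynamic programming on the sampled (discrete-time) Markov
#' chain, starting from the stationary distribution; the sampled chain
#' automatically accounts for unbinding-and-rebinding between frames.
#'
#' @param kon per-site binding-initiation rate (1/s).
#' @param mean_on_s mean on-time (s).
#' @param n_frames number of sampled frames.
#' @param dt_s frame interval (s).
#' @param qual_frames run length that counts as an engagement.
#' @return probability in \[0, 1\].
#' @export
engagement_probability <- function(kon, mean_on_s, n_frames, dt_s,
                                   qual_frames = 5L) {
  assert_pos(kon, "kon", strict = FALSE)
  assert_pos(mean_on_s, "mean_on_s")
  n_frames <- assert_count(n_frames, "n_frames", min = 1L)
  qual_frames <- assert_count(qual_frames, "qual_frames", min = 1L)
  if (kon == 0) return(0)
  koff <- 1 / mean_on_s
  s <- kon + koff
  pi_on <- kon / s
  e <- exp(-s * dt_s)
  p_oo <- pi_on + (1 - pi_on) * e   # bound -> bound over one frame
  p_fo <- pi_on * (1 - e)           # unbound -> bound over one frame
  ## DP states: current on-run length r = 0 (off) .. k-1, plus an
  ## absorbing "engaged" mass once a run reaches k frames.
  k <- qual_frames
  prob <- numeric(k)                # index r+1 holds P(run length == r)
  absorbed <- 0
  ## stationary start at the first frame
  if (k == 1L) {
    absorbed <- pi_on
    prob[1L] <- 1 - pi_on
  } else {
    prob[1L] <- 1 - pi_on
    prob[2L] <- pi_on
  }
  if (n_frames > 1L) {
    for (i in 2L:n_frames) {
      new <- numeric(k)
      on_mass <- if (k > 1L) sum(prob[2L:k]) else 0
      ## fall back to off
      new[1L] <- prob[1L] * (1 - p_fo) + on_mass * (1 - p_oo)
      ## off -> start a run of 1
      start <- prob[1L] * p_fo
      if (k == 1L) absorbed <- absorbed + start else new[2L] <- start
      ## extend runs r -> r + 1
      if (k > 1L) {
        for (r in 1L:(k - 1L)) {
          moved <- prob[r + 1L] * p_oo
          if (r + 1L == k) absorbed <- absorbed + moved
          else new[r + 2L] <- new[r + 2L] + moved
        }
      }
      prob <- new
    }
  }
  absorbed
}

#' Calibrate the per-site on-rate for a target engaged fraction
#'
#' Solves for the binding-initiation rate at which
#' [engagement_probability()] equals `target`. Used by the `pbs_1x` preset
#' so that the engaged fraction measured by the colocalization rules
#' recovers `p_engaged` without conditioning the episode durations.
#'
#' @param mean_on_s mean on-time (s).
#' @param target desired engaged fraction in (0, 1).
#' @param window_s observation window (s).
#' @param dt_s frame interval (s).
#' @param qual_frames qualifying run length in frames.
#' @return calibrated rate (1/s).
#' @export
calibrate_kon <- function(mean_on_s, target, window_s, dt_s,
                          qual_frames = 5L) {
  assert_prob(target, "target")
  if (target <= 0 || target >= 1) {
    stop_validation("target must be strictly inside (0, 1)")
  }
  n_frames <- floor(window_s / dt_s) + 1L
  f <- function(k) {
    engagement_probability(k, mean_on_s, n_frames, dt_s, qual_frames) - target
  }
  stats::uniroot(f, lower = 1e-6, upper = 10, tol = 1e-10)$root
}

#' Runoff preset describing ribosome clearance after initiation block
#'
#' Parameters for simulating translation-site intensity decay after a
#' harringtonine-type block of initiation. Per-mRNA clearance times are
#' drawn from `baseline` (a lognormal specification) multiplied by
#' `clearance_scale`; a `damaged_frac` subpopulation never clears
#' (runoff-resistant), and a fraction `znf_on_damaged` of those carry a
#' persistent protein (ZNF598) signal.
#'
#' @param name label.
#' @param clearance_scale multiplicative factor on the baseline
#'   clearance-time distribution (dimensionless, > 0).
#' @param damaged_frac probability an mRNA is runoff-resistant.
#' @param znf_on_damaged probability a damaged mRNA carries protein signal.
#' @param baseline list with `meanlog`, `sdlog` of the lognormal baseline
#'   clearance-time distribution in seconds.
#' @param hold_max_s the translation-site signal holds its plateau for a
#'   uniform 0..`hold_max_s` seconds before the linear runoff ramp
#'   starts. Kept below one frame interval by default: once initiation
#'   is blocked, elongating ribosomes start leaving immediately, and a
#'   longer hold would decouple the signal maximum (where clearance is
#'   measured from) from the ramp start (where the truth defines it).
#' @return object of class `runoff_preset`.
#' @export
runoff_preset <- function(name, clearance_scale = 1, damaged_frac = 0,
                          znf_on_damaged = 0,
                          baseline = list(meanlog = log(240), sdlog = 0.35),
                          hold_max_s = 10) {
  assert_pos(clearance_scale, "clearance_scale")
  assert_prob(damaged_frac, "damaged_frac")
  assert_prob(znf_on_damaged, "znf_on_damaged")
  assert_pos(hold_max_s, "hold_max_s", strict = FALSE)
  if (!is.list(baseline) || is.null(baseline$meanlog) ||
      is.null(baseline$sdlog) || baseline$sdlog <= 0) {
    stop_validation("baseline must be list(meanlog=, sdlog=) with sdlog > 0")
  }
  structure(
    list(name = name, clearance_scale = clearance_scale,
         damaged_frac = damaged_frac, znf_on_damaged = znf_on_damaged,
         baseline = baseline, hold_max_s = hold_max_s,
         ramp_model = "linear"),
    class = "runoff_preset"
  )
}

#' Built-in runoff presets
#'
#' * `"runoff_wt"` — wild-type clearance (scale 1, no damaged fraction).
#' * `"runoff_oe"` — ZNF598 overexpression: clearance 1.5x faster
#'   (scale 1/1.5).
#' * `"runoff_damaged"` — normal-message cohort with a 10% runoff-resistant
#'   (damaged) subpopulation, half of which carry persistent protein signal.
#'
#' @param name preset name.
#' @return a [runoff_preset()] object.
#' @export
preset_runoff <- function(name = c("runoff_wt", "runoff_oe",
                                   "runoff_damaged")) {
  name <- match.arg(name)
  switch(name,
    runoff_wt = runoff_preset("runoff_wt"),
    runoff_oe = runoff_preset("runoff_oe", clearance_scale = 1 / 1.5),
    runoff_damaged = runoff_preset("runoff_damaged", damaged_frac = 0.1,
                                   znf_on_damaged = 0.5)
  )
}

#' Rendering configuration for the synthetic movie generator
#'
#' Spatial/temporal calibration and camera model used by [render_movie()]
#' and [simulate_smfish_field()]. Defaults mirror the live-cell TIRF
#' acquisition settings of the assays the package emulates (160 nm pixels,
#' 2-s frames for steady state).
#'
#' @param pixel_size_nm lateral pixel size (nm).
#' @param frame_interval_s time between frames (s).
#' @param n_frames frames per movie.
#' @param field_px square field width/height in pixels.
#' @param psf_sigma_px lateral PSF standard deviation (px, >= 0.5).
#' @param psf_sigma_z_px axial PSF standard deviation (z-planes), for 3D.
#' @param n_z number of z-planes (1 for 2D time lapse).
#' @param photons_per_unit expected photons for one intensity unit.
#' @param background_mean mean background (counts).
#' @param read_noise_sd Gaussian read noise SD (counts).
#' @param diffusion_coeff lateral mRNA wander (um^2/s, confined).
#' @param seed integer seed for rendering noise.
#' @param noise logical; `FALSE` renders expected photon counts only.
#' @return object of class `render_config`.
#' @export
render_config <- function(pixel_size_nm = 160, frame_interval_s = 2,
                          n_frames = 151L, field_px = 64L,
                          psf_sigma_px = 1.3, psf_sigma_z_px = 1.2,
                          n_z = 1L, photons_per_unit = 300,
                          background_mean = 10, read_noise_sd = 2,
                          diffusion_coeff = 0.002, seed = 1L,
                          noise = TRUE) {
  assert_pos(pixel_size_nm, "pixel_size_nm")
  assert_pos(frame_interval_s, "frame_interval_s")
  n_frames <- assert_count(n_frames, "n_frames", min = 1L)
  field_px <- assert_count(field_px, "field_px", min = 8L)
  assert_pos(psf_sigma_px, "psf_sigma_px")
  if (psf_sigma_px < 0.5) {
    stop_validation("psf_sigma_px must be >= 0.5 (sampling requirement)")
  }
  assert_pos(psf_sigma_z_px, "psf_sigma_z_px")
  n_z <- assert_count(n_z, "n_z", min = 1L)
  assert_pos(photons_per_unit, "photons_per_unit")
  assert_pos(background_mean, "background_mean", strict = FALSE)
  assert_pos(read_noise_sd, "read_noise_sd", strict = FALSE)
  assert_pos(diffusion_coeff, "diffusion_coeff", strict = FALSE)
  structure(
    list(pixel_size_nm = pixel_size_nm, frame_interval_s = frame_interval_s,
         n_frames = n_frames, field_px = field_px,
         psf_sigma_px = psf_sigma_px, psf_sigma_z_px = psf_sigma_z_px,
         n_z = n_z, photons_per_unit = photons_per_unit,
         background_mean = background_mean, read_noise_sd = read_noise_sd,
         diffusion_coeff = diffusion_coeff, seed = as.integer(seed),
         noise = isTRUE(noise)),
    class = "render_config"
  )
}
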