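## End-to-end orchestration: declarative run configuration, stage
## execution with standardized file contracts, and reporting.

default_run_config <- function() {
  list(
    mode = "steady_state",
    seed = 1L,
    out_dir = "smtrack_run",
    simulate = list(
      preset = "pbs_1x",
      n_mrna = 100L,
      n_cells = 4L,
      window_s = 300,
      dt_s = 2,
      noise_sd = 0.1),
    runoff = list(
      preset = "runoff_wt",
      n_mrna = 150L,
      window_s = 1800,
      dt_s = 10,
      noise_sd = 0.05),
    smfish = list(
      n_single = 60L,
      n_tls = 40L,
      nap_mean = 40.3,
      nap_shape = 4,
      n_cells = 2L,
      field_px = 128L,
      n_z = 9L,
      photons_per_unit = 2000),
    rules = list(
      max_dist_px = 1.5,
      min_cell_mrna = 15L,
      min_cell_translating = 10L),
    tracking = list(
      max_disp_px = 3,
      max_gap_frames = 1L,
      min_len_mrna = 25L,
      min_len_protein = 4L,
      min_duration_s = 120,
      crossing_radius_px = 2.6),
    segmentation = list(
      alpha = 0.01,
      min_bound_s = 8,
      level_threshold = 0.5),
    render = list(
      enabled = FALSE,
      field_px = 64L,
      photons_per_unit = 300,
      background_mean = 10,
      read_noise_sd = 2,
      psf_sigma_px = 1.3)
  )
}

## Recursively overlay user values onto defaults; unknown keys error.
merge_config <- function(defaults, user, path = "") {
  for (key in names(user)) {
    full <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(defaults)) {
      stop_validation("unknown config key: ", full)
    }
    if (is.list(defaults[[key]]) && is.list(user[[key]])) {
      defaults[[key]] <- merge_config(defaults[[key]], user[[key]], full)
    } else {
      defaults[[key]] <- user[[key]]
    }
  }
  defaults
}

#' Load and resolve a pipeline run configuration
#'
#' Reads a YAML configuration, validates it against the known schema
#' (unknown keys are rejected) and fills every default explicitly, so
#' the resolved configuration is self-describing and round-trips
#' losslessly.
#'
#' @param path YAML file, or a list already in config shape.
#' @return resolved configuration list with a `config_hash` attribute.
#' @export
load_run_config <- function(path) {
  user <- if (is.character(path)) yaml::read_yaml(path) else path
  if (!is.list(user)) stop_validation("config must be a YAML mapping")
  cfg <- merge_config(default_run_config(), user)
  if (!cfg$mode %in% c("steady_state", "runoff", "smfish", "simulate")) {
    stop_validation("mode must be steady_state, runoff, smfish or simulate")
  }
  attr(cfg, "config_hash") <- config_hash(cfg)
  cfg
}

write_stage_csv <- function(df, dir, name) {
  utils::write.csv(df, file.path(dir, name), row.names = FALSE)
}

#' Write an image stack to TIFF
#'
#' One multi-page 16-bit TIFF per channel. Counts are quantized the way
#' a camera digitizer would: rounded to integers and clipped to
#' \[0, `scale`\] (the rare sub-zero read-noise excursions clip to 0).
#' A JSON sidecar records the rendering configuration and the scale.
#'
#' @param stack an `image_stack` from [render_movie()].
#' @param dir output directory.
#' @param prefix file-name prefix.
#' @param scale full-scale count (65535 for 16-bit).
#' @return invisibly, the written file paths.
#' @export
write_stack_tiff <- function(stack, dir, prefix = "movie",
                             scale = 65535) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  for (ch in names(stack$channels)) {
    a <- pmin(pmax(round(stack$channels[[ch]]), 0), scale) / scale
    pages <- lapply(seq_len(dim(a)[3L]), function(f) a[, , f])
    p <- file.path(dir, paste0(prefix, "_", ch, ".tif"))
    tiff::writeTIFF(pages, p, bits.per.sample = 16L, reduce = FALSE)
    paths <- c(paths, p)
  }
  side <- file.path(dir, paste0(prefix, "_config.json"))
  jsonlite::write_json(c(unclass(stack$cfg), list(tiff_scale = scale)),
                       side, auto_unbox = TRUE, digits = NA)
  invisible(c(paths, side))
}

#' Read a multi-page TIFF stack
#'
#' @param path TIFF file written by [write_stack_tiff()].
#' @param scale full-scale count (must match the writing scale; see the
#'   JSON sidecar).
#' @return 3D array `[y, x, frame]` in integer camera counts.
#' @export
read_stack_tiff <- function(path, scale = 65535) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  round(array(unlist(pages),
              dim = c(dim(pages[[1L]]), length(pages))) * scale)
}

#' Run the analysis pipeline for one configuration
#'
#' Executes the stage chain for the configured mode on synthetic input
#' generated from the configured presets:
#' `steady_state`: simulate, build/filter tracks, associate channels,
#' call colocalization, segment protein traces (cells.csv, linked.csv,
#' tracks.csv, segments.csv, residence.csv); `runoff`: simulate, extract
#' clearance times, Kaplan-Meier curve (clearance.csv, survival.csv);
#' `smfish`: simulate a field, quantify NAP counts (tls.csv,
#' cells_fish.csv); `simulate`: render and write TIFF stacks plus the
#' ground-truth table. Every output directory carries a `run_info.json`
#' with the resolved config and its hash; identical configurations
#' reproduce identical outputs.
#'
#' @param config path to a YAML config or a config list
#'   (see [load_run_config()]).
#' @return invisibly, a result bundle (list) with the stage outputs and
#'   `out_dir`.
#' @export
run_pipeline <- function(config) {
  cfg <- load_run_config(config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- list(config = cfg, out_dir = cfg$out_dir,
                 config_hash = attr(cfg, "config_hash"))

  if (cfg$mode %in% c("steady_state", "simulate")) {
    preset <- preset_kinetic(cfg$simulate$preset)
    cohort <- simulate_binding_cohort(
      preset, cfg$simulate$n_mrna, cfg$simulate$window_s,
      cfg$simulate$dt_s, seed = cfg$seed,
      noise_sd = cfg$simulate$noise_sd, n_cells = cfg$simulate$n_cells)
    bundle$cohort <- cohort
    if (cfg$mode == "simulate") {
      rc <- render_config(
        frame_interval_s = cfg$simulate$dt_s,
        n_frames = length(cohort$times),
        field_px = max(cfg$render$field_px, cohort$field_px),
        photons_per_unit = cfg$render$photons_per_unit,
        background_mean = cfg$render$background_mean,
        read_noise_sd = cfg$render$read_noise_sd,
        psf_sigma_px = cfg$render$psf_sigma_px,
        seed = cfg$seed)
      stack <- render_movie(cohort, rc)
      write_stack_tiff(stack, cfg$out_dir)
      gt <- cohort$truth$episodes
      write_stage_csv(gt, cfg$out_dir, "ground_truth_episodes.csv")
      write_stage_csv(cohort$truth$mrna, cfg$out_dir,
                      "ground_truth_mrna.csv")
      bundle$stack <- stack
    } else {
      rules <- link_rules("steady_state",
                          max_dist_px = cfg$rules$max_dist_px,
                          min_cell_mrna = cfg$rules$min_cell_mrna,
                          min_cell_translating =
                            cfg$rules$min_cell_translating)
      params <- link_params(
        max_disp_px = cfg$tracking$max_disp_px,
        max_gap_frames = cfg$tracking$max_gap_frames,
        min_len_mrna = cfg$tracking$min_len_mrna,
        min_len_protein = cfg$tracking$min_len_protein,
        min_duration_s = cfg$tracking$min_duration_s,
        crossing_radius_px = cfg$tracking$crossing_radius_px,
        frame_interval_s = cfg$simulate$dt_s)
      ana <- analyze_binding_cohort(cohort, rules, params,
                                    seed = cfg$seed)
      seg <- segment_binding_cohort(
        cohort, alpha = cfg$segmentation$alpha,
        min_bound_s = cfg$segmentation$min_bound_s,
        level_threshold = cfg$segmentation$level_threshold)
      ## residence times need every on-run, not only 8-s bound states
      seg_all <- segment_binding_cohort(
        cohort, alpha = cfg$segmentation$alpha, min_bound_s = 0,
        level_threshold = cfg$segmentation$level_threshold)
      rts <- residence_time_stats(seg_all$segments, cohort$dt_s,
                                  policy = "markov",
                                  total_frames = seg_all$total_frames,
                                  n_traces = seg_all$n_traces)
      write_stage_csv(ana$tracks, cfg$out_dir, "tracks.csv")
      write_stage_csv(ana$records$links, cfg$out_dir, "linked.csv")
      write_stage_csv(ana$cells, cfg$out_dir, "cells.csv")
      write_stage_csv(seg$segments, cfg$out_dir, "segments.csv")
      write_stage_csv(
        data.frame(policy = rts$policy, mean_on_s = rts$mean_s,
                   n_segments = rts$n, n_censored = rts$n_censored),
        cfg$out_dir, "residence.csv")
      bundle$analysis <- ana
      bundle$segments <- seg
      bundle$residence <- rts
    }
  } else if (cfg$mode == "runoff") {
    preset <- preset_runoff(cfg$runoff$preset)
    cohort <- simulate_runoff_cohort(
      preset, cfg$runoff$n_mrna, cfg$runoff$dt_s, cfg$runoff$window_s,
      seed = cfg$seed, noise_sd = cfg$runoff$noise_sd)
    cl <- clearance_cohort(cohort)
    ok <- cl[!cl$excluded, , drop = FALSE]
    curve <- km_greenwood(ok$clearance_s, ok$censored)
    write_stage_csv(cl, cfg$out_dir, "clearance.csv")
    write_stage_csv(as.data.frame(curve), cfg$out_dir, "survival.csv")
    bundle$cohort <- cohort
    bundle$clearance <- cl
    bundle$curve <- curve
  } else if (cfg$mode == "smfish") {
    sm <- cfg$smfish
    set.seed(derive_seed(cfg$seed, 6L))
    naps <- stats::rgamma(sm$n_tls, shape = sm$nap_shape,
                          scale = sm$nap_mean / sm$nap_shape)
    rc <- render_config(field_px = sm$field_px, n_z = sm$n_z,
                        photons_per_unit = sm$photons_per_unit,
                        seed = cfg$seed)
    field <- simulate_smfish_field(sm$n_single, naps, rc,
                                   seed = cfg$seed, n_cells = sm$n_cells)
    res <- analyze_smfish_field(field)
    write_stage_csv(res$tls, cfg$out_dir, "tls.csv")
    write_stage_csv(res$units, cfg$out_dir, "cells_fish.csv")
    bundle$field <- field
    bundle$smfish <- res
  }

  jsonlite::write_json(
    list(config = cfg, config_hash = attr(cfg, "config_hash"),
         mode = cfg$mode,
         package_version = as.character(utils::packageVersion("smtrack"))),
    file.path(cfg$out_dir, "run_info.json"), auto_unbox = TRUE,
    digits = NA)
  invisible(bundle)
}

#' Summarize a result bundle into tables and figures
#'
#' Re-exposes (never recomputes) the stage outputs: per-cell
#' colocalization fractions, residence-time summary, survival curve with
#' Greenwood confidence band, NAP-count distribution. When `pdf_file` is
#' given, base-graphics figures are written there.
#'
#' @param bundle result of [run_pipeline()].
#' @param pdf_file optional path for a PDF report.
#' @return list of summary tables (possibly empty, with a warning field
#'   when the bundle holds no results).
#' @export
make_report <- function(bundle, pdf_file = NULL) {
  out <- list(mode = bundle$config$mode,
              config_hash = bundle$config_hash)
  if (!is.null(pdf_file)) {
    grDevices::pdf(pdf_file, width = 6, height = 5)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  drew <- FALSE
  if (!is.null(bundle$analysis)) {
    out$cells <- bundle$analysis$cells
    out$grand_mean_frac <- bundle$analysis$grand_mean_frac
    if (!is.null(pdf_file) && nrow(out$cells)) {
      graphics::stripchart(out$cells$frac_coloc, vertical = TRUE,
                           method = "jitter", pch = 16,
                           ylab = "fraction colocalized / cell",
                           main = "Per-cell colocalization")
      drew <- TRUE
    }
  }
  if (!is.null(bundle$residence)) {
    out$residence <- data.frame(policy = bundle$residence$policy,
                                mean_on_s = bundle$residence$mean_s,
                                n = bundle$residence$n)
  }
  if (!is.null(bundle$curve)) {
    out$survival <- as.data.frame(bundle$curve)
    out$median_s <- km_median(bundle$curve)
    if (!is.null(pdf_file) && nrow(out$survival)) {
      cu <- out$survival
      graphics::plot(stats::stepfun(cu$time, c(1, cu$surv)),
                     do.points = FALSE, xlab = "time (s)",
                     ylab = "S(t)", main = "Translation-site survival",
                     ylim = c(0, 1))
      graphics::lines(stats::stepfun(cu$time, c(1, cu$lower)),
                      do.points = FALSE, lty = 2)
      graphics::lines(stats::stepfun(cu$time, c(1, cu$upper)),
                      do.points = FALSE, lty = 2)
      drew <- TRUE
    }
  }
  if (!is.null(bundle$smfish)) {
    naps <- bundle$smfish$tls$nap_count
    out$nap_summary <- data.frame(
      n_tls = length(naps), mean_nap = mean(naps, na.rm = TRUE),
      median_nap = stats::median(naps, na.rm = TRUE))
    if (!is.null(pdf_file) && length(stats::na.omit(naps))) {
      graphics::hist(naps, breaks = 30, main = "NAP counts",
                     xlab = "nascent peptides / site")
      drew <- TRUE
    }
  }
  if (length(out) == 2L) {
    out$warning <- "empty result bundle: nothing to report"
    warning(out$warning)
  }
  out
}
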