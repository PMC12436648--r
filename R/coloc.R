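## Two-channel track association, colocalization calls and per-cell
## engagement fractions.

#' Track-linkage and colocalization rules
#'
#' Defaults follow the analysis mode: steady-state imaging (2-s frames)
#' requires a temporal overlap of at least 4 frames to link tracks and at
#' least 5 consecutive within-radius frames (~10 s) to call a
#' colocalization; harringtonine-runoff and UV assays (10-s frames)
#' require 2 frames for both. Cell eligibility likewise follows the
#' reported rules: steady-state calibration assays require more than
#' `min_cell_mrna` mRNAs per cell; recruitment assays require more than
#' `min_cell_translating` translating mRNAs.
#'
#' @param mode `"steady_state"` or `"runoff_uv"`.
#' @param max_dist_px spatial association radius (px).
#' @param min_overlap_frames_link frames within radius required to link.
#' @param min_consec_frames_coloc consecutive within-radius frames that
#'   constitute a colocalization event.
#' @param min_cell_mrna cell eligibility: more than this many mRNAs.
#' @param min_cell_translating cell eligibility: more than this many
#'   translating mRNAs (used when `eligibility = "translating_count"`).
#' @param eligibility which cell-eligibility rule applies.
#' @param coloc_window_s colocalization events are only scored within
#'   this much time from acquisition start (5 min for steady state).
#' @return list of class `link_rules`.
#' @export
link_rules <- function(mode = c("steady_state", "runoff_uv"),
                       max_dist_px = 1.5,
                       min_overlap_frames_link = NULL,
                       min_consec_frames_coloc = NULL,
                       min_cell_mrna = 15L,
                       min_cell_translating = 10L,
                       eligibility = c("mrna_count", "translating_count"),
                       coloc_window_s = NULL) {
  mode <- match.arg(mode)
  eligibility <- match.arg(eligibility)
  defaults <- if (mode == "steady_state") {
    list(link = 4L, coloc = 5L, window = 300)
  } else {
    list(link = 2L, coloc = 2L, window = Inf)
  }
  min_overlap_frames_link <- as.integer(min_overlap_frames_link %||%
                                          defaults$link)
  min_consec_frames_coloc <- as.integer(min_consec_frames_coloc %||%
                                          defaults$coloc)
  coloc_window_s <- coloc_window_s %||% defaults$window
  assert_pos(max_dist_px, "max_dist_px")
  if (min_consec_frames_coloc < 1L) {
    stop_validation("min_consec_frames_coloc must be >= 1")
  }
  structure(list(mode = mode, max_dist_px = max_dist_px,
                 min_overlap_frames_link = min_overlap_frames_link,
                 min_consec_frames_coloc = min_consec_frames_coloc,
                 min_cell_mrna = as.integer(min_cell_mrna),
                 min_cell_translating = as.integer(min_cell_translating),
                 eligibility = eligibility,
                 coloc_window_s = coloc_window_s),
            class = "link_rules")
}

#' Associate protein / translation-site tracks to mRNA tracks
#'
#' A candidate pair qualifies when, over the temporal intersection of the
#' two tracks, the per-frame distance is within `max_dist_px` for at
#' least `min_overlap_frames_link` frames. Each non-mRNA track is
#' assigned to at most one mRNA: the qualifying mRNA with the smallest
#' time-averaged distance (ties broken by the lower mRNA track id).
#'
#' @param tracks data.frame from the tracking stage (columns `track_id`,
#'   `channel`, `frame`, `t_s`, `x`, `y`, optionally `cell`, `status`).
#'   Discarded tracks (`status != "kept"`) are ignored.
#' @param rules a [link_rules()] list.
#' @return object of class `linked_records`: list with `mrna` (per-mRNA
#'   table), `links` (association table), and `within` (per-link logical
#'   series of within-radius frames over the overlap, gaps broken).
#' @export
associate_tracks <- function(tracks, rules = link_rules()) {
  if (!is.null(tracks$status)) {
    tracks <- tracks[tracks$status == "kept", , drop = FALSE]
  }
  if (is.null(tracks$cell)) tracks$cell <- 1L
  m <- tracks[tracks$channel == "mrna", , drop = FALSE]
  o <- tracks[tracks$channel != "mrna", , drop = FALSE]
  mrna_ids <- unique(m$track_id)
  mrna_tbl <- data.frame(
    mrna_track = mrna_ids,
    cell = m$cell[match(mrna_ids, m$track_id)])
  if (!is.null(m$truth_mrna)) {
    mrna_tbl$truth_mrna <- m$truth_mrna[match(mrna_ids, m$track_id)]
  }
  links <- NULL
  within_list <- list()
  if (nrow(o) > 0L && length(mrna_ids) > 0L) {
    m_by <- split(m[, c("frame", "t_s", "x", "y")],
                  factor(m$track_id, mrna_ids))
    mcx <- vapply(m_by, function(d) mean(d$x), 0)
    mcy <- vapply(m_by, function(d) mean(d$y), 0)
    mex <- vapply(m_by, function(d)
      max(sqrt((d$x - mean(d$x))^2 + (d$y - mean(d$y))^2)), 0)
    other_ids <- unique(o$track_id)
    o_by <- split(o[, c("frame", "t_s", "x", "y", "channel")],
                  factor(o$track_id, other_ids))
    rows <- list()
    k <- 0L
    for (oi in seq_along(other_ids)) {
      od <- o_by[[oi]]
      ocx <- mean(od$x); ocy <- mean(od$y)
      oex <- max(sqrt((od$x - ocx)^2 + (od$y - ocy)^2))
      cand <- which(sqrt((mcx - ocx)^2 + (mcy - ocy)^2) -
                      mex - oex <= rules$max_dist_px)
      best <- NULL
      for (mi in cand) {
        md <- m_by[[mi]]
        common <- intersect(md$frame, od$frame)
        if (length(common) < rules$min_overlap_frames_link) next
        common <- sort(common)
        im <- match(common, md$frame)
        io <- match(common, od$frame)
        d <- sqrt((md$x[im] - od$x[io])^2 + (md$y[im] - od$y[io])^2)
        within <- d <= rules$max_dist_px
        if (sum(within) < rules$min_overlap_frames_link) next
        score <- mean(d)
        if (is.null(best) || score < best$score ||
            (score == best$score && mrna_ids[mi] < best$mrna)) {
          best <- list(mrna = mrna_ids[mi], score = score,
                       frames = common, t_s = md$t_s[im], within = within,
                       n_within = sum(within))
        }
      }
      if (!is.null(best)) {
        k <- k + 1L
        rows[[k]] <- data.frame(
          mrna_track = best$mrna, other_track = other_ids[oi],
          channel = od$channel[1L], n_common = length(best$frames),
          n_within = best$n_within, mean_dist = best$score)
        ## expand to a gap-free timeline so runs break at missing frames
        fr <- best$frames
        full <- seq.int(min(fr), max(fr))
        w <- logical(length(full))
        w[match(fr, full)] <- best$within
        tt <- rep(NA_real_, length(full))
        tt[match(fr, full)] <- best$t_s
        within_list[[k]] <- list(frames = full, within = w, t_s = tt)
      }
    }
    links <- if (k) do.call(rbind, rows) else NULL
  }
  if (is.null(links)) {
    links <- data.frame(mrna_track = integer(0), other_track = integer(0),
                        channel = character(0), n_common = integer(0),
                        n_within = integer(0), mean_dist = numeric(0))
  }
  structure(list(mrna = mrna_tbl, links = links, within = within_list),
            class = "linked_records")
}

#' Call colocalization on a within-radius frame series
#'
#' TRUE when some run of consecutive within-radius frames reaches the
#' mode's threshold; also returns every qualifying run.
#'
#' @param within logical vector (one element per frame; gaps must be
#'   encoded as FALSE/NA).
#' @param rules a [link_rules()] list (uses `min_consec_frames_coloc`).
#' @param t_s optional frame times; frames beyond `rules$coloc_window_s`
#'   are not scored.
#' @return list with `colocalized` and `events` (data.frame of
#'   `start`, `end`, `length` in frame indices of `within`).
#' @export
call_colocalization <- function(within, rules = link_rules(), t_s = NULL) {
  w <- !is.na(within) & within
  if (!is.null(t_s) && is.finite(rules$coloc_window_s)) {
    w <- w & (!is.na(t_s) & t_s <= rules$coloc_window_s)
  }
  runs <- true_runs(w)
  runs <- runs[runs$length >= rules$min_consec_frames_coloc, , drop = FALSE]
  list(colocalized = nrow(runs) > 0L, events = runs)
}

#' Score colocalization for every link of a record set
#'
#' @param records a `linked_records` object from [associate_tracks()].
#' @param rules a [link_rules()] list.
#' @return `records` with a `colocalized` column added to `links` and a
#'   per-mRNA `colocalized` / `translating` flag on `mrna` (an mRNA is
#'   colocalized when any associated protein track yields a qualifying
#'   event; translating when any translation-site track is linked).
#' @export
colocalize_records <- function(records, rules = link_rules()) {
  lk <- records$links
  if (nrow(lk)) {
    lk$colocalized <- vapply(seq_len(nrow(lk)), function(i) {
      call_colocalization(records$within[[i]]$within, rules,
                          records$within[[i]]$t_s)$colocalized
    }, logical(1L))
  } else {
    lk$colocalized <- logical(0)
  }
  records$links <- lk
  prot <- lk[lk$channel == "protein" & lk$colocalized, , drop = FALSE]
  tlsl <- lk[lk$channel == "tls", , drop = FALSE]
  records$mrna$colocalized <-
    records$mrna$mrna_track %in% prot$mrna_track
  records$mrna$translating <-
    records$mrna$mrna_track %in% tlsl$mrna_track
  records
}

#' Classify an mRNA as translating
#'
#' An mRNA is translating when a translation-site track is associated to
#' it under the same linkage rules used for the protein channel.
#'
#' @param records a `linked_records` object (after [associate_tracks()]).
#' @return logical vector along `records$mrna`.
#' @export
classify_translating <- function(records) {
  tlsl <- records$links[records$links$channel == "tls", , drop = FALSE]
  records$mrna$mrna_track %in% tlsl$mrna_track
}

#' Per-cell colocalization summary
#'
#' Computes, per cell, the number of (kept) mRNAs, the number
#' translating, and the fraction of mRNAs showing at least one
#' qualifying colocalization event — over all mRNAs and separately over
#' translating and non-translating mRNAs. Cell eligibility follows
#' `rules$eligibility`: strictly more than `min_cell_mrna` mRNAs, or
#' strictly more than `min_cell_translating` translating mRNAs.
#' Ineligible cells keep their fractions but are flagged.
#'
#' @param records a `linked_records` object after [colocalize_records()].
#' @param rules a [link_rules()] list.
#' @param has_tls whether a translation-site channel exists (fractions
#'   over translating mRNAs are NA otherwise).
#' @return data.frame with one row per cell: `cell`, `n_mrna`,
#'   `n_translating`, `frac_coloc`, `frac_coloc_translating`,
#'   `frac_coloc_nontranslating`, `eligible`.
#' @export
summarize_cells <- function(records, rules = link_rules(),
                            has_tls = any(records$links$channel == "tls")) {
  mt <- records$mrna
  if (is.null(mt$colocalized)) {
    stop_validation("run colocalize_records() first")
  }
  cells <- sort(unique(mt$cell))
  out <- lapply(cells, function(cl) {
    d <- mt[mt$cell == cl, , drop = FALSE]
    n <- nrow(d)
    ntr <- if (has_tls) sum(d$translating) else NA_integer_
    frac <- if (n) mean(d$colocalized) else NA_real_
    ftr <- if (has_tls && !is.na(ntr) && ntr > 0)
      mean(d$colocalized[d$translating]) else NA_real_
    fnt <- if (has_tls && !is.na(ntr) && (n - ntr) > 0)
      mean(d$colocalized[!d$translating]) else NA_real_
    eligible <- if (rules$eligibility == "mrna_count")
      n > rules$min_cell_mrna else
      (!is.na(ntr) && ntr > rules$min_cell_translating)
    data.frame(cell = cl, n_mrna = n, n_translating = ntr,
               frac_coloc = frac, frac_coloc_translating = ftr,
               frac_coloc_nontranslating = fnt, eligible = eligible)
  })
  do.call(rbind, out)
}

#' Trace-level colocalization analysis of a simulated binding cohort
#'
#' Convenience chain for simulated cohorts: build tracks from the traces,
#' apply the track filters and crossing exclusion, associate channels,
#' call colocalization and summarize per cell.
#'
#' @param cohort a `binding_cohort`.
#' @param rules a [link_rules()] list.
#' @param params a [link_params()] list; `frame_interval_s` is taken
#'   from the cohort.
#' @param seed seed for the detection/localization jitter.
#' @return list with `records`, `cells`, and `grand_mean_frac` (mean
#'   per-cell colocalized fraction over eligible cells; over translating
#'   mRNAs when a TLS channel exists).
#' @export
analyze_binding_cohort <- function(cohort, rules = link_rules(),
                                   params = NULL, seed = 1L) {
  params <- params %||% link_params(frame_interval_s = cohort$dt_s)
  tracks <- cohort_to_tracks(cohort, seed = seed)
  tracks <- filter_tracks(tracks, params,
                          mode = if (rules$mode == "steady_state")
                            "steady_state" else "runoff_uv")
  tracks <- flag_crossings(tracks, params$crossing_radius_px)
  records <- associate_tracks(tracks, rules)
  records <- colocalize_records(records, rules)
  cells <- summarize_cells(records, rules)
  has_tls <- any(records$links$channel == "tls")
  elig <- cells[cells$eligible, , drop = FALSE]
  gm <- if (nrow(elig) == 0L) NA_real_
        else if (has_tls) mean(elig$frac_coloc_translating, na.rm = TRUE)
        else mean(elig$frac_coloc)
  list(records = records, cells = cells, tracks = tracks,
       grand_mean_frac = gm)
}
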