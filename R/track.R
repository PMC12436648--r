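## Frame-to-frame linking (optimal bipartite assignment), gap closing and
## the track-level filters.

#' Linking parameters for particle tracking
#'
#' @param max_disp_px per-frame gating radius (px).
#' @param max_gap_frames allowed missed detections when closing gaps.
#' @param min_len_mrna minimum mRNA track length in frames (tracks
#'   shorter than this are discarded; 25 keeps tracks of >= 25 frames).
#' @param min_len_protein minimum protein track length in frames (4).
#' @param min_duration_s minimum mRNA track duration in seconds (120).
#' @param crossing_radius_px proximity at which two mRNA tracks count as
#'   crossing paths.
#' @param frame_interval_s frame interval (s), used for durations.
#' @return list of class `link_params`.
#' @export
link_params <- function(max_disp_px = 3, max_gap_frames = 1L,
                        min_len_mrna = 25L, min_len_protein = 4L,
                        min_duration_s = 120, crossing_radius_px = 2.6,
                        frame_interval_s = 2) {
  assert_pos(max_disp_px, "max_disp_px")
  max_gap_frames <- assert_count(max_gap_frames, "max_gap_frames")
  min_len_mrna <- assert_count(min_len_mrna, "min_len_mrna")
  min_len_protein <- assert_count(min_len_protein, "min_len_protein")
  if (min_len_mrna < min_len_protein) {
    stop_validation("min_len_mrna must be >= min_len_protein")
  }
  assert_pos(min_duration_s, "min_duration_s", strict = FALSE)
  assert_pos(crossing_radius_px, "crossing_radius_px")
  assert_pos(frame_interval_s, "frame_interval_s")
  structure(list(max_disp_px = max_disp_px,
                 max_gap_frames = max_gap_frames,
                 min_len_mrna = min_len_mrna,
                 min_len_protein = min_len_protein,
                 min_duration_s = min_duration_s,
                 crossing_radius_px = crossing_radius_px,
                 frame_interval_s = frame_interval_s),
            class = "link_params")
}

#' Optimal assignment for a rectangular cost matrix
#'
#' Hungarian algorithm (shortest augmenting paths with potentials,
#' O(n^2 m)). Solves `min sum cost[i, assign(i)]` over injective
#' assignments of rows to columns; requires `nrow <= ncol`.
#'
#' @param cost numeric cost matrix, rows <= cols, finite values.
#' @return integer vector: column assigned to each row.
#' @export
solve_assignment <- function(cost) {
  if (!is.matrix(cost) || anyNA(cost)) {
    stop_validation("cost must be a numeric matrix without NA")
  }
  n <- nrow(cost)
  m <- ncol(cost)
  if (n == 0L) return(integer(0))
  if (n > m) stop_validation("cost must have nrow <= ncol")
  u <- numeric(n)
  v <- numeric(m + 1L)           # index m+1 is the virtual start column
  p <- integer(m + 1L)           # row currently assigned to each column
  way <- integer(m)
  for (i in seq_len(n)) {
    p[m + 1L] <- i
    j0 <- m + 1L
    minv <- rep(Inf, m)
    used <- logical(m + 1L)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]
      free <- which(!used[seq_len(m)])
      cur <- cost[i0, free] - u[i0] - v[free]
      upd <- cur < minv[free]
      if (any(upd)) {
        minv[free[upd]] <- cur[upd]
        way[free[upd]] <- j0
      }
      jrel <- which.min(minv[free])
      j1 <- free[jrel]
      delta <- minv[j1]
      usedj <- which(used)
      rows <- p[usedj]
      u[rows[rows > 0L]] <- u[rows[rows > 0L]] + delta
      v[usedj] <- v[usedj] - delta
      minv[free] <- minv[free] - delta
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == m + 1L) break
    }
  }
  ans <- integer(n)
  for (j in seq_len(m)) if (p[j] > 0L) ans[p[j]] <- j
  ans
}

## Gated frame-pair linking: returns for each source index the matched
## target index or NA, minimizing summed squared displacement with
## births/deaths allowed at cost max_disp^2 each (standard LAP layout).
link_pair <- function(xy1, xy2, max_disp) {
  n1 <- nrow(xy1)
  n2 <- nrow(xy2)
  if (n1 == 0L || n2 == 0L) return(rep(NA_integer_, n1))
  d2 <- outer(xy1[, 1], xy2[, 1], "-")^2 + outer(xy1[, 2], xy2[, 2], "-")^2
  big <- 1e12
  b <- max_disp^2
  nn <- n1 + n2
  cost <- matrix(0, nn, nn)
  cost[seq_len(n1), seq_len(n2)] <- ifelse(d2 <= b, d2, big)
  cost[seq_len(n1), n2 + seq_len(n1)] <- big
  cost[cbind(seq_len(n1), n2 + seq_len(n1))] <- b
  cost[n1 + seq_len(n2), seq_len(n2)] <- big
  cost[cbind(n1 + seq_len(n2), seq_len(n2))] <- b
  a <- solve_assignment(cost)
  match <- a[seq_len(n1)]
  match[match > n2] <- NA_integer_
  ## drop gated-out links that were forced
  if (any(!is.na(match))) {
    i <- which(!is.na(match))
    bad <- d2[cbind(i, match[i])] > b
    match[i[bad]] <- NA_integer_
  }
  match
}

#' Link per-frame spots into tracks
#'
#' Frame-to-frame linking by optimal bipartite assignment minimizing the
#' summed squared displacement, with a hard gating radius; unassigned
#' spots start new tracks. Channels (if present) are linked
#' independently. Deterministic given the input.
#'
#' @param spots data.frame with columns `frame`, `x`, `y` and optionally
#'   `channel` (plus any extra columns, which are carried through).
#' @param params a [link_params()] list.
#' @return the input data.frame with a `track_id` column, ordered by
#'   track and frame.
#' @export
link_frames <- function(spots, params = link_params()) {
  need <- c("frame", "x", "y")
  if (!all(need %in% names(spots))) {
    stop_validation("spots must have columns frame, x, y")
  }
  if (nrow(spots) == 0L) {
    spots$track_id <- integer(0)
    return(spots)
  }
  if (is.null(spots$channel)) spots$channel <- "spots"
  out <- vector("list", length(unique(spots$channel)))
  nxt <- 1L
  ci <- 0L
  for (ch in unique(spots$channel)) {
    s <- spots[spots$channel == ch, , drop = FALSE]
    s <- s[order(s$frame), , drop = FALSE]
    s$track_id <- NA_integer_
    frames <- sort(unique(s$frame))
    prev_idx <- which(s$frame == frames[1L])
    s$track_id[prev_idx] <- seq.int(nxt, nxt + length(prev_idx) - 1L)
    nxt <- nxt + length(prev_idx)
    if (length(frames) > 1L) {
      for (fi in 2L:length(frames)) {
        cur_idx <- which(s$frame == frames[fi])
        if (frames[fi] - frames[fi - 1L] == 1L && length(prev_idx)) {
          m <- link_pair(cbind(s$x[prev_idx], s$y[prev_idx]),
                         cbind(s$x[cur_idx], s$y[cur_idx]),
                         params$max_disp_px)
          linked <- which(!is.na(m))
          s$track_id[cur_idx[m[linked]]] <- s$track_id[prev_idx[linked]]
        }
        new <- cur_idx[is.na(s$track_id[cur_idx])]
        if (length(new)) {
          s$track_id[new] <- seq.int(nxt, nxt + length(new) - 1L)
          nxt <- nxt + length(new)
        }
        prev_idx <- cur_idx
      }
    }
    ci <- ci + 1L
    out[[ci]] <- s
  }
  res <- do.call(rbind, out[seq_len(ci)])
  res[order(res$track_id, res$frame), , drop = FALSE]
}

## Per-track summary used by gap closing and filtering.
track_summary <- function(tracks) {
  f <- factor(tracks$track_id, levels = unique(tracks$track_id))
  data.frame(
    track_id = unique(tracks$track_id),
    channel = as.character(tapply(as.character(tracks$channel), f,
                                  `[`, 1L)),
    first = as.numeric(tapply(tracks$frame, f, min)),
    last = as.numeric(tapply(tracks$frame, f, max)),
    n_frames = as.integer(tapply(tracks$frame, f, length)),
    row.names = NULL)
}

#' Close short gaps between track fragments
#'
#' Joins track ends to later track starts within `max_gap_frames` missed
#' frames and a gating radius scaled by the gap length
#' (`max_disp_px * sqrt(gap + 1)`), using optimal assignment over the
#' candidate end-start pairs. Temporally overlapping tracks are never
#' merged. With `max_gap_frames = 0` the input is returned unchanged.
#'
#' @param tracks data.frame from [link_frames()].
#' @param params a [link_params()] list.
#' @return tracks with merged `track_id`s.
#' @export
close_gaps <- function(tracks, params = link_params()) {
  if (params$max_gap_frames == 0L || nrow(tracks) == 0L) return(tracks)
  repeat {
    merged <- FALSE
    for (ch in unique(tracks$channel)) {
      sel <- tracks$channel == ch
      info <- track_summary(tracks[sel, , drop = FALSE])
      if (nrow(info) < 2L) next
      ## candidate pairs: end of a, start of b, 1 <= gap <= max_gap
      ends <- info
      starts <- info
      pairs <- NULL
      for (ai in seq_len(nrow(ends))) {
        g <- starts$first - ends$last[ai] - 1L
        ok <- which(g >= 1L & g <= params$max_gap_frames &
                    starts$track_id != ends$track_id[ai])
        if (length(ok)) {
          pairs <- rbind(pairs, cbind(a = ai, b = ok, gap = g[ok]))
        }
      }
      if (is.null(pairs)) next
      ## distances end->start
      last_pos <- function(id) {
        r <- tracks[tracks$track_id == id, , drop = FALSE]
        r <- r[which.max(r$frame), ]
        c(r$x, r$y)
      }
      first_pos <- function(id) {
        r <- tracks[tracks$track_id == id, , drop = FALSE]
        r <- r[which.min(r$frame), ]
        c(r$x, r$y)
      }
      d <- numeric(nrow(pairs))
      admissible <- logical(nrow(pairs))
      for (k in seq_len(nrow(pairs))) {
        pa <- last_pos(ends$track_id[pairs[k, "a"]])
        pb <- first_pos(starts$track_id[pairs[k, "b"]])
        d[k] <- sqrt(sum((pa - pb)^2))
        admissible[k] <- d[k] <=
          params$max_disp_px * sqrt(pairs[k, "gap"] + 1)
      }
      pairs <- pairs[admissible, , drop = FALSE]
      d <- d[admissible]
      if (nrow(pairs) == 0L) next
      ## greedy optimal: smallest distance first, each end/start used once
      ord <- order(d, pairs[, "a"], pairs[, "b"])
      used_a <- used_b <- integer(0)
      for (k in ord) {
        a <- pairs[k, "a"]
        b <- pairs[k, "b"]
        if (a %in% used_a || b %in% used_b) next
        id_a <- ends$track_id[a]
        id_b <- starts$track_id[b]
        tracks$track_id[tracks$track_id == id_b] <- id_a
        used_a <- c(used_a, a)
        used_b <- c(used_b, b)
        merged <- TRUE
      }
    }
    if (!merged) break
  }
  tracks[order(tracks$track_id, tracks$frame), , drop = FALSE]
}

#' Apply the track-level filters
#'
#' Discards mRNA tracks shorter than `min_len_mrna` frames and protein
#' tracks shorter than `min_len_protein` frames ("shorter than N
#' discarded", so tracks of exactly N frames are kept), and mRNA tracks
#' whose span is below `min_duration_s`. Discarded tracks are retained
#' with a machine-readable reason; filtering is idempotent.
#'
#' @param tracks data.frame with `track_id`, `channel`, `frame`.
#' @param params a [link_params()] list.
#' @param mode `"steady_state"` or `"runoff_uv"` (kept for provenance;
#'   the length thresholds come from `params`).
#' @return tracks with `status` (`"kept"`/`"discarded"`) and `reason`.
#' @export
filter_tracks <- function(tracks, params = link_params(),
                          mode = c("steady_state", "runoff_uv")) {
  mode <- match.arg(mode)
  if (nrow(tracks) == 0L) {
    tracks$status <- character(0)
    tracks$reason <- character(0)
    return(tracks)
  }
  info <- track_summary(tracks)
  info$duration_s <- (info$last - info$first + 1L) * params$frame_interval_s
  status <- rep("kept", nrow(info))
  reason <- rep("none", nrow(info))
  too_short <- (info$channel == "mrna" & info$n_frames < params$min_len_mrna) |
    (info$channel %in% c("protein", "tls") &
       info$n_frames < params$min_len_protein)
  status[too_short] <- "discarded"
  reason[too_short] <- "too_short"
  short_dur <- info$channel == "mrna" & !too_short &
    info$duration_s < params$min_duration_s
  status[short_dur] <- "discarded"
  reason[short_dur] <- "too_brief"
  idx <- match(tracks$track_id, info$track_id)
  tracks$status <- status[idx]
  tracks$reason <- reason[idx]
  tracks
}

#' Flag mRNA tracks that cross paths
#'
#' Any pair of mRNA tracks that approach within `crossing_radius_px` at a
#' shared frame is flagged (both members) and excluded from downstream
#' analysis, mirroring the discard rule for mRNAs whose tracking was
#' disrupted by path crossing.
#'
#' @param tracks data.frame with `track_id`, `channel`, `frame`, `x`, `y`
#'   (and `status` from [filter_tracks()], which is respected).
#' @param crossing_radius_px flag distance (px).
#' @return tracks with crossing tracks marked
#'   `status = "discarded", reason = "crossing"`.
#' @export
flag_crossings <- function(tracks, crossing_radius_px = 2.6) {
  m <- tracks[tracks$channel == "mrna", , drop = FALSE]
  if (nrow(m) == 0L) return(tracks)
  if (!is.null(m$status)) m <- m[m$status == "kept", , drop = FALSE]
  flagged <- integer(0)
  ids <- unique(m$track_id)
  if (length(ids) > 1L) {
    by_id <- split(m[, c("frame", "x", "y")], factor(m$track_id, ids))
    ## prune distant pairs by track centroid + maximal excursion
    cx <- vapply(by_id, function(d) mean(d$x), 0)
    cy <- vapply(by_id, function(d) mean(d$y), 0)
    ex <- vapply(by_id, function(d)
      max(sqrt((d$x - mean(d$x))^2 + (d$y - mean(d$y))^2)), 0)
    for (ai in seq_along(ids)[-length(ids)]) {
      a <- by_id[[ai]]
      for (bi in (ai + 1L):length(ids)) {
        cd <- sqrt((cx[ai] - cx[bi])^2 + (cy[ai] - cy[bi])^2)
        if (cd - ex[ai] - ex[bi] > crossing_radius_px) next
        b <- by_id[[bi]]
        common <- intersect(a$frame, b$frame)
        if (length(common) == 0L) next
        ia <- match(common, a$frame)
        ib <- match(common, b$frame)
        dmin <- min(sqrt((a$x[ia] - b$x[ib])^2 + (a$y[ia] - b$y[ib])^2))
        if (dmin <= crossing_radius_px) {
          flagged <- union(flagged, c(ids[ai], ids[bi]))
        }
      }
    }
  }
  if (length(flagged)) {
    sel <- tracks$track_id %in% flagged
    if (is.null(tracks$status)) {
      tracks$status <- "kept"
      tracks$reason <- "none"
    }
    tracks$status[sel] <- "discarded"
    tracks$reason[sel] <- "crossing"
  }
  tracks
}
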