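## smFISH-IF quantification: 3D spot detection per cell mask, translation
## site identification, per-cell single-protein calibration and
## nascent-peptide (NAP) counting.

mask_cell_at <- function(mask, x, y) {
  r <- pmin(pmax(round(y) + 1, 1), nrow(mask))
  c <- pmin(pmax(round(x) + 1, 1), ncol(mask))
  mask[cbind(r, c)]
}

#' Detect mRNA spots in an smFISH field
#'
#' 3D LoG detection and Gaussian fitting on the mRNA channel, restricted
#' to pixels covered by a cell mask; each spot is annotated with its cell
#' id.
#'
#' @param field output of [simulate_smfish_field()] (or a list with
#'   `mrna` 3D array and `mask` label matrix).
#' @param params a [detection_params()] list with `dims = 3`.
#' @return data.frame of spots with a `cell` column (spots outside the
#'   mask are excluded).
#' @export
detect_mrna_spots <- function(field, params = detection_params(dims = 3L)) {
  spots <- detect_spots(field$mrna, params)
  if (nrow(spots) == 0L) return(cbind(spots, cell = integer(0)))
  spots$cell <- mask_cell_at(field$mask, spots$x, spots$y)
  spots[spots$cell > 0L, , drop = FALSE]
}

#' Detect protein-channel spots in an smFISH field
#'
#' @inheritParams detect_mrna_spots
#' @return data.frame of protein spots with `cell` annotation.
#' @export
detect_protein_spots <- function(field,
                                 params = detection_params(dims = 3L)) {
  spots <- detect_spots(field$protein, params)
  if (nrow(spots) == 0L) return(cbind(spots, cell = integer(0)))
  spots$cell <- mask_cell_at(field$mask, spots$x, spots$y)
  spots[spots$cell > 0L, , drop = FALSE]
}

#' Identify translation sites among protein spots
#'
#' A protein-channel spot is a translation site (TLS) when it lies
#' within `max_dist_xy` pixels laterally and `max_dist_z` planes axially
#' of a detected mRNA spot; each TLS is linked to its nearest mRNA.
#' Amplitude thresholding happens in the detection stage.
#'
#' @param field smFISH field (see [detect_mrna_spots()]).
#' @param mrna_spots output of [detect_mrna_spots()].
#' @param params a [detection_params()] list with `dims = 3`.
#' @param max_dist_xy lateral association radius (px).
#' @param max_dist_z axial association distance (planes).
#' @param protein_spots optional precomputed [detect_protein_spots()]
#'   output (avoids re-detection).
#' @return list with `tls` (TLS table with `mrna_id`, `dist_xy`) and
#'   `protein_spots` (all protein detections, with `is_tls`).
#' @export
detect_translation_sites <- function(field, mrna_spots,
                                     params = detection_params(dims = 3L),
                                     max_dist_xy = 2, max_dist_z = 1,
                                     protein_spots = NULL) {
  ps <- protein_spots %||% detect_protein_spots(field, params)
  ps$is_tls <- FALSE
  ps$mrna_id <- NA_integer_
  ps$dist_xy <- NA_real_
  if (nrow(ps) && nrow(mrna_spots)) {
    for (i in seq_len(nrow(ps))) {
      dxy <- sqrt((mrna_spots$x - ps$x[i])^2 + (mrna_spots$y - ps$y[i])^2)
      dz <- abs(mrna_spots$z - ps$z[i])
      ok <- which(dxy <= max_dist_xy & dz <= max_dist_z)
      if (length(ok)) {
        j <- ok[which.min(dxy[ok])]
        ps$is_tls[i] <- TRUE
        ps$mrna_id[i] <- j
        ps$dist_xy[i] <- dxy[j]
      }
    }
  }
  list(tls = ps[ps$is_tls, , drop = FALSE],
       protein_spots = ps)
}

#' Per-cell single-protein unit intensity
#'
#' Mean integrated intensity of mature single proteins: protein-channel
#' detections outside the exclusion region of every translation site
#' (an ellipsoid of `roi_k` fitted sigmas around the TLS), averaged per
#' cell. Cells with fewer than `min_n` single-protein detections are
#' flagged unusable.
#'
#' @param protein_spots all protein detections (from
#'   [detect_translation_sites()]`$protein_spots`).
#' @param tls the TLS table.
#' @param roi_k exclusion half-axes in units of the TLS fitted sigma.
#' @param min_n minimum single-protein detections per cell.
#' @return data.frame per cell: `cell`, `unit_mean`, `n_single`, `ok`,
#'   `reason`.
#' @export
single_protein_intensity <- function(protein_spots, tls, roi_k = 3,
                                     min_n = 5L) {
  singles <- protein_spots[!protein_spots$is_tls, , drop = FALSE]
  if (nrow(singles) && nrow(tls)) {
    excl <- rep(FALSE, nrow(singles))
    for (j in seq_len(nrow(tls))) {
      q <- ((singles$x - tls$x[j]) / (roi_k * tls$sigma_x[j]))^2 +
        ((singles$y - tls$y[j]) / (roi_k * tls$sigma_y[j]))^2 +
        ((singles$z - tls$z[j]) / (roi_k * tls$sigma_z[j]))^2
      excl <- excl | q <= 1
    }
    singles <- singles[!excl, , drop = FALSE]
  }
  cells <- sort(unique(c(singles$cell, tls$cell)))
  out <- lapply(cells, function(cl) {
    s <- singles[singles$cell == cl, , drop = FALSE]
    n <- nrow(s)
    data.frame(cell = cl,
               unit_mean = if (n) mean(s$integrated_intensity) else NA_real_,
               n_single = n,
               ok = n >= min_n,
               reason = if (n >= min_n) "none" else "too_few_singles",
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Nascent-peptide counts per translation site
#'
#' Normalizes each TLS integrated intensity by the single-protein unit
#' mean of the *same* cell; TLS in cells without a usable unit mean get
#' `NA` with a reason.
#'
#' @param tls TLS table.
#' @param units per-cell table from [single_protein_intensity()].
#' @return the TLS table with `nap_count` and `nap_reason` columns.
#' @export
nap_counts <- function(tls, units) {
  idx <- match(tls$cell, units$cell)
  usable <- !is.na(idx) & units$ok[idx]
  tls$nap_count <- ifelse(usable,
                          tls$integrated_intensity / units$unit_mean[idx],
                          NA_real_)
  tls$nap_reason <- ifelse(usable, "none", "no_unit_calibration")
  tls
}

#' Compare two NAP-count distributions
#'
#' Square-root transforms both samples (variance-stabilizing for skewed
#' count data) and applies a two-tailed pooled-variance t test.
#'
#' @param a,b non-negative numeric samples of NAP counts.
#' @param var_equal pooled-variance t test (default TRUE).
#' @return list with `statistic` and `p_value`.
#' @export
compare_nap_distributions <- function(a, b, var_equal = TRUE) {
  if (any(a < 0, na.rm = TRUE) || any(b < 0, na.rm = TRUE)) {
    stop_validation("NAP counts must be non-negative for the sqrt transform")
  }
  h <- stats::t.test(sqrt(a), sqrt(b), var.equal = var_equal)
  list(statistic = unname(h$statistic), p_value = h$p.value)
}

#' Full smFISH-IF quantification of one field
#'
#' Chains mRNA detection, translation-site identification, per-cell
#' single-protein calibration and NAP counting.
#'
#' @param field output of [simulate_smfish_field()].
#' @param params a [detection_params()] list with `dims = 3`.
#' @param max_dist_xy,max_dist_z TLS-mRNA association thresholds.
#' @param min_n minimum single proteins per cell.
#' @return list with `mrna_spots`, `tls` (with `nap_count`), `units`.
#' @export
analyze_smfish_field <- function(field,
                                 params = detection_params(dims = 3L),
                                 max_dist_xy = 2, max_dist_z = 1,
                                 min_n = 5L) {
  mr <- detect_mrna_spots(field, params)
  dt <- detect_translation_sites(field, mr, params, max_dist_xy,
                                 max_dist_z)
  units <- single_protein_intensity(dt$protein_spots, dt$tls,
                                    min_n = min_n)
  tls <- nap_counts(dt$tls, units)
  list(mrna_spots = mr, tls = tls, units = units)
}
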