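## Harringtonine-runoff clearance times and Kaplan-Meier survival with
## Greenwood variance.

#' Rules for clearance-time extraction
#'
#' @param frac fraction of the maximum below which the signal counts as
#'   lost (0.10 per the runoff protocol).
#' @param coincident_frames molecules whose mRNA and TLS signals are lost
#'   within this many frames of each other are excluded (3).
#' @param first_frames number of leading frames whose mean must reach
#'   `frac` of the maximum for the molecule to count as translating (4).
#' @return list of rules.
#' @export
clearance_rules <- function(frac = 0.10, coincident_frames = 3L,
                            first_frames = 4L) {
  assert_prob(frac, "frac")
  list(frac = frac,
       coincident_frames = assert_count(coincident_frames,
                                        "coincident_frames"),
       first_frames = assert_count(first_frames, "first_frames", min = 1L))
}

## First index strictly after i_max at which x < frac * max(x); NA if never.
first_crossing <- function(x, frac) {
  i_max <- which.max(x)
  thr <- frac * x[i_max]
  after <- which(x < thr)
  after <- after[after > i_max]
  list(i_max = i_max, i_cross = if (length(after)) after[1L] else NA_integer_)
}

#' Clearance time of one translation site after initiation block
#'
#' Implements the runoff measurement: find the frame of maximal
#' translation-site (TLS) signal, then the first later frame at which the
#' signal falls strictly below 10% of that maximum; the clearance time is
#' the elapsed time between the two. Exclusion rules, applied in order:
#' molecules whose first-`first_frames` mean TLS signal is below 10% of
#' the maximum are excluded as not translating; molecules whose mRNA and
#' TLS losses coincide within `coincident_frames` frames are excluded
#' (signal loss for reasons other than ribosome clearance); TLS signal
#' persisting after mRNA loss is kept. Traces that never cross are
#' censored at the window end.
#'
#' @param tls_trace TLS intensity series (treatment clock).
#' @param mrna_trace mRNA intensity series, same length.
#' @param frame_interval_s frame interval (s).
#' @param rules a [clearance_rules()] list.
#' @return one-row data.frame: `t_max_s`, `clearance_s`, `censored`,
#'   `excluded`, `excluded_reason` (`"none"`, `"not_translating"`,
#'   `"coincident_loss"`).
#' @export
clearance_time <- function(tls_trace, mrna_trace, frame_interval_s,
                           rules = clearance_rules()) {
  if (length(tls_trace) != length(mrna_trace)) {
    stop_validation("tls and mrna traces must have equal length")
  }
  assert_pos(frame_interval_s, "frame_interval_s")
  n <- length(tls_trace)
  res <- data.frame(t_max_s = NA_real_, clearance_s = NA_real_,
                    censored = FALSE, excluded = FALSE,
                    excluded_reason = "none", stringsAsFactors = FALSE)
  tls_max <- max(tls_trace)
  k <- min(rules$first_frames, n)
  if (mean(tls_trace[seq_len(k)]) < rules$frac * tls_max) {
    res$excluded <- TRUE
    res$excluded_reason <- "not_translating"
    return(res)
  }
  ct <- first_crossing(tls_trace, rules$frac)
  cm <- first_crossing(mrna_trace, rules$frac)
  if (!is.na(ct$i_cross) && !is.na(cm$i_cross) &&
      abs(ct$i_cross - cm$i_cross) <= rules$coincident_frames) {
    res$excluded <- TRUE
    res$excluded_reason <- "coincident_loss"
    return(res)
  }
  res$t_max_s <- (ct$i_max - 1L) * frame_interval_s
  if (is.na(ct$i_cross)) {
    res$censored <- TRUE
    res$clearance_s <- (n - ct$i_max) * frame_interval_s
  } else {
    res$clearance_s <- (ct$i_cross - ct$i_max) * frame_interval_s
  }
  res
}

#' Clearance times for a whole runoff cohort
#'
#' Applies [clearance_time()] to every molecule of a simulated (or
#' assembled) runoff cohort.
#'
#' @param cohort a `runoff_cohort` (or any list with `tls`, `mrna` trace
#'   matrices and `dt_s`).
#' @param rules a [clearance_rules()] list.
#' @return data.frame with one row per molecule (`mrna` id column added).
#' @export
clearance_cohort <- function(cohort, rules = clearance_rules()) {
  n <- ncol(cohort$tls)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    r <- clearance_time(cohort$tls[, i], cohort$mrna[, i], cohort$dt_s,
                        rules)
    r$mrna <- i
    out[[i]] <- r
  }
  do.call(rbind, out)
}

#' Kaplan-Meier survival curve with Greenwood variance
#'
#' Product-limit estimate over event (clearance) times with right
#' censoring. The variance follows Greenwood's formula,
#' `Var(S(t)) = S(t)^2 * sum_{t_i <= t} d_i / (n_i (n_i - d_i))`, and the
#' 95% confidence bounds are `S +/- 1.96 sqrt(Var)` clipped to \[0, 1\]
#' (`conf_type = "plain"`) or the log-log transformed bounds
#' (`conf_type = "log-log"`).
#'
#' @param times event or censoring times (s).
#' @param censored logical; TRUE where the molecule never cleared.
#' @param conf_type confidence-bound transformation.
#' @return object of class `survival_curve`: data.frame with `time`,
#'   `n_risk`, `n_event`, `surv`, `var`, `lower`, `upper`.
#' @export
km_greenwood <- function(times, censored = rep(FALSE, length(times)),
                         conf_type = c("plain", "log-log")) {
  conf_type <- match.arg(conf_type)
  if (length(times) != length(censored)) {
    stop_validation("times and censored must have equal length")
  }
  if (any(times < 0)) stop_validation("times must be non-negative")
  event_times <- sort(unique(times[!censored]))
  if (length(event_times) == 0L) {
    out <- data.frame(time = numeric(0), n_risk = integer(0),
                      n_event = integer(0), surv = numeric(0),
                      var = numeric(0), lower = numeric(0),
                      upper = numeric(0))
    attr(out, "n") <- length(times)
    attr(out, "all_censored") <- TRUE
    class(out) <- c("survival_curve", "data.frame")
    return(out)
  }
  n_risk <- vapply(event_times, function(t) sum(times >= t), 0)
  n_event <- vapply(event_times, function(t) sum(times == t & !censored), 0)
  surv <- cumprod(1 - n_event / n_risk)
  gw <- cumsum(ifelse(n_risk > n_event,
                      n_event / (n_risk * (n_risk - n_event)), 0))
  v <- surv^2 * gw
  ## at the last event time with S = 0 the Greenwood sum is degenerate
  v[surv == 0] <- 0
  if (conf_type == "plain") {
    lower <- pmax(surv - 1.96 * sqrt(v), 0)
    upper <- pmin(surv + 1.96 * sqrt(v), 1)
  } else {
    ## log-log: exp(-exp(log(-log S) +/- 1.96 se_loglog))
    se_ll <- ifelse(surv > 0 & surv < 1,
                    sqrt(gw) / abs(log(surv)), NA_real_)
    lower <- ifelse(is.na(se_ll), ifelse(surv == 0, 0, surv),
                    surv^exp(1.96 * se_ll))
    upper <- ifelse(is.na(se_ll), surv, surv^exp(-1.96 * se_ll))
  }
  out <- data.frame(time = event_times, n_risk = n_risk, n_event = n_event,
                    surv = surv, var = v, lower = lower, upper = upper)
  attr(out, "n") <- length(times)
  attr(out, "all_censored") <- FALSE
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Median survival time of a Kaplan-Meier curve
#'
#' Time at which the survival estimate reaches 0.5. The step definition
#' (first event time with `S <= 0.5`) is quantized to the frame grid;
#' with `interpolate = TRUE` the crossing is interpolated linearly
#' between the bracketing event times, which removes the grid
#' quantization when frames are coarse. `NA` when the curve never
#' reaches 0.5 (heavy censoring).
#'
#' @param curve a `survival_curve`.
#' @param interpolate linearly interpolate the 0.5 crossing.
#' @return median time (s) or `NA`.
#' @export
km_median <- function(curve, interpolate = FALSE) {
  i <- which(curve$surv <= 0.5)
  if (length(i) == 0L) return(NA_real_)
  i <- i[1L]
  if (!interpolate) return(curve$time[i])
  t1 <- curve$time[i]
  s1 <- curve$surv[i]
  t0 <- if (i == 1L) 0 else curve$time[i - 1L]
  s0 <- if (i == 1L) 1 else curve$surv[i - 1L]
  if (s0 == s1) return(t1)
  t0 + (s0 - 0.5) / (s0 - s1) * (t1 - t0)
}

#' Compare two runoff cohorts by their survival medians
#'
#' @param curve_a,curve_b `survival_curve` objects (e.g. wild-type and
#'   overexpression cohorts).
#' @param interpolate interpolate the median crossings (default TRUE:
#'   at 10-s frames the step medians are grid-quantized, which only
#'   adds noise to the ratio).
#' @return list with `median_a`, `median_b`, `median_ratio`
#'   (`median_a / median_b`; a ratio above 1 means cohort b clears
#'   faster) and `defined`.
#' @export
compare_cohorts <- function(curve_a, curve_b, interpolate = TRUE) {
  ma <- km_median(curve_a, interpolate)
  mb <- km_median(curve_b, interpolate)
  defined <- !is.na(ma) && !is.na(mb) && mb > 0 &&
    !isTRUE(attr(curve_a, "all_censored")) &&
    !isTRUE(attr(curve_b, "all_censored"))
  list(median_a = ma, median_b = mb,
       median_ratio = if (defined) ma / mb else NA_real_,
       defined = defined)
}

#' Fraction of translating molecules persisting at a time point
#'
#' Among non-excluded clearance records, the fraction whose
#' translation-site signal had not yet dropped below the 10%-of-maximum
#' level at `t_s` after its maximum (either censored, or crossing later
#' than `t_s`).
#'
#' @param clearance data.frame from [clearance_cohort()].
#' @param t_s time point (s), e.g. 600 for 10 min.
#' @return list with `fraction`, `n_persistent`, `n_total` and the
#'   persistent record ids `mrna`.
#' @export
persistent_fraction <- function(clearance, t_s) {
  ok <- clearance[!clearance$excluded, , drop = FALSE]
  persist <- ok$censored | ok$clearance_s + ok$t_max_s > t_s
  list(fraction = if (nrow(ok)) mean(persist) else NA_real_,
       n_persistent = sum(persist), n_total = nrow(ok),
       mrna = ok$mrna[persist])
}
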