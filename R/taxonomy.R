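# Seven-category demographic transition taxonomy from crude-rate
# trajectories: before / early / mid transition, and late / post transition
# split by the sign of net migration.

#' Detect a sustained decline in a series
#'
#' The onset is the first year that begins a run of at least `w`
#' consecutive years, each of which lies below the running maximum of the
#' series *before the run* by at least the relative margin `m`.
#' Deterministic; returns `NA` if no such run exists.
#'
#' @param series numeric vector (e.g. a crude rate by year).
#' @param w run length in years (>= 2).
#' @param m relative margin below the pre-run maximum (default 0.05).
#' @return the 1-based onset index, or `NA_integer_`.
#' @export
detect_sustained_decline <- function(series, w = 10, m = 0.05) {
  if (w < 2) stop("w must be >= 2", call. = FALSE)
  n <- length(series)
  if (n < w + 1) return(NA_integer_)
  for (i in 2:(n - w + 1)) {
    pre_max <- max(series[1:(i - 1)])
    if (all(series[i:(i + w - 1)] <= pre_max * (1 - m))) return(i)
  }
  NA_integer_
}

#' Classify a location-year into a demographic transition category
#'
#' The five underlying stages use sustained declines in the crude death
#' and birth rates and the history of the natural rate of increase (NRI =
#' CBR - CDR); the late and post stages are split by the sign of net
#' migration (trailing mean), giving seven categories:
#'
#' 1. *before*: no sustained CDR decline yet.
#' 2. *early*: CDR in sustained decline while growth is still at or
#'    approaching its peak, without the full mid-stage signature (CBR not
#'    yet in sustained decline, or the peak NRI below the threshold).
#' 3. *mid*: both rates in sustained decline, the maximum NRI has reached
#'    the threshold (3.0%/yr), and NRI has not yet fallen below
#'    `peak_frac` of its historical peak.
#' 4./5. *late_emigration* / *late_immigration*: NRI fallen below
#'    `peak_frac` of its historical peak but still non-negative.
#' 6./7. *post_emigration* / *post_immigration*: NRI negative (CBR-CDR
#'    crossover).
#'
#' @param traj data.frame with columns `year`, `cbr`, `cdr` (per 1000) and
#'   `net_migration_rate` (per 1000, sign meaningful).
#' @param year the year to classify (history through this year is used).
#' @param w,m sustained-decline window and margin ([detect_sustained_decline()]).
#' @param nri_threshold "achieved high growth" NRI threshold, per 1000
#'   (default 30 = 3.0%/yr).
#' @param peak_frac fraction of the historical peak NRI below which the
#'   mid stage ends (default 0.8).
#' @param migration_window trailing years averaged for the migration sign
#'   (exactly zero counts as immigration, flagged).
#' @return list with `label` (one of the seven categories), and
#'   diagnostics `cdr_onset`, `cbr_onset`, `max_nri`, `nri`,
#'   `net_migration_sign`, `zero_migration_tie`.
#' @export
classify_stage <- function(traj, year, w = 10, m = 0.05, nri_threshold = 30,
                           peak_frac = 0.8, migration_window = 5) {
  h <- traj[traj$year <= year, , drop = FALSE]
  h <- h[order(h$year), , drop = FALSE]
  if (nrow(h) < w + 1) stop("insufficient history (< ", w + 1, " years)", call. = FALSE)
  nri <- h$cbr - h$cdr
  cdr_onset <- detect_sustained_decline(h$cdr, w, m)
  cbr_onset <- detect_sustained_decline(h$cbr, w, m)
  max_nri <- max(nri)
  nri_now <- nri[nrow(h)]
  mig <- utils::tail(h$net_migration_rate, migration_window)
  mig_mean <- mean(mig)
  tie <- mig_mean == 0
  sign_tag <- if (mig_mean >= 0) "immigration" else "emigration"
  at_peak <- nri_now >= peak_frac * max_nri
  label <-
    if (is.na(cdr_onset)) {
      "before"
    } else if (nri_now < 0) {
      paste0("post_", sign_tag)
    } else if (!is.na(cbr_onset) && max_nri >= nri_threshold && at_peak) {
      "mid"
    } else if (!at_peak) {
      # growth has fallen below peak_frac of its historical peak
      paste0("late_", sign_tag)
    } else {
      # CDR declining with growth still at or approaching its peak
      "early"
    }
  list(label = label, cdr_onset = cdr_onset, cbr_onset = cbr_onset,
       max_nri = max_nri, nri = nri_now,
       net_migration_sign = sign_tag, zero_migration_tie = tie)
}

#' Classify every feasible year of a trajectory
#'
#' @inheritParams classify_stage
#' @return data.frame `year`, `label` (years with at least `w + 1` years
#'   of history).
#' @export
classify_trajectory <- function(traj, w = 10, m = 0.05, nri_threshold = 30,
                                peak_frac = 0.8, migration_window = 5) {
  yrs <- sort(traj$year)
  yrs <- yrs[-seq_len(min(w, length(yrs)))]
  out <- lapply(yrs, function(y) {
    data.frame(year = y,
               label = classify_stage(traj, y, w, m, nri_threshold,
                                      peak_frac, migration_window)$label)
  })
  do.call(rbind, out)
}
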