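#' Fertility schedules
#'
#' An age-specific fertility schedule over the nine 5-year maternal age
#' groups 10-14 ... 50-54 (births per woman-year), together with the sex
#' ratio at birth (male births per female birth).
#'
#' @param asfr numeric vector of nine non-negative rates; may be named by
#'   group start (10, 15, ..., 50), otherwise assumed in order.
#' @param srb sex ratio at birth (> 0), default 1.05.
#' @return object of class `fertility_schedule`.
#' @export
#' @examples
#' fs <- fertility_schedule(c(0.005, rep(0.1, 7), 0.002))
#' tfr_from_asfr(fs)
fertility_schedule <- function(asfr, srb = 1.05) {
  starts <- seq(10, 50, by = 5)
  if (!is.null(names(asfr))) {
    asfr <- asfr[as.character(starts)]
    if (anyNA(asfr)) stop("missing maternal age group", call. = FALSE)
  }
  if (length(asfr) != 9) stop("need exactly nine maternal age groups (10-54)", call. = FALSE)
  if (any(asfr < 0)) stop("asfr must be >= 0", call. = FALSE)
  if (srb <= 0) stop("srb must be > 0", call. = FALSE)
  structure(list(age_start = starts, asfr = as.numeric(asfr), srb = srb),
            class = "fertility_schedule")
}

#' @export
print.fertility_schedule <- function(x, ...) {
  cat("<fertility_schedule> TFR =", round(tfr_from_asfr(x), 3),
      " srb =", x$srb, "\n")
  invisible(x)
}

#' Total fertility rate from a schedule
#'
#' TFR = 5 * sum of the nine 5-year-group rates: the number of births a
#' woman would have surviving through age 55 at current rates.
#'
#' @param sched a [fertility_schedule()].
#' @return the TFR (births per woman).
#' @export
tfr_from_asfr <- function(sched) {
  stopifnot(inherits(sched, "fertility_schedule"))
  5 * sum(sched$asfr)
}

#' Extend a 15-49 schedule to the terminal maternal age groups
#'
#' Rates for 10-14 and 50-54 are filled as fixed ratios of the adjacent
#' observed groups: `asfr(10-14) = r10 * asfr(15-19)` and
#' `asfr(50-54) = r50 * asfr(45-49)`.
#'
#' @param asfr_15_49 seven rates for groups 15-19 ... 45-49.
#' @param r10,r50 non-negative extension ratios (defaults 0.03 and 0.02).
#' @param srb sex ratio at birth for the returned schedule.
#' @return a complete nine-group [fertility_schedule()].
#' @export
extend_terminal_asfr <- function(asfr_15_49, r10 = 0.03, r50 = 0.02, srb = 1.05) {
  if (length(asfr_15_49) != 7) stop("need seven interior groups (15-49)", call. = FALSE)
  if (r10 < 0 || r50 < 0) stop("extension ratios must be >= 0", call. = FALSE)
  fertility_schedule(c(r10 * asfr_15_49[1], asfr_15_49, r50 * asfr_15_49[7]), srb = srb)
}

#' Births implied by a schedule and female population
#'
#' @param sched a [fertility_schedule()].
#' @param women female person-years (or mid-year counts) by maternal age
#'   group, nine values aligned with the schedule.
#' @return list with `total`, `female`, `male` births per year; the female
#'   share is `1 / (1 + srb)`.
#' @export
births_from_schedule <- function(sched, women) {
  stopifnot(inherits(sched, "fertility_schedule"))
  if (length(women) != 9) stop("need nine female population groups", call. = FALSE)
  if (any(women < 0)) stop("population must be >= 0", call. = FALSE)
  total <- sum(sched$asfr * women)
  fshare <- 1 / (1 + sched$srb)
  list(total = total, female = total * fshare, male = total * (1 - fshare))
}

#' Net reproduction rate and replacement-level TFR
#'
#' NRR is the expected number of daughters per woman under current fertility
#' and female mortality: `NRR = (1/(1+srb)) * sum_a asfr_a * (nLa / l0)`
#' over maternal age groups. Replacement TFR is the TFR the same age shape
#' would need for NRR = 1, i.e. `TFR / NRR` (a uniform rescaling of the
#' schedule scales NRR proportionally).
#'
#' @param sched a [fertility_schedule()].
#' @param female_lt a female `life_table` whose grid contains the 5-year
#'   maternal age groups 10-54.
#' @return list with `nrr` and `replacement_tfr`.
#' @export
nrr_and_replacement <- function(sched, female_lt) {
  stopifnot(inherits(sched, "fertility_schedule"))
  l0 <- female_lt$lx[1]
  surv <- vapply(sched$age_start, function(a) {
    i <- match(TRUE, abs(female_lt$age_start - a) < 1e-9)
    if (is.na(i) || female_lt$age_width[i] != 5) {
      stop("female life table must contain 5-year group starting at ", a, call. = FALSE)
    }
    female_lt$Lx[i] / l0
  }, numeric(1))
  nrr <- sum(sched$asfr * surv) / (1 + sched$srb)
  if (nrr == 0) stop("NRR is zero; replacement TFR undefined", call. = FALSE)
  list(nrr = nrr, replacement_tfr = tfr_from_asfr(sched) / nrr)
}

#' Completed cohort fertility by age 50
#'
#' Cumulates a single birth cohort's age-specific rates over ages 15-49
#' (plus 10-14 / 50-54 where supplied). Coverage must be complete: no
#' imputation is performed for missing ages.
#'
#' @param age_start starting exact age of each rate's interval.
#' @param asfr rates aligned with `age_start`.
#' @param width interval widths (single value or vector), default 1.
#' @return CCF50, births per woman.
#' @export
ccf50 <- function(age_start, asfr, width = 1) {
  if (length(width) == 1) width <- rep(width, length(age_start))
  if (length(asfr) != length(age_start)) stop("asfr/age mismatch", call. = FALSE)
  covered <- unlist(mapply(function(a, w) seq(a, a + w - 1), age_start, width,
                           SIMPLIFY = FALSE))
  if (!all(15:49 %in% covered)) {
    stop("incomplete cohort coverage of ages 15-49: missing ",
         paste(utils::head(setdiff(15:49, covered), 5), collapse = ","), call. = FALSE)
  }
  if (anyDuplicated(covered)) stop("overlapping cohort age intervals", call. = FALSE)
  sum(width * asfr)
}

#' Split observed total births into pseudo age-specific observations
#'
#' Second-round incorporation of sources that only report total births:
#' the total is allocated across maternal age groups in proportion to the
#' first-round expected births (first-round rate x female exposure), and
#' converted back to rates. The resulting pseudo-observations carry an
#' inflated variance so they weigh less than directly observed rates.
#'
#' @param first_round a [fertility_schedule()] from the first estimation
#'   round.
#' @param total_births observed total births for the location-year.
#' @param women female exposure by maternal age group (nine values).
#' @param variance_multiplier factor applied to the reference-source
#'   variance (default 4).
#' @param reference_variance per-group variance of the reference source.
#' @return data.frame with `age_start`, `asfr` (pseudo-observations) and
#'   `variance`.
#' @export
second_round_fertility <- function(first_round, total_births, women,
                                   variance_multiplier = 4,
                                   reference_variance = 1e-4) {
  stopifnot(inherits(first_round, "fertility_schedule"))
  expected <- first_round$asfr * women
  tot <- sum(expected)
  if (tot <= 0 && total_births > 0) {
    stop("first-round schedule implies zero births; cannot split observed total",
         call. = FALSE)
  }
  scale <- if (tot > 0) total_births / tot else 0
  data.frame(age_start = first_round$age_start,
             asfr = first_round$asfr * scale,
             variance = variance_multiplier * reference_variance)
}
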