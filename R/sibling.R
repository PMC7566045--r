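# Sibling survival histories: adult mortality (45q15) with survivor-bias
# weights. Because sibships are only observed through a surviving adult
# respondent, sibships with many survivors are over-sampled; weighting each
# sibship by (sibship size) / (surviving potential respondents) undoes the
# selection (the estimator remains conditional on at least one survivor).

#' Adult mortality from sibling survival histories
#'
#' Tallies person-years and deaths of reported siblings in ages 15-59
#' within each calendar period, weighting each sibship by
#' `sibship_size / surviving_respondents`, and converts the weighted
#' age-specific rates (5-year bands) to the probability of dying between
#' exact ages 15 and 60 under piecewise-constant hazards.
#'
#' @param records data.frame with one row per reported sibling:
#'   `respondent_id`, `birth_year`, `death_year` (`NA` if alive),
#'   `sibship_size`, `surviving_respondents` (>= 1), `survey_year`.
#' @param periods list of `c(start, end)` calendar windows (end exclusive).
#' @param weighted if `FALSE`, all weights are 1 (for bias comparisons).
#' @return data.frame with one row per period: `start`, `end`,
#'   `exposure_py`, `deaths`, `q45_15`.
#' @export
sibling_45q15 <- function(records, periods, weighted = TRUE) {
  req <- c("respondent_id", "birth_year", "death_year", "sibship_size",
           "surviving_respondents", "survey_year")
  if (!all(req %in% names(records))) {
    stop("records need columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (any(records$surviving_respondents < 1)) {
    stop("surviving potential respondents must be >= 1 for observed sibships",
         call. = FALSE)
  }
  died <- !is.na(records$death_year)
  if (any(records$death_year[died] < records$birth_year[died])) {
    stop("death before birth", call. = FALSE)
  }
  w <- if (weighted) records$sibship_size / records$surviving_respondents else
    rep(1, nrow(records))
  bands <- seq(15, 55, by = 5)
  out <- lapply(periods, function(p) {
    py <- numeric(length(bands)); dth <- numeric(length(bands))
    for (y in seq(p[1], p[2] - 1)) {
      age <- y - records$birth_year            # age during [y, y+1)
      alive <- is.na(records$death_year) | records$death_year >= y
      observed <- records$survey_year > y
      b <- findInterval(age, bands)
      inband <- age >= 15 & age < 60 & alive & observed
      for (k in seq_along(bands)) {
        sel <- inband & b == k
        if (!any(sel)) next
        # siblings dying this year contribute half a year of exposure
        dies_now <- sel & !is.na(records$death_year) & records$death_year == y
        py[k] <- py[k] + sum(w[sel]) - 0.5 * sum(w[dies_now])
        dth[k] <- dth[k] + sum(w[dies_now])
      }
    }
    if (sum(py) == 0) stop("no sibling exposure in period ", p[1], "-", p[2],
                           call. = FALSE)
    mx <- ifelse(py > 0, dth / py, 0)
    q <- 1 - prod(exp(-5 * mx))
    data.frame(start = p[1], end = p[2], exposure_py = sum(py),
               deaths = sum(dth), q45_15 = q)
  })
  do.call(rbind, out)
}
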