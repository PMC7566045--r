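# Death distribution methods for vital registration completeness: the
# generalised growth balance method (GGB), synthetic extinct generations
# (SEG), and the combined GGB-SEG, plus optimal age-trim selection and
# logit-space synthesis of completeness time series.

#' Intercensal registration dataset
#'
#' Two census age distributions bracketing a period of registered deaths,
#' the unit of analysis for death distribution methods.
#'
#' @param census1,census2 data.frames with `age_start` (5-year starts,
#'   terminal open) and `count`, on a common grid.
#' @param deaths data.frame with `age_start`, `count`: registered deaths
#'   over the whole intercensal period.
#' @param date1,date2 decimal census dates (`date1 < date2`).
#' @param location,sex metadata tags.
#' @return object of class `registration_dataset`.
#' @export
registration_dataset <- function(census1, census2, deaths, date1, date2,
                                 location = "loc", sex = "total") {
  if (date2 <= date1) stop("census dates must be ordered", call. = FALSE)
  ages <- census1$age_start
  if (!identical(ages, census2$age_start) || !identical(ages, deaths$age_start)) {
    stop("census and death ages must be on a common grid", call. = FALSE)
  }
  if (any(census1$count < 0) || any(census2$count < 0) || any(deaths$count < 0)) {
    stop("counts must be >= 0", call. = FALSE)
  }
  structure(list(ages = ages, N1 = census1$count, N2 = census2$count,
                 D = deaths$count, date1 = date1, date2 = date2,
                 location = location, sex = sex),
            class = "registration_dataset")
}

#' @export
print.registration_dataset <- function(x, ...) {
  cat("<registration_dataset> ", x$location, " ", x$date1, "-", x$date2,
      ", ", length(x$ages), " age groups, ", round(sum(x$D)), " registered deaths\n",
      sep = "")
  invisible(x)
}

completeness_estimate <- function(c, method, trim, k = NA_real_, diagnostics = list()) {
  if (c <= 0) stop(method, " produced non-positive completeness", call. = FALSE)
  structure(list(c = c, method = method, trim = trim, k = k,
                 diagnostics = diagnostics),
            class = "completeness_estimate")
}

#' @export
print.completeness_estimate <- function(x, ...) {
  cat("<completeness_estimate> c = ", round(x$c, 3), " (", x$method,
      ", trim ", x$trim[1], "-", x$trim[2],
      if (!is.na(x$k)) paste0(", k = ", round(x$k, 3)), ")\n", sep = "")
  invisible(x)
}

# orthogonal (total least squares) line y = a + b x
orthogonal_fit <- function(x, y) {
  mx <- mean(x); my <- mean(y)
  sxx <- mean((x - mx)^2); syy <- mean((y - my)^2); sxy <- mean((x - mx) * (y - my))
  if (abs(sxy) < 1e-300) stop("singular regression", call. = FALSE)
  b <- (syy - sxx + sqrt((syy - sxx)^2 + 4 * sxy^2)) / (2 * sxy)
  a <- my - b * mx
  # perpendicular residual RMSE
  res <- (y - a - b * x) / sqrt(1 + b^2)
  list(a = a, b = b, rmse = sqrt(mean(res^2)))
}

ggb_points <- function(ds) {
  T <- ds$date2 - ds$date1
  Nbar <- sqrt(ds$N1 * ds$N2)           # mid-period population by group
  Dann <- ds$D / T                       # annualised deaths
  ages <- ds$ages
  k <- length(ages)
  cumrev <- function(v) rev(cumsum(rev(v)))
  Nplus <- cumrev(Nbar); N1p <- cumrev(ds$N1); N2p <- cumrev(ds$N2)
  Dplus <- cumrev(Dann)
  idx <- 2:k                             # exact ages with a group below them
  entry <- (Nbar[idx - 1] + Nbar[idx]) / 10   # persons reaching exact age x per year
  r_plus <- log(N2p[idx] / N1p[idx]) / T
  data.frame(age = ages[idx],
             lhs = entry / Nplus[idx] - r_plus,
             rhs = Dplus[idx] / Nplus[idx])
}

trim_rows <- function(pts, trim) {
  sel <- pts$age >= trim[1] & pts$age <= trim[2]
  if (sum(sel) < 4) stop("need >= 4 age points inside trim", call. = FALSE)
  pts[sel, , drop = FALSE]
}

#' Generalised growth balance method
#'
#' Regresses the entry rate minus the growth rate of the open-ended
#' population above each age on the registered death rate above that age
#' (orthogonal regression over the trim ages). The slope estimates 1/c,
#' where c is the completeness of death registration relative to census
#' coverage; the intercept estimates the relative coverage of the two
#' censuses, `k = census2 : census1 = exp(-intercept * Dt)`.
#'
#' @param ds a [registration_dataset()].
#' @param trim `c(low, high)` exact-age range used for inference.
#' @return a `completeness_estimate` with method `"GGB"`, the coverage
#'   ratio `k`, and regression diagnostics.
#' @export
ggb <- function(ds, trim = c(15, 75)) {
  pts <- trim_rows(ggb_points(ds), trim)
  fit <- orthogonal_fit(pts$rhs, pts$lhs)
  T <- ds$date2 - ds$date1
  completeness_estimate(c = 1 / fit$b, method = "GGB", trim = trim,
                        k = exp(-fit$a * T),
                        diagnostics = list(intercept = fit$a, slope = fit$b,
                                           rmse = fit$rmse, points = pts))
}

#' Synthetic extinct generations method
#'
#' Reconstructs the population at each exact age from the registered
#' deaths above that age, grown by age-specific intercensal growth rates,
#' and takes the median ratio of reconstructed to observed population over
#' the trim ages as the completeness estimate.
#'
#' @param ds a [registration_dataset()].
#' @param trim exact-age range used for the ratio median.
#' @param k census-2:census-1 relative coverage correction (census 2 counts
#'   are divided by `k` before use), e.g. from [ggb()].
#' @param e_open remaining life expectancy at the open interval; `NULL`
#'   uses the stationary approximation `N(open)/D(open)`.
#' @return a `completeness_estimate` with method `"SEG"`.
#' @export
seg <- function(ds, trim = c(15, 75), k = 1, e_open = NULL) {
  if (k <= 0) stop("k must be > 0", call. = FALSE)
  T <- ds$date2 - ds$date1
  N2 <- ds$N2 / k
  Nbar <- sqrt(ds$N1 * N2)
  Dann <- ds$D / T
  ages <- ds$ages
  m <- length(ages)
  r <- log(pmax(N2, 1e-12) / pmax(ds$N1, 1e-12)) / T
  if (is.null(e_open)) {
    if (Dann[m] <= 0) stop("no deaths in the open interval; supply e_open", call. = FALSE)
    e_open <- Nbar[m] / Dann[m]
  }
  Nx <- numeric(m)                       # persons at exact age ages[i] per year
  re <- r[m] * e_open
  Nx[m] <- Dann[m] * (exp(re) - re^2 / 6)
  for (i in (m - 1):2) {
    w <- ages[i + 1] - ages[i]
    Nx[i] <- Nx[i + 1] * exp(w * r[i]) + Dann[i] * exp(w / 2 * r[i])
  }
  grp_hat <- numeric(m)
  for (i in 2:(m - 1)) {
    w <- ages[i + 1] - ages[i]
    grp_hat[i] <- w / 2 * (Nx[i] + Nx[i + 1])
  }
  sel <- ages >= trim[1] & ages <= trim[2] & seq_len(m) > 1 & seq_len(m) < m
  if (!any(sel)) stop("empty trim", call. = FALSE)
  ratios <- grp_hat[sel] / Nbar[sel]
  chat <- stats::median(ratios)
  completeness_estimate(c = chat, method = "SEG", trim = trim, k = k,
                        diagnostics = list(ratios = ratios,
                                           rmse = sqrt(mean((ratios - chat)^2))))
}

#' Combined GGB-SEG method
#'
#' Applies the census coverage ratio k estimated by [ggb()] and then runs
#' [seg()] on the coverage-corrected data.
#'
#' @inheritParams seg
#' @return a `completeness_estimate` with method `"GGB-SEG"`.
#' @export
ggb_seg <- function(ds, trim = c(15, 75), e_open = NULL) {
  g <- ggb(ds, trim)
  s <- seg(ds, trim, k = g$k, e_open = e_open)
  completeness_estimate(c = s$c, method = "GGB-SEG", trim = trim, k = g$k,
                        diagnostics = c(s$diagnostics, list(ggb = g)))
}

#' Choose the optimum age trim for a DDM
#'
#' Runs the method over each candidate trim and returns the trim whose fit
#' diagnostic (orthogonal-regression residual RMSE for GGB, dispersion of
#' the age-specific completeness ratios for SEG variants) is smallest;
#' ties, within numerical tolerance, go to the widest trim. Deterministic.
#'
#' @param ds a [registration_dataset()].
#' @param method `"ggb"`, `"seg"` or `"ggb_seg"`.
#' @param trims list of `c(low, high)` candidates.
#' @return list with `trim`, the winning `estimate`, and the per-candidate
#'   `diagnostics` table.
#' @export
select_age_trim <- function(ds, method = c("ggb", "seg", "ggb_seg"),
                            trims = list(c(5, 75), c(15, 75), c(25, 75),
                                         c(15, 65), c(25, 65))) {
  method <- match.arg(method)
  fn <- switch(method, ggb = ggb, seg = seg, ggb_seg = ggb_seg)
  res <- lapply(trims, function(tr) tryCatch(fn(ds, tr), error = function(e) NULL))
  ok <- !vapply(res, is.null, logical(1))
  if (!any(ok)) stop("all candidate trims infeasible", call. = FALSE)
  rmse <- vapply(res[ok], function(e) e$diagnostics$rmse, numeric(1))
  width <- vapply(trims[ok], diff, numeric(1))
  best <- min(rmse)
  cand <- which(rmse <= best + 1e-9)
  pick <- cand[which.max(width[cand])]
  tab <- data.frame(low = vapply(trims[ok], `[`, numeric(1), 1),
                    high = vapply(trims[ok], `[`, numeric(1), 2),
                    rmse = rmse, c = vapply(res[ok], `[[`, numeric(1), "c"))
  list(trim = trims[ok][[pick]], estimate = res[ok][[pick]], diagnostics = tab)
}

#' Synthesise a completeness time series
#'
#' Smooths point DDM estimates into an annual completeness series in
#' scaled-logit space (completeness bounded in (0, 1.5\]), using the child
#' registration completeness series as a covariate when supplied, via the
#' ST-GPR engine. For death-adjustment use the series is capped at 1; the
#' raw series is retained.
#'
#' @param ddm_points data.frame with `year`, `c`, optional `variance`
#'   (natural scale, default 0.01^2... of the scaled value).
#' @param years prediction years.
#' @param child_series optional data.frame `year`, `c_child` (completeness
#'   of under-5 registration) used as a covariate.
#' @param config an [stgpr_config()]; its transform is ignored (scaled
#'   logit is always used).
#' @return data.frame `year`, `mean`, `lower`, `upper` (raw scale) and
#'   `c_adjust` = `pmin(mean, 1)`.
#' @export
synthesize_completeness <- function(ddm_points, years,
                                    child_series = NULL,
                                    config = stgpr_config(amplitude = 0.5,
                                                          length_scale = 15,
                                                          n_draws = 500)) {
  if (!nrow(ddm_points)) stop("no DDM points", call. = FALSE)
  cap <- 1.5
  fwd <- function(c) logit(pmin(pmax(c / cap, 1e-4), 1 - 1e-4))
  inv <- function(y) cap * inv_logit(y)
  v <- if (!is.null(ddm_points$variance)) ddm_points$variance else rep(0.05^2, nrow(ddm_points))
  obs <- data.frame(location = "loc", year = ddm_points$year,
                    value = fwd(ddm_points$c),
                    variance = pmax(v * (1 / (pmin(pmax(ddm_points$c / cap, 1e-4), 1 - 1e-4) *
                                            (1 - pmin(pmax(ddm_points$c / cap, 1e-4), 1 - 1e-4)) * cap))^2,
                                    1e-6))
  grid <- data.frame(location = "loc", year = years)
  covs <- character()
  if (!is.null(child_series)) {
    obs$child <- stats::approx(child_series$year, child_series$c_child,
                               xout = obs$year, rule = 2)$y
    grid$child <- stats::approx(child_series$year, child_series$c_child,
                                xout = years, rule = 2)$y
    covs <- "child"
  }
  s1 <- fit_stage1(obs, grid, covariates = covs)
  s2 <- spacetime_smooth(s1$prior, obs, config = config)
  ds <- gp_posterior(s2, obs, config)
  ds$draws <- inv(ds$draws)
  summ <- summarize_draws(ds)
  data.frame(year = years, mean = rowMeans(ds$draws),
             lower = summ$lower, upper = summ$upper,
             c_adjust = pmin(rowMeans(ds$draws), 1))
}
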