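# Relational model life table system: a synthetic standard library, flexible
# standard selection, Brass-logit relational fitting to (5q0, 45q15) targets,
# Kannisto old-age extension, and shock/HIV envelope assembly.

siler_hazard <- function(x, a1, b1, a2, a3, b3) {
  a1 * exp(-b1 * x) + a2 + a3 * exp(b3 * x)
}

# interval-averaged Siler hazard over [x, x+n)
siler_interval_mx <- function(start, width, a1, b1, a2, a3, b3) {
  ifelse(is.finite(width),
         a1 * (exp(-b1 * start) - exp(-b1 * (start + width))) / (b1 * width) +
           a2 + a3 * (exp(b3 * (start + width)) - exp(b3 * start)) / (b3 * width),
         siler_hazard(start + 4, a1, b1, a2, a3, b3))
}

#' Synthetic standard life table library
#'
#' Builds a library of standard life tables from a two-way grid of
#' parametric (Siler) hazard schedules: a declining infant/child component,
#' a constant background, and a senescent exponential component. The grid
#' is chosen so the standards span roughly 5q0 in \[0.003, 0.25\] and 45q15
#' in \[0.05, 0.6\], playing the role of an empirical life table collection
#' at desk scale. Each standard passes deterministic shape checks: hazard
#' monotone above age 30 and survivorship strictly decreasing.
#'
#' @param n_child,n_adult grid sizes for the child and adult mortality
#'   dimensions (default 5 x 5 = 25 standards).
#' @param sex tag recorded on every standard.
#' @return a `standard_library`: list of standards, each with `id`, `sex`,
#'   `lx` (radix 1, on the gbd23 grid), `mx`, `q5_0`, `q45_15`.
#' @export
standard_library <- function(n_child = 5, n_adult = 5, sex = "total") {
  grid <- build_age_grid("gbd23")
  a1s <- exp(seq(log(0.0018), log(0.32), length.out = n_child))
  a3s <- exp(seq(log(1.4e-5), log(2.2e-4), length.out = n_adult))
  lib <- list()
  for (i in seq_along(a1s)) {
    for (j in seq_along(a3s)) {
      mx <- siler_interval_mx(grid$age_start, grid$age_width,
                              a1 = a1s[i], b1 = 1.1,
                              a2 = 4e-4 + 1.1e-3 * (j - 1) / max(1, n_adult - 1),
                              a3 = a3s[j], b3 = 0.095)
      lt <- lifetable_from_mx(mx, grid, ax_rule = "constant_hazard", radix = 1)
      sp <- summary_probabilities(lt)
      old <- lt$age_start >= 30 & is.finite(lt$age_width)
      stopifnot(!is.unsorted(lt$mx[old]), all(diff(lt$lx) < 0))
      lib[[length(lib) + 1]] <- list(
        id = sprintf("std_%02d_%02d", i, j), sex = sex,
        lx = lt$lx, mx = mx, q5_0 = sp$q5_0, q45_15 = sp$q45_15
      )
    }
  }
  structure(lib, class = "standard_library", grid = grid)
}

#' @export
print.standard_library <- function(x, ...) {
  q5 <- vapply(x, `[[`, numeric(1), "q5_0")
  q45 <- vapply(x, `[[`, numeric(1), "q45_15")
  cat("<standard_library> ", length(x), " standards, 5q0 in [",
      signif(min(q5), 3), ", ", signif(max(q5), 3), "], 45q15 in [",
      signif(min(q45), 3), ", ", signif(max(q45), 3), "]\n", sep = "")
  invisible(x)
}

#' Flexible standard selection
#'
#' Finds the `k` standards nearest to the target summary pair in
#' (logit 5q0, logit 45q15) space and pools them by inverse-distance
#' weighting of their logit-survivorship schedules. An exact match returns
#' that standard unchanged.
#'
#' @param lib a [standard_library()].
#' @param target list or vector with `q5_0` and `q45_15` in (0,1).
#' @param k number of neighbours to pool (>= 1).
#' @return list with `lx` (pooled standard, radix 1), `ids` and `weights`.
#' @export
select_standard <- function(lib, target, k = 5) {
  if (!length(lib)) stop("empty standard library", call. = FALSE)
  k <- min(k, length(lib))
  tq5 <- logit(target[["q5_0"]]); tq45 <- logit(target[["q45_15"]])
  d <- vapply(lib, function(s) {
    sqrt((logit(s$q5_0) - tq5)^2 + (logit(s$q45_15) - tq45)^2)
  }, numeric(1))
  ord <- order(d)[seq_len(k)]
  if (d[ord[1]] < 1e-12) {
    s <- lib[[ord[1]]]
    return(list(lx = s$lx, ids = s$id, weights = 1))
  }
  w <- 1 / d[ord]; w <- w / sum(w)
  # average in Y = logit(1 - lx) space (interior boundaries), keep l0 = 1
  Y <- sapply(lib[ord], function(s) logit(1 - s$lx[-1] / s$lx[1]))
  lx <- c(1, 1 - inv_logit(drop(Y %*% w)))
  list(lx = lx, ids = vapply(lib[ord], `[[`, character(1), "id"), weights = w)
}

relational_lx <- function(standard_lx, alpha, beta) {
  Ys <- logit(1 - standard_lx[-1] / standard_lx[1])
  c(1, 1 - inv_logit(alpha + beta * Ys))
}

#' Fit the Brass-logit relational model to mortality targets
#'
#' Solves for the level and slope `(alpha, beta)` of
#' `Y(x) = alpha + beta * Y_standard(x)`, where
#' `Y(x) = logit(1 - lx/l0)`, such that the produced life table matches the
#' target 5q0 and 45q15. Given beta, alpha is determined in closed form by
#' the 5q0 constraint; beta is then found by safeguarded one-dimensional
#' root finding on the 45q15 constraint within \[0.3, 3\] (expanded if
#' needed), achieving both targets to 1e-8 or better.
#'
#' @param standard_lx standard survivorship (radix 1) on the gbd23 grid, as
#'   returned by [select_standard()].
#' @param target list/vector with `q5_0` and `q45_15`, each in (0,1).
#' @param grid the age grid of `standard_lx` (default gbd23).
#' @param terminal_mx open-interval death rate for the rebuilt table;
#'   `NULL` extrapolates as 1.5x the last closed-interval rate.
#' @return list with `alpha`, `beta`, `lx`, and `lt` (a full `life_table`
#'   rebuilt from the fitted survivorship under piecewise-constant hazards).
#' @export
fit_relational <- function(standard_lx, target, grid = build_age_grid("gbd23"),
                           terminal_mx = NULL) {
  q5 <- target[["q5_0"]]; q45 <- target[["q45_15"]]
  if (q5 <= 0 || q5 >= 1 || q45 <= 0 || q45 >= 1) {
    stop("targets must lie in (0,1)", call. = FALSE)
  }
  i5 <- match(TRUE, abs(grid$age_start - 5) < 1e-9)
  i15 <- match(TRUE, abs(grid$age_start - 15) < 1e-9)
  i60 <- match(TRUE, abs(grid$age_start - 60) < 1e-9)
  Ys <- logit(1 - standard_lx[-1] / standard_lx[1])
  ys5 <- Ys[i5 - 1]; ys15 <- Ys[i15 - 1]; ys60 <- Ys[i60 - 1]
  alpha_of <- function(beta) logit(q5) - beta * ys5
  f <- function(beta) {
    a <- alpha_of(beta)
    l15 <- 1 - inv_logit(a + beta * ys15)
    l60 <- 1 - inv_logit(a + beta * ys60)
    (1 - l60 / l15) - q45
  }
  lo <- 0.3; hi <- 3
  while (f(lo) * f(hi) > 0 && hi < 64) { lo <- lo / 2; hi <- hi * 2 }
  if (f(lo) * f(hi) > 0) {
    stop("no relational root for targets (5q0 = ", q5, ", 45q15 = ", q45,
         "); residual at box edges: ", signif(f(lo), 3), ", ", signif(f(hi), 3),
         call. = FALSE)
  }
  beta <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  alpha <- alpha_of(beta)
  lx <- relational_lx(standard_lx, alpha, beta)
  n <- grid$age_width
  kk <- length(lx)
  mx <- c(log(lx[-kk] / lx[-1]) / n[-kk], NA)
  mx[kk] <- if (is.null(terminal_mx)) 1.5 * mx[kk - 1] else terminal_mx
  lt <- lifetable_from_mx(pmax(mx, 1e-12), grid, ax_rule = "constant_hazard")
  list(alpha = alpha, beta = beta, lx = lx, lt = lt)
}

#' Kannisto old-age mortality extension
#'
#' Fits the logistic (Kannisto) hazard `mu(x) = A e^{Bx} / (1 + A e^{Bx})`
#' to observed rates for ages 60-89 -- linear regression of logit(mx) on
#' interval midpoints -- and extrapolates to 90-94 and the open interval
#' 95+ (evaluated at ages 92.5 and 100). The extension is non-decreasing
#' and bounded above by the asymptote 1.
#'
#' @param mx observed death rates for consecutive 5-year groups ending at
#'   85-89 (at least 4 groups, all positive, all < 1).
#' @param age_start starting ages matching `mx` (default 60, 65, ..., 85).
#' @return list with `A`, `B`, `mx_90_94`, `mx_95plus` and the fitted
#'   function `hazard(x)`.
#' @export
extend_old_age <- function(mx, age_start = seq(60, 85, by = 5)) {
  if (length(mx) < 4) stop("need at least 4 age groups", call. = FALSE)
  if (any(mx <= 0)) stop("non-positive input rates", call. = FALSE)
  if (any(mx >= 1)) stop("rates must be < 1 for the logistic fit", call. = FALSE)
  mid <- age_start + 2.5
  fit <- stats::lm(logit(mx) ~ mid)
  A <- exp(unname(stats::coef(fit)[1]))
  B <- unname(stats::coef(fit)[2])
  hazard <- function(x) { z <- A * exp(B * x); z / (1 + z) }
  list(A = A, B = B,
       mx_90_94 = hazard(92.5), mx_95plus = hazard(100),
       hazard = hazard)
}

#' Disaggregate a shock event by age and sex
#'
#' Allocates an event's all-age both-sex death total across age-sex cells
#' in proportion to a cause-specific global pattern rate times the local
#' population, rescaled so the allocation sums exactly to the event total.
#'
#' @param total_deaths event total (>= 0).
#' @param population data.frame with columns `sex`, `age_start`, `count`.
#' @param pattern data.frame with columns `sex`, `age_start`, `rate_weight`
#'   (>= 0), matched to `population` rows by sex and age.
#' @return `population` with a `deaths` column added.
#' @export
disaggregate_shock <- function(total_deaths, population, pattern) {
  if (total_deaths < 0) stop("deaths must be >= 0", call. = FALSE)
  key <- paste(pattern$sex, pattern$age_start)
  idx <- match(paste(population$sex, population$age_start), key)
  if (anyNA(idx)) stop("pattern does not cover all population cells", call. = FALSE)
  w <- pattern$rate_weight[idx] * population$count
  if (any(w < 0)) stop("pattern rates must be >= 0", call. = FALSE)
  if (sum(w) == 0 && total_deaths > 0) {
    stop("all-zero pattern x population with positive deaths", call. = FALSE)
  }
  population$deaths <- if (sum(w) > 0) total_deaths * w / sum(w) else 0 * w
  population
}

#' Assemble the all-cause mortality envelope
#'
#' Adds HIV mortality rates and shock deaths to an HIV-free schedule as a
#' simple rate addition (no competing-risk correction), returns the total
#' death counts and the life table rebuilt from the implied rates.
#'
#' @param hiv_free_mx HIV-free death rates per grid interval.
#' @param hiv_mx HIV-specific death rates (same grid), default 0.
#' @param shock_deaths shock death counts per interval, default 0.
#' @param person_years population exposure per interval (> 0).
#' @param grid the age grid.
#' @param ax_rule passed to [lifetable_from_mx()].
#' @return list with `deaths` (total per interval), `mx` and `lt`.
#' @export
assemble_all_cause <- function(hiv_free_mx, hiv_mx = 0, shock_deaths = 0,
                               person_years, grid,
                               ax_rule = "constant_hazard") {
  grid <- stopifnot_grid(grid)
  if (any(hiv_free_mx < 0) || any(hiv_mx < 0) || any(shock_deaths < 0)) {
    stop("negative mortality components", call. = FALSE)
  }
  hiv_mx <- rep_len(hiv_mx, nrow(grid))
  shock_deaths <- rep_len(shock_deaths, nrow(grid))
  mx <- hiv_free_mx + hiv_mx + shock_deaths / person_years
  deaths <- mx * person_years
  list(deaths = deaths, mx = mx,
       lt = lifetable_from_mx(mx, grid, ax_rule = ax_rule))
}
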