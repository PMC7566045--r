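# Sullivan healthy life expectancy, the Socio-demographic Index, and
# expected outcomes given SDI via an ensemble of cubic splines with linear
# tails.

#' Sullivan healthy life expectancy
#'
#' Weights each interval's person-years by the fraction of the year lived
#' free of disability: `HALE(x) = sum_{a >= x} La * (1 - yld_a) / lx`
#' (abridged form, no within-interval interpolation of the YLD rate).
#'
#' @param lt a `life_table`.
#' @param yld years lived with disability per person-year by age group
#'   (values in \[0, 1)), aligned with the life-table grid.
#' @return numeric vector of HALE at the start of each age group.
#' @export
#' @examples
#' g <- build_age_grid("gbd23")
#' lt <- lifetable_from_mx(rep(0.02, 23), g, "constant_hazard")
#' all.equal(sullivan_hale(lt, rep(0, 23)), lt$ex) # yld = 0 recovers ex
sullivan_hale <- function(lt, yld) {
  if (length(yld) != nrow(lt)) stop("yld must align with the life table grid", call. = FALSE)
  if (any(yld < 0 | yld >= 1)) stop("yld must lie in [0, 1)", call. = FALSE)
  healthy <- lt$Lx * (1 - yld)
  Th <- rev(cumsum(rev(healthy)))
  ifelse(lt$lx > 0, Th / lt$lx, 0)
}

#' Socio-demographic Index
#'
#' Geometric mean of three min-max scaled components: lag-distributed
#' income per capita (log scale), mean years of schooling, and total
#' fertility under age 25 (inverted: lower fertility scores higher).
#' Components are clamped to their declared bounds before scaling.
#'
#' @param income,schooling,tfu25 component values (vectors recycle).
#' @param bounds list with `income`, `schooling`, `tfu25`, each
#'   `c(worst, best)`; note for `tfu25` "worst" is the *high* fertility
#'   bound. Income is scaled on the log scale.
#' @return SDI values in \[0, 1\].
#' @export
compute_sdi <- function(income, schooling, tfu25,
                        bounds = list(income = c(250, 60000),
                                      schooling = c(0, 17),
                                      tfu25 = c(3, 0))) {
  scale01 <- function(x, b, log_scale = FALSE) {
    if (log_scale) { x <- log(x); b <- log(b) }
    if (b[1] == b[2]) stop("degenerate bounds", call. = FALSE)
    pmin(pmax((x - b[1]) / (b[2] - b[1]), 0), 1)
  }
  i <- scale01(income, bounds$income, log_scale = TRUE)
  s <- scale01(schooling, bounds$schooling)
  f <- scale01(tfu25, bounds$tfu25)  # bounds reversed: high fertility -> 0
  (i * s * f)^(1 / 3)
}

# draw interior knots in [0.1, 0.8] with pairwise gaps >= 0.1 (rejection)
draw_knots <- function(n_interior = 3) {
  repeat {
    k <- sort(stats::runif(n_interior, 0.1, 0.8))
    if (n_interior < 2 || all(diff(k) >= 0.1)) return(k)
  }
}

#' Ensemble of cubic splines with linear tails
#'
#' Fits `n_models` cubic-spline regressions of an outcome (in transform
#' space) on a predictor in \[0, 1\]. Each member has five knots -- the two
#' boundary knots at 0 and 1 plus three interior knots drawn uniformly in
#' \[0.1, 0.8\] with minimum inter-knot distance 0.1 -- and its left-most
#' and right-most segments are enforced to be linear with slopes matching
#' the adjacent interior segments (a natural cubic spline on the interior
#' knots). The ensemble prediction is the uniformly weighted member mean.
#' Optional symmetric residual trimming refits each member after dropping
#' the largest residuals.
#'
#' @param x predictor values (>= 30 points recommended, spanning (0,1)).
#' @param y outcome values (transform space).
#' @param n_models ensemble size (default 50).
#' @param seed integer seed for knot placement.
#' @param trim fraction of observations trimmed symmetrically per member
#'   (default 0 for determinism; 0.1 mimics trimmed meta-regression).
#' @param weights member weights (default uniform).
#' @return object of class `spline_ensemble` with a [predict()] method.
#' @export
fit_spline_ensemble <- function(x, y, n_models = 50, seed = 1L, trim = 0,
                                weights = NULL) {
  if (length(x) != length(y)) stop("x/y length mismatch", call. = FALSE)
  if (length(x) < 8) stop("too few points for a spline member", call. = FALSE)
  set.seed(as.integer(seed))
  make_basis <- function(kn) {
    force(kn)
    function(xx) splines::ns(xx, knots = kn[2], Boundary.knots = kn[c(1, 3)])
  }
  members <- vector("list", n_models)
  for (m in seq_len(n_models)) {
    kn <- draw_knots(3)
    basis <- make_basis(kn)
    fit_once <- function(keep) {
      X <- cbind(1, basis(x[keep]))
      stats::lm.fit(X, y[keep])$coefficients
    }
    keep <- seq_along(x)
    beta <- fit_once(keep)
    if (trim > 0) {
      B <- cbind(1, basis(x))
      res <- abs(y - drop(B %*% beta))
      keep <- order(res)[seq_len(ceiling((1 - trim) * length(x)))]
      beta <- fit_once(keep)
    }
    members[[m]] <- list(knots = kn, beta = beta, basis = basis)
  }
  if (is.null(weights)) weights <- rep(1 / n_models, n_models)
  weights <- weights / sum(weights)
  structure(list(members = members, weights = weights,
                 range_y = range(y), n = length(x)),
            class = "spline_ensemble")
}

#' @export
predict.spline_ensemble <- function(object, newdata, ...) {
  xx <- if (is.list(newdata)) newdata[[1]] else newdata
  preds <- vapply(object$members, function(m) {
    drop(cbind(1, m$basis(xx)) %*% m$beta)
  }, numeric(length(xx)))
  if (length(xx) == 1) preds <- matrix(preds, nrow = 1)
  drop(preds %*% object$weights)
}

#' @export
print.spline_ensemble <- function(x, ...) {
  cat("<spline_ensemble> ", length(x$members), " members, fitted to ",
      x$n, " points\n", sep = "")
  invisible(x)
}

#' Expected mortality and life expectancy at a given SDI
#'
#' Given per-age-group (and per-sex, if desired) spline ensembles fitted to
#' log death rates against SDI, predicts the expected mx schedule at an
#' SDI value, builds the life table and reports expected life expectancy
#' at birth. SDI values outside \[0,1\] extrapolate along the linear tails
#' with a warning.
#'
#' @param ensembles list of `spline_ensemble` objects, one per age group
#'   of `grid`, fitted on the log-mortality scale.
#' @param sdi the SDI value at which to predict.
#' @param grid the age grid of the schedules.
#' @param observed_mx optional observed schedule; when given, the result
#'   includes `e0_diff` = e0(observed) - e0(expected).
#' @param ax_rule passed to [lifetable_from_mx()].
#' @return list with `mx` (expected schedule), `lt`, `e0`, and optionally
#'   `e0_observed`, `e0_diff`.
#' @export
expected_mortality_le <- function(ensembles, sdi, grid = build_age_grid("gbd23"),
                                  observed_mx = NULL, ax_rule = "constant_hazard") {
  grid <- stopifnot_grid(grid)
  if (length(ensembles) != nrow(grid)) {
    stop("need one ensemble per age group", call. = FALSE)
  }
  if (sdi < 0 || sdi > 1) {
    warning("SDI outside [0,1]; extrapolating along linear tails")
  }
  mx <- vapply(ensembles, function(e) exp(predict(e, sdi)), numeric(1))
  lt <- lifetable_from_mx(mx, grid, ax_rule = ax_rule)
  out <- list(mx = mx, lt = lt, e0 = lt$ex[1])
  if (!is.null(observed_mx)) {
    e_obs <- lifetable_from_mx(observed_mx, grid, ax_rule = ax_rule)$ex[1]
    out$e0_observed <- e_obs
    out$e0_diff <- e_obs - out$e0
  }
  out
}

#' Rake an expected fertility schedule to an expected TFR
#'
#' Uniform multiplicative scaling so the schedule's TFR equals the target
#' exactly.
#'
#' @param sched a [fertility_schedule()].
#' @param target_tfr the expected TFR (> 0 requires a nonzero schedule).
#' @return the raked `fertility_schedule`.
#' @export
rake_expected_fertility <- function(sched, target_tfr) {
  cur <- tfr_from_asfr(sched)
  if (cur == 0 && target_tfr > 0) {
    stop("cannot rake a zero schedule to a positive TFR", call. = FALSE)
  }
  factor <- if (cur > 0) target_tfr / cur else 0
  fertility_schedule(sched$asfr * factor, srb = sched$srb)
}
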