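# Three-stage data synthesis engine: covariate prior (linear mixed model on
# standard locations), space-time residual smoothing, and Gaussian-process
# regression with draw-based uncertainty. All stages operate in transform
# space (logit for probabilities/completeness, log for rates); the driver
# stgpr() handles transformation and back-transformation.

#' ST-GPR configuration
#'
#' @param transform `"logit"`, `"log"` or `"identity"`; the space in which
#'   all three stages operate. Logit keeps bounded quantities in (0,1)
#'   after back-transform, log keeps rates positive.
#' @param lambda time-weight decay for the space-time stage: the weight on
#'   a residual `dt` years away is `1 - (dt / (1 + dt_max))^lambda`.
#' @param zeta spatial borrowing weight in (0,1\]: residuals from sibling
#'   locations (same parent) are down-weighted by `zeta`, all others by
#'   `zeta^2`.
#' @param omega age-weight decay: residuals `k` age groups away are
#'   down-weighted by `exp(-omega * k)`.
#' @param amplitude,length_scale squared-exponential GP kernel parameters
#'   (transform-space SD and years).
#' @param n_draws posterior draws per cell (>= 2; 1000 gives the 25th/975th
#'   order-statistic uncertainty interval).
#' @param shrink_n random-intercept shrinkage constant: a location with n
#'   observations gets `n / (n + shrink_n)` of its mean residual.
#' @param seed master seed; each (stage, location) pair gets its own
#'   deterministic stream.
#' @return a list of class `stgpr_config`.
#' @export
stgpr_config <- function(transform = c("logit", "log", "identity"),
                         lambda = 0.7, zeta = 0.9, omega = 1.0,
                         amplitude = 0.3, length_scale = 12,
                         n_draws = 1000, shrink_n = 1, seed = 1L) {
  transform <- match.arg(transform)
  stopifnot(lambda >= 0, zeta > 0, zeta <= 1, omega >= 0,
            amplitude > 0, length_scale > 0, n_draws >= 2)
  structure(list(transform = transform, lambda = lambda, zeta = zeta,
                 omega = omega, amplitude = amplitude,
                 length_scale = length_scale, n_draws = as.integer(n_draws),
                 shrink_n = shrink_n, seed = as.integer(seed)),
            class = "stgpr_config")
}

transform_fns <- function(transform) {
  switch(transform,
    logit = list(fwd = logit, inv = inv_logit,
                 dfwd = function(p) 1 / (p * (1 - p))),
    log = list(fwd = log, inv = exp, dfwd = function(x) 1 / x),
    identity = list(fwd = identity, inv = identity, dfwd = function(x) 1)
  )
}

#' Stage 1: covariate prior via a linear mixed model
#'
#' Fixed covariate effects are fit by precision-weighted least squares on
#' observations from *standard locations* only; location random intercepts
#' are shrunken mean residuals (`n/(n+shrink_n)`), nested so that a
#' location with no data inherits its parent's intercept.
#'
#' @param obs data.frame with columns `location`, `year`, `value`
#'   (transform space), `variance`, optional covariate columns.
#' @param pred_grid data.frame of `location`, `year` (plus covariate
#'   columns when `covariates` is non-empty) at which to predict.
#' @param covariates character vector of covariate column names (may be
#'   empty for an intercept-only prior).
#' @param hierarchy data.frame `location`, `parent` (`NA` for the root);
#'   `NULL` treats all locations as siblings under one root.
#' @param standard_locations locations whose data identify the fixed
#'   effects; default all observed locations.
#' @return list with `beta`, `se`, `re` (named location intercepts) and
#'   `prior` (`pred_grid` plus a `mean` column).
#' @export
fit_stage1 <- function(obs, pred_grid, covariates = character(),
                       hierarchy = NULL, standard_locations = NULL,
                       shrink_n = 1) {
  if (is.null(standard_locations)) standard_locations <- unique(obs$location)
  std <- obs[obs$location %in% standard_locations, , drop = FALSE]
  if (!nrow(std)) stop("no observations in standard locations", call. = FALSE)
  form <- if (length(covariates)) {
    stats::reformulate(covariates, response = "value")
  } else {
    value ~ 1
  }
  fit <- stats::lm(form, data = std, weights = 1 / std$variance)
  if (any(is.na(stats::coef(fit)))) stop("rank-deficient stage-1 design", call. = FALSE)
  fixed_at <- function(df) as.numeric(stats::predict(fit, newdata = df))
  resid_all <- obs$value - fixed_at(obs)

  locs <- unique(c(obs$location, pred_grid$location,
                   hierarchy$location, hierarchy$parent))
  locs <- locs[!is.na(locs)]
  own <- vapply(locs, function(l) {
    r <- resid_all[obs$location == l]
    if (!length(r)) return(NA_real_)
    length(r) / (length(r) + shrink_n) * mean(r)
  }, numeric(1))
  names(own) <- locs
  parent_of <- function(l) {
    if (is.null(hierarchy)) return(NA_character_)
    p <- hierarchy$parent[match(l, hierarchy$location)]
    if (length(p)) p else NA_character_
  }
  re <- vapply(locs, function(l) {
    v <- own[[l]]
    p <- parent_of(l)
    while (is.na(v) && !is.na(p)) {
      # parent intercept: shrunken mean residual over all data under it
      desc <- hierarchy$location[hierarchy$parent == p & !is.na(hierarchy$parent)]
      r <- resid_all[obs$location %in% c(p, desc)]
      v <- if (length(r)) length(r) / (length(r) + shrink_n) * mean(r) else NA_real_
      p <- parent_of(p)
    }
    if (is.na(v)) 0 else v
  }, numeric(1))
  names(re) <- locs

  prior <- pred_grid
  prior$mean <- fixed_at(pred_grid) + re[as.character(pred_grid$location)]
  # vcov warns on degenerate perfect fits (e.g. constant toy data)
  se <- suppressWarnings(sqrt(diag(stats::vcov(fit))))
  list(beta = stats::coef(fit), se = se, re = re, prior = prior)
}

#' Estimate source random effects against a prior surface
#'
#' @param obs observations with `source_id`; `prior_mean` the stage-1 mean
#'   evaluated at each observation.
#' @return named vector of mean residuals by source.
#' @export
estimate_source_effects <- function(obs, prior_mean) {
  tapply(obs$value - prior_mean, obs$source_id, mean)
}

#' Shift non-reference sources onto the reference source's level
#'
#' Each observation from a non-reference source is shifted in transform
#' space by the difference between the reference source's random effect and
#' its own; variances are unchanged.
#'
#' @param obs observations with `source_id` column.
#' @param source_re named numeric vector of source random effects.
#' @param reference_source the designated reference source id.
#' @return `obs` with adjusted `value`.
#' @export
adjust_source_bias <- function(obs, source_re, reference_source) {
  if (is.na(reference_source) || !reference_source %in% names(source_re)) {
    stop("missing reference source designation", call. = FALSE)
  }
  shift <- source_re[[reference_source]] - source_re[as.character(obs$source_id)]
  shift[is.na(shift)] <- 0
  obs$value <- obs$value + shift
  obs
}

st_weights <- function(dt, dt_max, sibling, same_loc, dage, config) {
  wt <- 1 - (dt / (1 + dt_max))^config$lambda
  ws <- ifelse(same_loc, 1, ifelse(sibling, config$zeta, config$zeta^2))
  wa <- exp(-config$omega * dage)
  wt * ws * wa
}

#' Stage 2: space-time residual smoothing
#'
#' Residuals of the observations against the stage-1 prior are averaged
#' into each prediction cell with multiplicative time, space and age
#' weights (normalised to sum to one per cell) and added to the prior.
#' Cells with no residual data anywhere keep the prior unchanged.
#'
#' @param prior output of [fit_stage1()]`$prior` (may carry an `age_index`
#'   column for age-structured smoothing).
#' @param obs observations (same columns as [fit_stage1()]; `age_index`
#'   optional).
#' @param hierarchy as in [fit_stage1()].
#' @param config an [stgpr_config()].
#' @return `prior` with a `mean` column replaced by the stage-2 surface and
#'   a `residual` column with the smoothed residual.
#' @export
spacetime_smooth <- function(prior, obs, hierarchy = NULL, config = stgpr_config()) {
  key <- function(df) paste(df$location, df$year,
                            if (!is.null(df$age_index)) df$age_index else 0)
  pm <- prior$mean[match(key(obs), key(prior))]
  if (anyNA(pm)) stop("observations outside the prediction grid", call. = FALSE)
  rdf <- data.frame(location = obs$location, year = obs$year,
                    age_index = if (!is.null(obs$age_index)) obs$age_index else 0,
                    r = obs$value - pm)
  parent <- function(l) {
    if (is.null(hierarchy)) return("root")
    p <- hierarchy$parent[match(l, hierarchy$location)]
    if (is.na(p)) "root" else p
  }
  rpar <- vapply(as.character(rdf$location), parent, character(1))
  dt_max <- max(abs(outer(unique(prior$year), unique(rdf$year), "-")))
  page <- if (!is.null(prior$age_index)) prior$age_index else rep(0, nrow(prior))
  smoothed <- vapply(seq_len(nrow(prior)), function(i) {
    dt <- abs(rdf$year - prior$year[i])
    w <- st_weights(dt, dt_max,
                    sibling = rpar == parent(as.character(prior$location[i])),
                    same_loc = rdf$location == prior$location[i],
                    dage = abs(rdf$age_index - page[i]), config)
    if (sum(w) == 0) return(0)
    sum(w * rdf$r) / sum(w)
  }, numeric(1))
  prior$residual <- smoothed
  prior$mean <- prior$mean + smoothed
  prior
}

#' Stage 3: Gaussian-process posterior and draws
#'
#' Per location, a GP over calendar time with the stage-2 surface as mean
#' function, a squared-exponential kernel, and heteroskedastic observation
#' noise equal to each point's data variance. Draws are sampled from the
#' posterior with one deterministic stream per location.
#'
#' @param stage2 data.frame `location`, `year`, `mean` (transform space).
#' @param obs observations as before.
#' @param config an [stgpr_config()].
#' @return a `draw_set`: list with `cells` (location, year, posterior mean
#'   and SD) and `draws` (cells x n_draws matrix), transform recorded.
#' @export
gp_posterior <- function(stage2, obs, config = stgpr_config()) {
  cells <- NULL; draws <- NULL
  for (loc in unique(stage2$location)) {
    p <- stage2[stage2$location == loc, , drop = FALSE]
    p <- p[order(p$year), , drop = FALSE]
    o <- obs[obs$location == loc, , drop = FALSE]
    tstar <- p$year
    K <- function(a, b) config$amplitude^2 *
      exp(-outer(a, b, "-")^2 / (2 * config$length_scale^2))
    if (nrow(o)) {
      prior_at <- stats::approx(p$year, p$mean, xout = o$year, rule = 2)$y
      Koo <- K(o$year, o$year) + diag(o$variance, nrow(o)) +
        diag(1e-9, nrow(o))
      Kso <- K(tstar, o$year)
      L <- chol(Koo)
      a <- backsolve(L, forwardsolve(t(L), o$value - prior_at))
      mu <- p$mean + drop(Kso %*% a)
      V <- forwardsolve(t(L), t(Kso))
      Sig <- K(tstar, tstar) - crossprod(V)
    } else {
      mu <- p$mean
      Sig <- K(tstar, tstar)
    }
    Sig <- (Sig + t(Sig)) / 2 + diag(1e-10, length(tstar))
    ev <- eigen(Sig, symmetric = TRUE)
    ev$values[ev$values < 0] <- 0
    Rt <- ev$vectors %*% (sqrt(ev$values) * t(ev$vectors))
    set.seed(derive_seed(config$seed, c("gp", loc)))
    Z <- matrix(stats::rnorm(length(tstar) * config$n_draws), length(tstar))
    D <- mu + Rt %*% Z
    cells <- rbind(cells, data.frame(location = loc, year = tstar,
                                     mean = mu, sd = sqrt(pmax(diag(Sig), 0))))
    draws <- rbind(draws, D)
  }
  structure(list(cells = cells, draws = draws, transform = config$transform),
            class = "draw_set")
}

#' @export
print.draw_set <- function(x, ...) {
  cat("<draw_set> ", nrow(x$cells), " cells x ", ncol(x$draws),
      " draws (transform: ", x$transform, ")\n", sep = "")
  invisible(x)
}

#' Summarise a draw set
#'
#' Mean and the 95% uncertainty interval taken as the 25th and 975th order
#' statistics when there are 1000 draws (nearest-rank quantiles otherwise).
#'
#' @param ds a `draw_set` or a plain draws matrix (cells x draws).
#' @return data.frame with `mean`, `lower`, `upper` (plus cell columns when
#'   available).
#' @export
summarize_draws <- function(ds) {
  draws <- if (inherits(ds, "draw_set")) ds$draws else as.matrix(ds)
  if (!length(draws)) stop("empty draw set", call. = FALSE)
  n <- ncol(draws)
  lo_r <- max(1L, as.integer(ceiling(0.025 * n)))
  hi_r <- max(1L, as.integer(ceiling(0.975 * n)))
  srt <- t(apply(draws, 1, sort))
  out <- data.frame(mean = rowMeans(draws),
                    lower = srt[, lo_r], upper = srt[, hi_r])
  if (inherits(ds, "draw_set")) out <- cbind(ds$cells[c("location", "year")], out)
  out
}

#' Full three-stage ST-GPR pipeline
#'
#' Transforms natural-scale observations, fits the covariate prior on
#' standard locations, optionally adjusts source bias onto a reference
#' source, smooths residuals in space-time, runs the GP per location, and
#' back-transforms draws to the natural scale.
#'
#' @param obs data.frame `location`, `year`, `value` (natural scale),
#'   `variance` (natural scale; converted by the delta method), optional
#'   `source_id`, covariate columns.
#' @param pred_grid prediction cells (`location`, `year` + covariates).
#' @param config an [stgpr_config()].
#' @param covariates covariate column names.
#' @param hierarchy,standard_locations as in [fit_stage1()].
#' @param reference_source if non-NULL, source bias adjustment is applied
#'   with this source as reference.
#' @return list with `draws` (a natural-scale `draw_set`), `summary`
#'   (mean/lower/upper per cell, natural scale), `stage1`, `stage2`.
#' @export
stgpr <- function(obs, pred_grid, config = stgpr_config(),
                  covariates = character(), hierarchy = NULL,
                  standard_locations = NULL, reference_source = NULL) {
  tf <- transform_fns(config$transform)
  tobs <- obs
  tobs$value <- tf$fwd(obs$value)
  tobs$variance <- pmax(obs$variance * tf$dfwd(obs$value)^2, 1e-8)
  s1 <- fit_stage1(tobs, pred_grid, covariates, hierarchy, standard_locations,
                   shrink_n = config$shrink_n)
  if (!is.null(reference_source)) {
    key <- function(df) paste(df$location, df$year)
    pm <- s1$prior$mean[match(key(tobs), key(s1$prior))]
    sre <- estimate_source_effects(tobs, pm)
    tobs <- adjust_source_bias(tobs, sre, reference_source)
  }
  s2 <- spacetime_smooth(s1$prior, tobs, hierarchy, config)
  ds <- gp_posterior(s2, tobs, config)
  nat <- ds
  nat$draws <- tf$inv(ds$draws)
  nat$cells$mean <- rowMeans(nat$draws)
  summ <- summarize_draws(nat)
  list(draws = nat, summary = summ, stage1 = s1, stage2 = s2)
}
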