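# Cohort-component population projection and Bayesian reconstruction of the
# baseline population, net migration and (optionally) death-registration
# completeness from censuses -- the BCCMP machinery.
#
# The projection state is kept on single-year ages internally (so cohorts
# advance exactly along diagonals) and aggregated to the 5-year I/O grid;
# rates are supplied per 5-year group and applied uniformly within it.

expand_to_single <- function(counts, ages, top_extra = 25, mx_top = 0.15) {
  n <- length(ages)
  single <- list()
  for (i in seq_len(n - 1)) {
    w <- ages[i + 1] - ages[i]
    single[[i]] <- rep(counts[i] / w, w)
  }
  j <- 0:(top_extra - 1)
  wts <- exp(-mx_top * j); wts <- wts / sum(wts)
  single[[n]] <- counts[n] * wts
  unlist(single)
}

single_index <- function(ages, top_extra = 25) {
  # map single-year age -> 5-year group index
  n <- length(ages)
  grp <- integer(0)
  for (i in seq_len(n - 1)) grp <- c(grp, rep(i, ages[i + 1] - ages[i]))
  c(grp, rep(n, top_extra))
}

#' Deterministic cohort-component projection
#'
#' Standard female-dominant projection with annual steps: half of the
#' year's net migrants are added before exposure to mortality and
#' fertility, cohorts are survived with piecewise-constant hazards
#' (`exp(-mx)` per year), births arise from female exposure times the
#' age-specific fertility rates and are split by the sex ratio at birth,
#' newborns are survived with half a year of infant exposure, and the
#' remaining migrants are added after. The event ledger makes the
#' balancing identity `dP = births - deaths + net migration` exact at
#' every step.
#'
#' @param baseline matrix `n_age x 2` (columns `f`, `m`) of counts on the
#'   5-year grid `ages` at the first year.
#' @param ages 5-year group starts, last group open (top >= 55 so the
#'   maternal ages are covered).
#' @param asfr matrix `n_years x 9`: rates for maternal groups 10-14 ...
#'   50-54 in each projection year.
#' @param mx array `n_years x n_age x 2`: death rates by year, age group
#'   and sex (`f`, `m`).
#' @param migration array `n_years x n_age x 2` of net migrant counts
#'   (default zero), split half before / half after survival.
#' @param srb sex ratio at birth.
#' @param horizon number of annual steps (defaults to `dim(asfr)[1]`).
#' @return list with `pop` (`(horizon+1) x n_age x 2` array), `ledger`
#'   (data.frame per year: `births`, `births_f`, `births_m`, `deaths`,
#'   `net_migration`), `deaths_age` (`horizon x n_age x 2`),
#'   `person_years` (`horizon x n_age x 2`, mid-year approximation), and
#'   `clipped` (TRUE if negative counts were clipped to zero).
#' @export
project_ccmpp <- function(baseline, ages, asfr, mx, migration = NULL,
                          srb = 1.05, horizon = NULL, detail = TRUE) {
  n <- length(ages)
  if (ages[n] < 55) stop("open age group must start at 55 or above", call. = FALSE)
  if (is.null(horizon)) horizon <- dim(asfr)[1]
  if (is.null(migration)) migration <- array(0, c(horizon, n, 2))
  stopifnot(nrow(baseline) == n, dim(mx)[2] == n, dim(asfr)[2] == 9)
  top_extra <- 25
  gidx <- single_index(ages, top_extra)
  nS <- length(gidx)
  grp_ends <- cumsum(tabulate(gidx, n))
  gsize <- tabulate(gidx, n)[gidx]
  agg <- function(v) diff(c(0, cumsum(v)[grp_ends]))
  # maternal-age map on single years
  mat_grp <- findInterval(0:(nS - 1), seq(10, 55, by = 5))
  mat_ok <- mat_grp >= 1 & mat_grp <= 9 & (0:(nS - 1)) < 55

  Pf <- expand_to_single(baseline[, 1], ages, top_extra, mx[1, n, 1])
  Pm <- expand_to_single(baseline[, 2], ages, top_extra, mx[1, n, 2])
  pop <- array(0, c(horizon + 1, n, 2), dimnames = list(NULL, ages, c("f", "m")))
  pop[1, , 1] <- agg(Pf); pop[1, , 2] <- agg(Pm)
  deaths_age <- array(0, c(horizon, n, 2))
  py <- array(0, c(horizon, n, 2))
  lb <- numeric(horizon); lbf <- numeric(horizon); lbm <- numeric(horizon)
  ld <- numeric(horizon); lm <- numeric(horizon)
  clipped <- FALSE
  fshare <- 1 / (1 + srb)
  for (t in seq_len(horizon)) {
    mf <- mx[t, gidx, 1]; mm <- mx[t, gidx, 2]
    migf <- migration[t, gidx, 1] / gsize
    migm <- migration[t, gidx, 2] / gsize
    Pf <- Pf + 0.5 * migf; Pm <- Pm + 0.5 * migm
    if (any(Pf < 0) || any(Pm < 0)) { clipped <- TRUE; Pf <- pmax(Pf, 0); Pm <- pmax(Pm, 0) }
    asfr_single <- numeric(nS)
    asfr_single[mat_ok] <- asfr[t, mat_grp[mat_ok]]
    B <- sum(asfr_single * Pf)
    Bf <- B * fshare; Bm <- B - Bf
    Sf <- Pf * exp(-mf); Sm <- Pm * exp(-mm)
    d_exist_f <- Pf - Sf; d_exist_m <- Pm - Sm
    Bfs <- Bf * exp(-0.5 * mx[t, 1, 1]); Bms <- Bm * exp(-0.5 * mx[t, 1, 2])
    if (detail) {
      # exact person-years under within-year constant hazards: (P - S)/m,
      # so recorded deaths equal mx * person-years identically; the birth
      # cohort contributes its half-year exposure to the first group
      py[t, , 1] <- agg(ifelse(mf > 1e-12, d_exist_f / mf, Pf))
      py[t, , 2] <- agg(ifelse(mm > 1e-12, d_exist_m / mm, Pm))
    }
    # advance cohorts one year; the final single-year age absorbs
    newPf <- c(Bfs, Sf[-nS]); newPf[nS] <- newPf[nS] + Sf[nS]
    newPm <- c(Bms, Sm[-nS]); newPm[nS] <- newPm[nS] + Sm[nS]
    Pf <- newPf + 0.5 * migf; Pm <- newPm + 0.5 * migm
    if (any(Pf < 0) || any(Pm < 0)) { clipped <- TRUE; Pf <- pmax(Pf, 0); Pm <- pmax(Pm, 0) }
    if (detail) {
      deaths_age[t, , 1] <- agg(d_exist_f); deaths_age[t, , 2] <- agg(d_exist_m)
      deaths_age[t, 1, 1] <- deaths_age[t, 1, 1] + (Bf - Bfs)
      deaths_age[t, 1, 2] <- deaths_age[t, 1, 2] + (Bm - Bms)
      m0f <- mx[t, 1, 1]; m0m <- mx[t, 1, 2]
      py[t, 1, 1] <- py[t, 1, 1] + if (m0f > 1e-12) (Bf - Bfs) / m0f else 0.5 * Bf
      py[t, 1, 2] <- py[t, 1, 2] + if (m0m > 1e-12) (Bm - Bms) / m0m else 0.5 * Bm
    }
    lb[t] <- B; lbf[t] <- Bf; lbm[t] <- Bm
    ld[t] <- sum(d_exist_f) + sum(d_exist_m) + (B - Bfs - Bms)
    lm[t] <- sum(migration[t, , ])
    pop[t + 1, , 1] <- agg(Pf); pop[t + 1, , 2] <- agg(Pm)
  }
  ledger <- data.frame(year = seq_len(horizon), births = lb, births_f = lbf,
                       births_m = lbm, deaths = ld, net_migration = lm)
  list(pop = pop, ledger = ledger, deaths_age = deaths_age,
       person_years = py, ages = ages, clipped = clipped)
}

#' Census log-likelihood against a projected series
#'
#' Independent normal densities on log counts with a common coverage
#' standard deviation, summed over age-sex cells.
#'
#' @param proj output of [project_ccmpp()].
#' @param census list with `year_index` (1-based index into the projected
#'   series) and `counts` (matrix `n_age x 2`).
#' @param coverage_sd SD of log coverage error (default 0.03).
#' @return the log density.
#' @export
census_loglik <- function(proj, census, coverage_sd = 0.03) {
  pr <- proj$pop[census$year_index, , ]
  obs <- census$counts
  use <- obs > 0
  if (any(pr[use] <= 0)) {
    stop("zero projected count with positive census count", call. = FALSE)
  }
  sum(stats::dnorm(log(obs[use]), log(pr[use]), coverage_sd, log = TRUE))
}

#' Priors for the Bayesian population reconstruction
#'
#' @param baseline_mean matrix `n_age x 2`: prior mean baseline counts.
#' @param baseline_log_sd SD of the per-age log-scale baseline
#'   perturbation (shared by sex).
#' @param mig_shape fixed net-migration age shape over the 5-year groups
#'   (Rogers-Castro-like young-adult concentration by default; normalised
#'   internally).
#' @param mig_level_sd prior SD of the yearly net migration level (in
#'   persons).
#' @param mig_smooth_sd SD of year-on-year changes in the level (random
#'   walk smoothness).
#' @param mig_knot_every knot spacing in years for the level path.
#' @param coverage_sd census coverage SD on log counts.
#' @param completeness_logit_mean,completeness_logit_sd prior for
#'   registration completeness (on the logit scale).
#' @param deaths_sd overdispersion SD for log registered deaths.
#' @return list of class `bccmp_prior`.
#' @export
bccmp_prior <- function(baseline_mean, baseline_log_sd = 0.1,
                        mig_shape = NULL, mig_level_sd = NULL,
                        mig_smooth_sd = NULL, mig_knot_every = 5,
                        coverage_sd = 0.03,
                        completeness_logit_mean = 0,
                        completeness_logit_sd = 1.5,
                        deaths_sd = 0.1) {
  n <- nrow(baseline_mean)
  if (is.null(mig_shape)) {
    a <- seq_len(n) - 1
    mig_shape <- exp(-((a * 5 + 2.5 - 25) / 12)^2) + 0.3 * exp(-a / 3)
  }
  mig_shape <- mig_shape / sum(mig_shape)
  total <- sum(baseline_mean)
  if (is.null(mig_level_sd)) mig_level_sd <- 0.01 * total
  if (is.null(mig_smooth_sd)) mig_smooth_sd <- 0.2 * mig_level_sd
  structure(list(baseline_mean = baseline_mean, baseline_log_sd = baseline_log_sd,
                 mig_shape = mig_shape, mig_level_sd = mig_level_sd,
                 mig_smooth_sd = mig_smooth_sd, mig_knot_every = mig_knot_every,
                 coverage_sd = coverage_sd,
                 completeness_logit_mean = completeness_logit_mean,
                 completeness_logit_sd = completeness_logit_sd,
                 deaths_sd = deaths_sd),
            class = "bccmp_prior")
}

bccmp_unpack <- function(theta, n_age, knot_years, horizon, prior,
                         estimate_completeness) {
  delta <- theta[seq_len(n_age)]
  lv <- theta[n_age + seq_along(knot_years)]
  level <- stats::approx(knot_years, lv, xout = seq_len(horizon), rule = 2)$y
  cpar <- if (estimate_completeness) inv_logit(theta[length(theta)]) else NA
  list(delta = delta, level = level, c = cpar)
}

bccmp_logpost <- function(theta, inputs) {
  p <- inputs$prior
  u <- bccmp_unpack(theta, inputs$n_age, inputs$knot_years, inputs$horizon,
                    p, inputs$estimate_completeness)
  baseline <- p$baseline_mean * exp(u$delta)
  mig <- array(0, c(inputs$horizon, inputs$n_age, 2))
  for (t in seq_len(inputs$horizon)) {
    mig[t, , 1] <- 0.5 * u$level[t] * p$mig_shape
    mig[t, , 2] <- 0.5 * u$level[t] * p$mig_shape
  }
  proj <- project_ccmpp(baseline, inputs$ages, inputs$asfr, inputs$mx,
                        migration = mig, srb = inputs$srb,
                        horizon = inputs$horizon, detail = FALSE)
  ll <- 0
  for (cen in inputs$censuses) {
    # clipped-to-zero projections (wild proposals) get a finite penalty so
    # the sampler can move back into the feasible region
    li <- tryCatch(census_loglik(proj, cen, p$coverage_sd),
                   error = function(e) -1e10)
    ll <- ll + li
  }
  if (inputs$estimate_completeness && !is.null(inputs$registered_deaths)) {
    dhat <- proj$ledger$deaths[inputs$registered_deaths$year_index]
    obs <- inputs$registered_deaths$count
    ll <- ll + sum(stats::dnorm(log(pmax(obs, 1e-6)),
                                log(pmax(u$c * dhat, 1e-12)),
                                p$deaths_sd, log = TRUE))
  }
  lp <- sum(stats::dnorm(u$delta, 0, p$baseline_log_sd, log = TRUE)) +
    sum(stats::dnorm(theta[inputs$n_age + seq_along(inputs$knot_years)],
                     0, p$mig_level_sd, log = TRUE)) +
    sum(stats::dnorm(diff(u$level), 0, p$mig_smooth_sd, log = TRUE))
  if (inputs$estimate_completeness) {
    lp <- lp + stats::dnorm(theta[length(theta)], p$completeness_logit_mean,
                            p$completeness_logit_sd, log = TRUE)
  }
  ll + lp
}

#' Bayesian reconstruction of baseline population and net migration
#'
#' Estimates the age-specific baseline population (log-scale per-age
#' perturbations of the prior mean, shared across sexes) and a yearly net
#' migration level applied to a fixed age shape, conditional on
#' age-specific fertility and mortality and two or more censuses. Two
#' samplers are available: a Laplace approximation around the posterior
#' mode (fast, default) and adaptive random-walk Metropolis with multiple
#' chains and a split-Rhat convergence diagnostic.
#'
#' @param censuses list of censuses, each `list(year_index, counts)` with
#'   `counts` an `n_age x 2` matrix (>= 2 censuses required).
#' @param ages,asfr,mx,srb as in [project_ccmpp()].
#' @param prior a [bccmp_prior()].
#' @param method `"laplace"` or `"rwm"`.
#' @param n_draws posterior draws returned (>= 500 recommended).
#' @param chains,iter RWM settings (burn-in is the first half).
#' @param seed integer seed.
#' @param estimate_completeness if `TRUE`, registration completeness `c`
#'   is a likelihood parameter for `registered_deaths`.
#' @param registered_deaths data.frame `year_index`, `count` of registered
#'   intercensal deaths (totals per year).
#' @return object of class `bccmp_fit`: posterior draws of the baseline
#'   (`draws_baseline`: draws x age), migration level path
#'   (`draws_migration`: draws x year), completeness (`draws_c` or NULL),
#'   summaries, and diagnostics (`rhat` for RWM).
#' @export
estimate_baseline_migration <- function(censuses, ages, asfr, mx, srb = 1.05,
                                        prior, method = c("laplace", "rwm"),
                                        n_draws = 500, chains = 4, iter = 2000,
                                        seed = 1L,
                                        estimate_completeness = FALSE,
                                        registered_deaths = NULL) {
  method <- match.arg(method)
  if (length(censuses) < 2) stop("need at least 2 censuses", call. = FALSE)
  horizon <- dim(asfr)[1]
  n_age <- length(ages)
  knot_years <- unique(c(seq(1, horizon, by = prior$mig_knot_every), horizon))
  npar <- n_age + length(knot_years) + as.integer(estimate_completeness)
  inputs <- list(prior = prior, n_age = n_age, ages = ages, asfr = asfr,
                 mx = mx, srb = srb, horizon = horizon,
                 knot_years = knot_years, censuses = censuses,
                 estimate_completeness = estimate_completeness,
                 registered_deaths = registered_deaths)
  negf <- function(th) -bccmp_logpost(th, inputs)
  init <- rep(0, npar)
  if (estimate_completeness) {
    init[npar] <- prior$completeness_logit_mean
  }
  set.seed(as.integer(seed))
  rhat <- NULL
  if (method == "laplace") {
    # parameters are on comparable scales after rescaling migration levels
    sc <- c(rep(1, n_age), rep(prior$mig_level_sd, length(knot_years)),
            if (estimate_completeness) 1)
    opt <- stats::optim(init / sc, function(z) negf(z * sc), method = "BFGS",
                        control = list(maxit = 200, reltol = 1e-8))
    H <- stats::optimHess(opt$par, function(z) negf(z * sc))
    H <- (H + t(H)) / 2
    ev <- eigen(H, symmetric = TRUE)
    vals <- pmax(ev$values, 1e-8)
    Rt <- ev$vectors %*% (1 / sqrt(vals) * t(ev$vectors))
    Z <- matrix(stats::rnorm(npar * n_draws), npar)
    draws <- t(opt$par + Rt %*% Z) * rep(sc, each = n_draws)
  } else {
    per <- max(2, ceiling(iter / 2))
    keep <- list()
    half_chains <- NULL
    for (ch in seq_len(chains)) {
      set.seed(derive_seed(seed, c("rwm", ch)))
      th <- init + stats::rnorm(npar, 0, 0.05)
      step <- rep(0.05, npar)
      step[n_age + seq_along(knot_years)] <- 0.05 * prior$mig_level_sd
      lp <- bccmp_logpost(th, inputs)
      out <- matrix(NA_real_, iter, npar)
      acc <- 0
      for (i in seq_len(iter)) {
        prop <- th + stats::rnorm(npar, 0, step)
        lpp <- bccmp_logpost(prop, inputs)
        if (log(stats::runif(1)) < lpp - lp) { th <- prop; lp <- lpp; acc <- acc + 1 }
        if (i %% 100 == 0) { # adapt toward ~25% acceptance during burn-in
          if (i <= iter / 2) step <- step * ifelse(acc / i > 0.25, 1.2, 0.8)
        }
        out[i, ] <- th
      }
      keep[[ch]] <- out[(iter / 2 + 1):iter, , drop = FALSE]
    }
    # split-Rhat on the first parameter group
    rhat <- vapply(seq_len(npar), function(j) {
      halves <- do.call(rbind, lapply(keep, function(m) {
        n2 <- floor(nrow(m) / 2)
        rbind(c(mean(m[1:n2, j]), stats::var(m[1:n2, j])),
              c(mean(m[(n2 + 1):(2 * n2), j]), stats::var(m[(n2 + 1):(2 * n2), j])))
      }))
      W <- mean(halves[, 2]); B <- stats::var(halves[, 1])
      if (W <= 0) return(1)
      sqrt((W + B) / W)
    }, numeric(1))
    if (any(rhat > 1.1)) {
      warning("split-Rhat > 1.1 for ", sum(rhat > 1.1),
              " parameters; chains may not have converged")
    }
    all <- do.call(rbind, keep)
    draws <- all[sample.int(nrow(all), min(n_draws, nrow(all))), , drop = FALSE]
  }
  d_delta <- draws[, seq_len(n_age), drop = FALSE]
  d_lv <- draws[, n_age + seq_along(knot_years), drop = FALSE]
  draws_baseline <- sweep(exp(d_delta), 2,
                          rowSums(prior$baseline_mean), "*")
  draws_migration <- t(apply(d_lv, 1, function(v) {
    stats::approx(knot_years, v, xout = seq_len(horizon), rule = 2)$y
  }))
  draws_c <- if (estimate_completeness) inv_logit(draws[, npar]) else NULL
  structure(list(draws_baseline = draws_baseline,
                 draws_migration = draws_migration,
                 draws_delta = d_delta,
                 draws_c = draws_c,
                 baseline_mean = colMeans(draws_baseline),
                 migration_mean = colMeans(draws_migration),
                 prior = prior, ages = ages, method = method,
                 knot_years = knot_years, rhat = rhat, seed = seed),
            class = "bccmp_fit")
}

#' @export
print.bccmp_fit <- function(x, ...) {
  cat("<bccmp_fit> ", x$method, " posterior, ", nrow(x$draws_baseline),
      " draws, ", length(x$ages), " age groups",
      if (!is.null(x$draws_c)) paste0(", completeness mean ",
                                      round(mean(x$draws_c), 3)), "\n", sep = "")
  invisible(x)
}

#' Registration completeness as a BCCMP likelihood parameter
#'
#' Runs [estimate_baseline_migration()] with registered deaths modelled as
#' `c` times projected deaths (log-normal overdispersion) and returns the
#' completeness posterior under the method tag `"BCCMP"`. With no death
#' data the completeness posterior reduces to its prior.
#'
#' @inheritParams estimate_baseline_migration
#' @return list with `c_mean`, `c_lower`, `c_upper`, `draws_c`, `fit` and
#'   a `completeness_estimate` in `estimate`.
#' @export
bccmp_completeness <- function(censuses, ages, asfr, mx, srb = 1.05, prior,
                               registered_deaths = NULL,
                               method = "laplace", n_draws = 500, seed = 1L, ...) {
  if (is.null(registered_deaths)) {
    set.seed(as.integer(seed))
    dr <- inv_logit(stats::rnorm(n_draws, prior$completeness_logit_mean,
                                 prior$completeness_logit_sd))
    qs <- stats::quantile(dr, c(0.025, 0.975), names = FALSE)
    return(list(c_mean = mean(dr), c_lower = qs[1], c_upper = qs[2],
                draws_c = dr, fit = NULL,
                estimate = completeness_estimate(mean(dr), "BCCMP", c(NA, NA))))
  }
  fit <- estimate_baseline_migration(censuses, ages, asfr, mx, srb, prior,
                                     method = method, n_draws = n_draws,
                                     seed = seed, estimate_completeness = TRUE,
                                     registered_deaths = registered_deaths, ...)
  qs <- stats::quantile(fit$draws_c, c(0.025, 0.975), names = FALSE)
  list(c_mean = mean(fit$draws_c), c_lower = qs[1], c_upper = qs[2],
       draws_c = fit$draws_c, fit = fit,
       estimate = completeness_estimate(mean(fit$draws_c), "BCCMP", c(NA, NA)))
}
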