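test_that("a rate-free projection shifts cohorts along diagonals", {
  p <- proj_inputs(H = 5)
  mx0 <- p$mx * 0 + 1e-12
  pr <- project_ccmpp(p$baseline, p$ages, p$asfr * 0, mx0)
  expect_equal(apply(pr$pop, 1, sum), rep(sum(p$baseline), 6), tolerance = 1e-9)
  shifted <- unname(pr$pop[6, , 1])
  expect_equal(shifted[2:(p$n - 1)], unname(p$baseline[1:(p$n - 2), "f"]),
               tolerance = 1e-6)
  expect_equal(shifted[p$n],
               unname(p$baseline[p$n - 1, "f"] + p$baseline[p$n, "f"]),
               tolerance = 1e-6)
})

test_that("the event ledger closes the demographic balancing identity exactly", {
  p <- proj_inputs()
  mig <- array(0, c(p$H, p$n, 2))
  mig[, 5, ] <- 20; mig[, 8, ] <- -10
  pr <- project_ccmpp(p$baseline, p$ages, p$asfr, p$mx, migration = mig)
  for (t in seq_len(p$H)) {
    dP <- sum(pr$pop[t + 1, , ]) - sum(pr$pop[t, , ])
    expect_equal(dP,
                 pr$ledger$births[t] - pr$ledger$deaths[t] +
                   pr$ledger$net_migration[t],
                 tolerance = 1e-8)
  }
  # recorded deaths equal mx * person-years identically
  expect_equal(pr$deaths_age[3, , 2], p$mx[3, , 2] * pr$person_years[3, , 2],
               tolerance = 1e-9)
})

test_that("projection is linear in the baseline when fertility is zero", {
  p <- proj_inputs(H = 10)
  z <- p$asfr * 0
  pr1 <- project_ccmpp(p$baseline, p$ages, z, p$mx)
  pr2 <- project_ccmpp(2 * p$baseline, p$ages, z, p$mx)
  expect_equal(pr2$pop, 2 * pr1$pop, tolerance = 1e-9)
  b3 <- p$baseline; b3[4, ] <- 0
  pr3 <- project_ccmpp(p$baseline - b3, p$ages, z, p$mx)
  pr4 <- project_ccmpp(b3, p$ages, z, p$mx)
  expect_equal(pr3$pop + pr4$pop, pr1$pop, tolerance = 1e-8)
})

test_that("the deterministic projection matches a microsimulation in expectation", {
  p <- proj_inputs(H = 6)
  scale <- 1e5 / sum(p$baseline)
  base <- round(p$baseline * scale)
  pr <- project_ccmpp(base, p$ages, p$asfr, p$mx, srb = 1.05)
  # individual-based oracle: single-year agents, annual binomial survival,
  # poisson births; aggregate expectations share the projection's rates
  nrep <- 12
  set.seed(41)
  totals <- matrix(0, nrep, 2)
  for (r in seq_len(nrep)) {
    Pf <- demrecon:::expand_to_single(base[, 1], p$ages, 25, p$mx[1, p$n, 1])
    Pm <- demrecon:::expand_to_single(base[, 2], p$ages, 25, p$mx[1, p$n, 2])
    Pf <- rpois(length(Pf), Pf); Pm <- rpois(length(Pm), Pm)
    gidx <- demrecon:::single_index(p$ages, 25)
    mat <- findInterval(0:(length(Pf) - 1), seq(10, 55, by = 5))
    ok <- mat >= 1 & mat <= 9 & (0:(length(Pf) - 1)) < 55
    for (t in seq_len(p$H)) {
      B <- sum(rpois(sum(ok), p$asfr[t, mat[ok]] * Pf[ok]))
      Bf <- rbinom(1, B, 1 / 2.05); Bm <- B - Bf
      sf <- exp(-p$mx[t, gidx, 1]); sm <- exp(-p$mx[t, gidx, 2])
      Sf <- rbinom(length(Pf), Pf, sf); Sm <- rbinom(length(Pm), Pm, sm)
      Bfs <- rbinom(1, Bf, exp(-0.5 * p$mx[t, 1, 1]))
      Bms <- rbinom(1, Bm, exp(-0.5 * p$mx[t, 1, 2]))
      Pf <- c(Bfs, Sf[-length(Sf)]); Pf[length(Pf)] <- Pf[length(Pf)] + Sf[length(Sf)]
      Pm <- c(Bms, Sm[-length(Sm)]); Pm[length(Pm)] <- Pm[length(Pm)] + Sm[length(Sm)]
    }
    totals[r, ] <- c(sum(Pf), sum(Pm))
  }
  for (sx in 1:2) {
    mc_mean <- mean(totals[, sx]); mc_se <- sd(totals[, sx]) / sqrt(nrep)
    expect_lt(abs(sum(pr$pop[p$H + 1, , sx]) - mc_mean), 3 * mc_se + 1e-9)
  }
})

test_that("the census likelihood is a normal log-density peaked at the projection", {
  p <- proj_inputs(H = 10)
  pr <- project_ccmpp(p$baseline, p$ages, p$asfr, p$mx)
  cen <- list(year_index = 6, counts = pr$pop[6, , ])
  ll0 <- census_loglik(pr, cen, 0.03)
  # closed-form oracle
  expect_equal(ll0, sum(dnorm(log(cen$counts), log(pr$pop[6, , ]), 0.03,
                              log = TRUE)), tolerance = 1e-12)
  # maximal over perturbations of the projection used as data
  for (f in c(0.95, 1.02, 1.1)) {
    expect_lt(census_loglik(pr, list(year_index = 6, counts = pr$pop[6, , ] * f),
                            0.03), ll0)
  }
  # doubling the sd raises the density of a discrepant census
  disc <- list(year_index = 6, counts = pr$pop[6, , ] * 1.25)
  expect_gt(census_loglik(pr, disc, 0.06), census_loglik(pr, disc, 0.03))
  bad <- pr; bad$pop[6, 2, 1] <- 0
  expect_error(census_loglik(bad, cen, 0.03), "zero projected")
})

bccmp_world <- function(seed, migration = FALSE) {
  p <- proj_inputs(H = 20, seed = 100 + seed)
  mig <- NULL
  truth <- project_ccmpp(p$baseline, p$ages, p$asfr, p$mx, migration = mig)
  set.seed(seed)
  censuses <- lapply(c(1, 11, 21), function(t) {
    list(year_index = t,
         counts = truth$pop[t, , ] * exp(matrix(rnorm(p$n * 2, 0, 0.03), p$n, 2)))
  })
  prior <- bccmp_prior(
    baseline_mean = truth$pop[1, , ] * exp(matrix(rnorm(p$n * 2, 0, 0.05), p$n, 2)),
    mig_knot_every = 10)
  list(p = p, truth = truth, censuses = censuses, prior = prior)
}

test_that("the Bayesian reconstruction recovers the baseline and is reproducible", {
  bw <- bccmp_world(1)
  fit <- estimate_baseline_migration(bw$censuses, bw$p$ages, bw$p$asfr, bw$p$mx,
                                     prior = bw$prior, seed = 5, n_draws = 300)
  err <- fit$baseline_mean / rowSums(bw$truth$pop[1, , ]) - 1
  expect_lt(mean(abs(err)), 0.05)
  # a zero-migration world concentrates the migration posterior near zero
  expect_lt(mean(abs(fit$migration_mean)), bw$prior$mig_level_sd / 2)
  # identical seeds give identical draws
  fit2 <- estimate_baseline_migration(bw$censuses, bw$p$ages, bw$p$asfr, bw$p$mx,
                                      prior = bw$prior, seed = 5, n_draws = 300)
  expect_identical(fit$draws_baseline, fit2$draws_baseline)
})

test_that("the random-walk sampler runs with convergence diagnostics", {
  bw <- bccmp_world(2)
  fit <- suppressWarnings(
    estimate_baseline_migration(bw$censuses, bw$p$ages, bw$p$asfr, bw$p$mx,
                                prior = bw$prior, method = "rwm", chains = 2,
                                iter = 200, seed = 9, n_draws = 100))
  expect_false(is.null(fit$rhat))
  expect_length(fit$rhat, ncol(fit$draws_delta) + length(fit$knot_years))
  expect_equal(nrow(fit$draws_baseline), 100)
})

test_that("completeness enters the likelihood and reduces to the prior without deaths", {
  bw <- bccmp_world(3)
  set.seed(3)
  for (cth in c(1, 0.7)) {
    reg <- data.frame(year_index = 1:20,
                      count = cth * bw$truth$ledger$deaths * exp(rnorm(20, 0, 0.05)))
    cc <- bccmp_completeness(bw$censuses, bw$p$ages, bw$p$asfr, bw$p$mx,
                             prior = bw$prior, registered_deaths = reg, seed = 11)
    expect_lt(abs(cc$c_mean - cth), 0.05)
    expect_equal(cc$estimate$method, "BCCMP")
  }
  # no death data: the posterior is the prior (matched moments on logit scale)
  none <- bccmp_completeness(bw$censuses, bw$p$ages, bw$p$asfr, bw$p$mx,
                             prior = bw$prior, registered_deaths = NULL,
                             seed = 11, n_draws = 4000)
  prior_draws <- demrecon:::inv_logit(rnorm(4000, 0, 1.5))
  expect_lt(abs(mean(none$draws_c) - mean(prior_draws)), 0.03)
  expect_lt(abs(sd(none$draws_c) - sd(prior_draws)), 0.03)
})
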