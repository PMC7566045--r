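test_that("world construction is deterministic given the seed", {
  a <- build_world(world_config(n_locations = 1, years = 1950:1990, seed = 5))
  b <- build_world(world_config(n_locations = 1, years = 1950:1990, seed = 5))
  expect_identical(a$world, b$world)
  c2 <- build_world(world_config(n_locations = 1, years = 1950:1990, seed = 6))
  expect_false(identical(a$world$loc1$pop, c2$world$loc1$pop))
})

test_that("ledger deaths equal hazard times person-years cell by cell", {
  tr <- small_world()
  w <- tr$world$loc1
  expected <- w$mx5 * w$person_years
  # shocks are added outside the hazard bookkeeping; compare shock-free cells
  rel <- abs(w$deaths_age[expected > 1e-6] / expected[expected > 1e-6] - 1)
  expect_lt(max(rel), 1e-3)
})

test_that("scenario presets steer the truth in the documented direction", {
  base <- build_world(world_config(n_locations = 1, years = 1970:2010, seed = 3))
  hiv <- build_world(scenario_preset("hiv_epidemic", n_locations = 1,
                                     years = 1970:2010, seed = 3))
  adult <- base$pop_ages >= 25 & base$pop_ages < 45
  t_peak <- match(1998, base$years)
  expect_true(all(hiv$world$loc1$mx5[t_peak, adult, ] >
                    base$world$loc1$mx5[t_peak, adult, ]))

  shock <- build_world(scenario_preset("conflict_shock", n_locations = 1,
                                       years = 1970:2010, seed = 3,
                                       shocks = data.frame(year = 1994,
                                                           total_deaths_frac = 0.02,
                                                           cause = "conflict")))
  t_s <- match(1994, shock$years)
  extra <- sum(shock$world$loc1$deaths_age[t_s, , ]) -
    sum(base$world$loc1$deaths_age[t_s, , ])
  expect_equal(extra, 0.02 * sum(shock$world$loc1$pop[t_s, , ]),
               tolerance = 1e-6)

  emig <- build_world(scenario_preset("emigration_wave", n_locations = 1,
                                      years = 1970:2010, seed = 3))
  expect_lt(sum(emig$world$loc1$ledger$net_migration), 0)
  expect_error(world_config(shocks = data.frame(year = 1900,
                                                total_deaths_frac = 0.01,
                                                cause = "x")), "outside")
})

test_that("noise-free administrative observations reproduce the truth", {
  tr <- small_world()   # complete registration, but census noise present
  cfg0 <- world_config(n_locations = 1, years = 1960:2000, seed = 2,
                       observation = list(vr_completeness = list(start = 1, end = 1,
                                                                 midpoint = 1980),
                                          census_years = c(1970, 1990),
                                          census_coverage_sd = 0,
                                          survey_years = 1990,
                                          n_mothers = 10, n_respondents = 10,
                                          sibling_frailty_sd = 0))
  tr0 <- build_world(cfg0)
  adm <- observe_admin(tr0)
  w <- tr0$world$loc1
  expect_equal(adm$vr_deaths$count[adm$vr_deaths$sex == "f"],
               as.vector(t(w$deaths_age[, , 1])), tolerance = 1e-9)
  cen <- adm$censuses[adm$censuses$year == 1990 & adm$censuses$sex == "m", ]
  expect_equal(cen$count, unname(w$pop[match(1990, tr0$years), , 2]),
               tolerance = 1e-9)
})

test_that("thinned registration matches its binomial expectation", {
  cfg <- world_config(n_locations = 1, years = 1960:2000, seed = 9,
                      observation = list(vr_completeness = list(start = 0.7, end = 0.7,
                                                                midpoint = 1980),
                                         census_years = 1980,
                                         census_coverage_sd = 0.03,
                                         survey_years = 1990,
                                         n_mothers = 10, n_respondents = 10,
                                         sibling_frailty_sd = 0))
  tr <- build_world(cfg)
  adm <- observe_admin(tr)
  w <- tr$world$loc1
  tot_true <- sum(w$deaths_age)
  tot_obs <- sum(adm$vr_deaths$count)
  se <- sqrt(0.7 * 0.3 * tot_true)
  expect_lt(abs(tot_obs - 0.7 * tot_true), 3 * se + nrow(adm$vr_deaths))
})

test_that("census coverage noise is centred on the truth", {
  cfg <- world_config(n_locations = 1, years = 1975:1985, seed = 1,
                      observation = list(vr_completeness = list(start = 1, end = 1,
                                                                midpoint = 1980),
                                         census_years = 1980,
                                         census_coverage_sd = 0.05,
                                         survey_years = 1980,
                                         n_mothers = 10, n_respondents = 10,
                                         sibling_frailty_sd = 0))
  tr <- build_world(cfg)
  w <- tr$world$loc1
  truth <- w$pop[match(1980, tr$years), , ]
  ratios <- replicate(200, {
    adm <- observe_admin(tr, seed = sample.int(1e6, 1))
    cen <- adm$censuses
    mean(cen$count / c(truth[, 1], truth[, 2]))
  })
  # multiplicative log-normal error with sd 0.05 has mean exp(0.00125)
  expect_lt(abs(mean(ratios) - exp(0.05^2 / 2)), 3 * sd(ratios) / sqrt(200))
})

test_that("a world without child mortality yields all-surviving birth histories", {
  cfg <- world_config(n_locations = 1, years = 1970:2000, seed = 4,
                      observation = list(vr_completeness = list(start = 1, end = 1,
                                                                midpoint = 1980),
                                         census_years = 1980,
                                         census_coverage_sd = 0,
                                         survey_years = 2000,
                                         n_mothers = 300, n_respondents = 10,
                                         sibling_frailty_sd = 0))
  tr <- build_world(cfg)
  tr$world$loc1$q5[, ] <- 0
  sv <- observe_surveys(tr, 2000, "loc1")
  expect_equal(sum(sv$sbh$ceb) - sum(sv$sbh$surviving), 0)
  expect_true(all(sv$siblings$surviving_respondents >= 1))
})

test_that("complete-birth-history direct estimates are unbiased for 5q0", {
  cfg <- world_config(n_locations = 1, years = 1970:2005, seed = 13,
                      q5 = list(start = 0.12, end = 0.06, midpoint = 1985,
                                steepness = 0.1),
                      observation = list(vr_completeness = list(start = 1, end = 1,
                                                                midpoint = 1985),
                                         census_years = 1980,
                                         census_coverage_sd = 0,
                                         survey_years = 2005,
                                         n_mothers = 120, n_respondents = 5,
                                         sibling_frailty_sd = 0))
  tr <- build_world(cfg)
  w <- tr$world$loc1
  q5hat <- replicate(150, {
    sv <- observe_surveys(tr, 2005, "loc1", seed = sample.int(1e6, 1))
    kids <- sv$cbh[sv$cbh$observed_age >= 5 & sv$cbh$observed_age <= 15, ]
    mean(kids$died_under5)
  })
  # truth: birth-cohort q5 averaged over the cohorts in the window
  cohorts <- match(2005 - 15, tr$years):match(2005 - 5, tr$years)
  fsh <- 1 / (1 + w$srb)
  truth <- mean(w$q5[cohorts, 1] * fsh + w$q5[cohorts, 2] * (1 - fsh))
  mc_se <- sd(q5hat) / sqrt(length(q5hat))
  expect_lt(abs(mean(q5hat) - truth), 2 * mc_se + 0.002)
})
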