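toy_obs <- function(values, years = seq_along(values), location = "a",
                    variance = 0.01, source = "vr") {
  data.frame(location = location, year = years, value = values,
              variance = variance, source_id = source)
}

test_that("stage 1 reduces to a precision-weighted mean without covariates", {
  obs <- data.frame(location = "a", year = 1:3, value = c(1, 2, 4),
                    variance = c(1, 1, 0.5))
  grid <- data.frame(location = "a", year = 1:3)
  s1 <- fit_stage1(obs, grid)
  expect_equal(unname(s1$beta[1] ),
               sum(obs$value / obs$variance) / sum(1 / obs$variance))
})

test_that("stage 1 recovers simulated covariate effects within 3 SE", {
  set.seed(2)
  n <- 120
  obs <- data.frame(location = rep(c("a", "b", "c"), each = n / 3),
                    year = rep(1:40, 3),
                    edu = runif(n, 0, 10), variance = 0.04)
  obs$value <- 0.5 + 0.3 * obs$edu + rnorm(n, 0, 0.2)
  grid <- unique(obs[c("location", "year")]); grid$edu <- 5
  s1 <- fit_stage1(obs, grid, covariates = "edu")
  expect_lt(abs(s1$beta[["edu"]] - 0.3), 3 * s1$se[["edu"]])
})

test_that("locations without data inherit the covariate term plus parent effect", {
  hierarchy <- data.frame(location = c("root", "a", "b"),
                          parent = c(NA, "root", "root"))
  obs <- data.frame(location = "a", year = 1:10, value = rep(2, 10),
                    variance = 0.01)
  grid <- data.frame(location = c(rep("a", 10), rep("b", 10)),
                     year = rep(1:10, 2))
  s1 <- fit_stage1(obs, grid, hierarchy = hierarchy,
                   standard_locations = "a")
  pb <- s1$prior$mean[s1$prior$location == "b"]
  # parent effect is the shrunken mean residual over all data under root
  expect_equal(unique(pb), unname(s1$beta[1]) + s1$re[["b"]])
  expect_equal(s1$re[["b"]], s1$re[["root"]])
})

test_that("source bias adjustment shifts only non-reference sources", {
  obs <- toy_obs(c(1, 1.1, 0.9), source = c("vr", "survey", "vr"))
  re <- c(vr = 0, survey = 0.10)
  adj <- adjust_source_bias(obs, re, "vr")
  expect_equal(adj$value, c(1, 1.0, 0.9))
  expect_equal(adj$variance, obs$variance)
  expect_error(adjust_source_bias(obs, re, NA), "reference")

  # a constant between-source offset is mostly removed
  set.seed(9)
  truth <- sin(seq(0, 2, length.out = 40)) + 2
  o <- rbind(toy_obs(truth + rnorm(40, 0, 0.01), 1:40, source = "ref"),
             toy_obs(truth + 0.5 + rnorm(40, 0, 0.01), 1:40, source = "biased"))
  prior <- rep(mean(o$value), 80)
  sre <- estimate_source_effects(o, prior)
  adj2 <- adjust_source_bias(o, sre, "ref")
  gap <- mean(adj2$value[o$source_id == "biased"]) -
    mean(adj2$value[o$source_id == "ref"])
  expect_lt(abs(gap), 0.1 * 0.5)
})

test_that("space-time smoothing is an exact pass-through for zero residuals", {
  obs <- toy_obs(rep(1.5, 10), 1:10)
  grid <- data.frame(location = "a", year = 1:20)
  s1 <- fit_stage1(obs, grid)
  s2 <- spacetime_smooth(s1$prior, obs)
  expect_equal(s2$mean, s1$prior$mean, tolerance = 1e-12)

  # weights are normalised: a constant residual passes through unchanged
  obs2 <- obs; obs2$value <- obs2$value + 0.3
  s2b <- spacetime_smooth(s1$prior, obs2)
  expect_equal(s2b$residual, rep(0.3, 20), tolerance = 1e-12)

  # a single spike's influence decays monotonically in time distance
  obs3 <- toy_obs(0.7, years = 10)
  prior0 <- data.frame(location = "a", year = 1:20, mean = 0)
  s2c <- spacetime_smooth(prior0, obs3)
  infl <- s2c$residual
  expect_true(all(diff(infl[1:10]) >= -1e-12))
  expect_true(all(diff(infl[10:20]) <= 1e-12))
})

test_that("the GP posterior interpolates precise data and reverts without data", {
  cfg <- stgpr_config(transform = "identity", n_draws = 50, amplitude = 0.4,
                      length_scale = 8)
  stage2 <- data.frame(location = "a", year = 1:30, mean = 0.2)
  none <- gp_posterior(stage2, toy_obs(0.5, 1)[0, ], cfg)
  expect_equal(none$cells$mean, rep(0.2, 30))
  expect_equal(none$cells$sd, rep(0.4, 30), tolerance = 1e-6)

  precise <- toy_obs(0.9, years = 15, variance = 1e-10)
  post <- gp_posterior(stage2, precise, cfg)
  expect_lt(abs(post$cells$mean[15] - 0.9), 1e-3)

  vague <- toy_obs(0.9, years = 15, variance = 1e6)
  post2 <- gp_posterior(stage2, vague, cfg)
  expect_lt(max(abs(post2$cells$mean - 0.2)), 1e-3)
})

test_that("draw summaries use the 25th and 975th order statistics", {
  ds <- matrix(rep(sample(1:1000), 2), nrow = 2, byrow = TRUE)
  s <- summarize_draws(ds)
  expect_equal(s$lower, c(25, 25))
  expect_equal(s$upper, c(975, 975))
  expect_equal(summarize_draws(matrix(7, 1, 100))$lower, 7)
  expect_equal(summarize_draws(matrix(7, 1, 100))$upper, 7)
  # permutation invariance
  perm <- ds[, sample(1:1000)]
  expect_equal(summarize_draws(perm), summarize_draws(ds))
})

test_that("the GP uncertainty interval is calibrated on replicated worlds", {
  set.seed(77)
  cfg <- stgpr_config(transform = "identity", n_draws = 200, amplitude = 0.3,
                      length_scale = 10)
  years <- 1:25
  K <- 0.3^2 * exp(-outer(years, years, "-")^2 / (2 * 10^2))
  Rt <- chol(K + diag(1e-9, 25))
  hits <- 0; cells <- 0
  for (r in 1:200) {
    truth <- 0.5 + drop(t(Rt) %*% rnorm(25))
    oy <- seq(2, 25, by = 4)
    obs <- data.frame(location = "a", year = oy,
                      value = truth[oy] + rnorm(length(oy), 0, 0.1),
                      variance = 0.01)
    stage2 <- data.frame(location = "a", year = years, mean = 0.5)
    cfg$seed <- r
    post <- gp_posterior(stage2, obs, cfg)
    s <- summarize_draws(post)
    hits <- hits + sum(s$lower <= truth & truth <= s$upper)
    cells <- cells + 25
  }
  expect_gte(hits / cells, 0.90)
})

test_that("the logit pipeline keeps draws inside (0, 1) and recovers a surface", {
  set.seed(4)
  years <- 1950:1999
  locs <- paste0("l", 1:10)
  truth <- sapply(seq_along(locs), function(i) {
    demrecon:::logistic_path(years, 0.22 * (1 + 0.05 * i), 0.03, 1975, 0.12)
  })
  obs <- do.call(rbind, lapply(seq_along(locs), function(i) {
    oy <- seq(2, 50, by = 3)
    data.frame(location = locs[i], year = years[oy],
               value = pmin(pmax(truth[oy, i] * exp(rnorm(length(oy), 0, 0.08)),
                                 1e-4), 0.97),
               variance = (0.08 * truth[oy, i])^2,
               source_id = "vr")
  }))
  grid <- expand.grid(location = locs, year = years,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  fit <- stgpr(obs, grid, stgpr_config(transform = "logit", n_draws = 100,
                                       amplitude = 0.6, length_scale = 10,
                                       seed = 99))
  expect_true(all(fit$draws$draws > 0 & fit$draws$draws < 1))
  est <- fit$summary
  tv <- sapply(seq_along(locs), function(i) truth[, i])
  mare <- mean(abs(est$mean[order(match(est$location, locs), est$year)] /
                     as.vector(tv) - 1))
  expect_lt(mare, 0.07)
})
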