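g23 <- build_age_grid("gbd23")
lt_mid <- lifetable_from_mx(siler_mx(g23), g23, ax_rule = "constant_hazard")

test_that("Sullivan HALE satisfies its closed-form identities", {
  expect_equal(sullivan_hale(lt_mid, rep(0, 23)), lt_mid$ex, tolerance = 1e-12)
  y <- 0.12
  expect_equal(sullivan_hale(lt_mid, rep(y, 23)), (1 - y) * lt_mid$ex,
               tolerance = 1e-12)
  set.seed(10)
  yld <- runif(23, 0, 0.3)
  h <- sullivan_hale(lt_mid, yld)
  # direct weighted-sum oracle
  oracle <- vapply(seq_len(23), function(i) {
    sum(lt_mid$Lx[i:23] * (1 - yld[i:23])) / lt_mid$lx[i]
  }, numeric(1))
  expect_equal(h, oracle, tolerance = 1e-12)
  expect_true(all(h <= lt_mid$ex + 1e-12))
  # poor-health years grow with any yld component
  yld2 <- yld; yld2[5] <- yld2[5] + 0.1
  expect_gt(lt_mid$ex[1] - sullivan_hale(lt_mid, yld2)[1],
            lt_mid$ex[1] - h[1])
  expect_error(sullivan_hale(lt_mid, rep(1.2, 23)), "\\[0, 1\\)")
})

test_that("the SDI is a geometric mean of scaled components", {
  b <- list(income = c(250, 60000), schooling = c(0, 17), tfu25 = c(3, 0))
  expect_equal(compute_sdi(60000, 17, 0, b), 1)
  expect_equal(compute_sdi(250, 10, 1, b), 0)   # worst income annihilates
  # monotone in every component
  s0 <- compute_sdi(5000, 8, 1.5, b)
  expect_gt(compute_sdi(9000, 8, 1.5, b), s0)
  expect_gt(compute_sdi(5000, 9, 1.5, b), s0)
  expect_gt(compute_sdi(5000, 8, 1.2, b), s0)
  # doubling income and both income bounds leaves the index unchanged
  b2 <- b; b2$income <- b$income * 2
  expect_equal(compute_sdi(10000, 8, 1.5, b2), s0, tolerance = 1e-12)
})

test_that("every ensemble member respects the knot constraints", {
  set.seed(3)
  x <- runif(100); y <- sin(2 * x) + rnorm(100, 0, 0.05)
  ens <- fit_spline_ensemble(x, y, n_models = 50, seed = 7)
  for (m in ens$members) {
    expect_length(m$knots, 3)
    expect_true(all(m$knots >= 0.1 & m$knots <= 0.8))
    expect_true(all(diff(m$knots) >= 0.1))
  }
  expect_equal(sum(ens$weights), 1)
})

test_that("linear outcomes stay linear through fit and extrapolation", {
  x <- seq(0.02, 0.98, length.out = 60)
  y <- 2 - 3 * x
  ens <- fit_spline_ensemble(x, y, n_models = 20, seed = 2)
  xx <- c(-0.5, 0, 0.31, 0.77, 1, 1.5)
  expect_equal(predict(ens, xx), 2 - 3 * xx, tolerance = 1e-8)
  # member-order permutation invariance
  perm <- ens; idx <- sample(seq_along(ens$members))
  perm$members <- ens$members[idx]; perm$weights <- ens$weights[idx]
  expect_equal(predict(perm, xx), predict(ens, xx), tolerance = 1e-12)
})

test_that("the ensemble beats a global line on curved signals", {
  set.seed(12)
  x <- runif(150)
  f <- function(x) 1 + 4 * (x - 0.4)^2
  y <- f(x) + rnorm(150, 0, 0.05)
  ens <- fit_spline_ensemble(x, y, n_models = 50, seed = 5)
  rmse_ens <- sqrt(mean((predict(ens, x) - f(x))^2))
  line <- lm(y ~ x)
  rmse_line <- sqrt(mean((fitted(line) - f(x))^2))
  expect_lt(rmse_ens, rmse_line)
})

test_that("residual trimming drops gross outliers from a member fit", {
  x <- seq(0.05, 0.95, length.out = 80)
  y <- 1 + x
  y[c(10, 40)] <- y[c(10, 40)] + 5
  plain <- fit_spline_ensemble(x, y, n_models = 5, seed = 1, trim = 0)
  trimmed <- fit_spline_ensemble(x, y, n_models = 5, seed = 1, trim = 0.1)
  xg <- seq(0.1, 0.9, length.out = 21)
  err_plain <- max(abs(predict(plain, xg) - (1 + xg)))
  err_trim <- max(abs(predict(trimmed, xg) - (1 + xg)))
  expect_lt(err_trim, err_plain)
})

test_that("expected mortality at a given SDI recovers a known training map", {
  set.seed(8)
  lib <- standard_library()
  std <- lib[[13]]$lx
  # training worlds: mortality level is a smooth monotone function of SDI,
  # realised through the relational model against one fixed standard
  sdi_train <- runif(60, 0.05, 0.95)
  schedule_at <- function(sdi) {
    q5 <- exp(-1.5 - 2.2 * sdi + 0.35 * sdi^2)
    q45 <- exp(-0.7 - 2.0 * sdi + 0.3 * sdi^2)
    fit_relational(std, list(q5_0 = q5, q45_15 = q45))$lt$mx
  }
  train_mx <- vapply(sdi_train, schedule_at, numeric(23))
  ensembles <- lapply(seq_len(23), function(a) {
    fit_spline_ensemble(sdi_train, log(train_mx[a, ]), n_models = 25, seed = a)
  })
  for (sdi0 in c(0.3, 0.6, 0.85)) {
    truth_e0 <- lifetable_from_mx(schedule_at(sdi0), g23,
                                  ax_rule = "constant_hazard")$ex[1]
    exp_out <- expected_mortality_le(ensembles, sdi0)
    expect_lt(abs(exp_out$e0 - truth_e0), 0.5)
    # interior predictions stay inside the training envelope
    expect_true(all(log(exp_out$mx) >= apply(log(train_mx), 1, min) - 1e-6))
    expect_true(all(log(exp_out$mx) <= apply(log(train_mx), 1, max) + 1e-6))
  }
  # the observed-minus-expected difference vanishes at equality
  obs <- expected_mortality_le(ensembles, 0.5)
  same <- expected_mortality_le(ensembles, 0.5, observed_mx = obs$mx)
  expect_equal(same$e0_diff, 0, tolerance = 1e-12)
  expect_warning(expected_mortality_le(ensembles, 1.2), "extrapolating")
})

test_that("expected fertility raking hits the target exactly", {
  s <- fertility_schedule(c(0.01, 0.1, 0.2, 0.15, 0.1, 0.04, 0.01, 0.004, 0.001))
  expect_equal(rake_expected_fertility(s, tfr_from_asfr(s))$asfr, s$asfr)
  s25 <- fertility_schedule(rep(0.5 / 9, 9))   # TFR 2.5
  r <- rake_expected_fertility(s25, 2.0)
  # target 2.0 from current 2.5: factor 0.8 on every group
  expect_equal(r$asfr, 0.8 * s25$asfr, tolerance = 1e-12)
  expect_equal(tfr_from_asfr(r), 2.0, tolerance = 1e-12)
  set.seed(2)
  s2 <- fertility_schedule(runif(9, 0, 0.2))
  expect_equal(tfr_from_asfr(rake_expected_fertility(s2, 3.3)), 3.3,
               tolerance = 1e-12)
  expect_error(rake_expected_fertility(fertility_schedule(rep(0, 9)), 1), "zero")
})

test_that("the correlation helper matches the textbook formula", {
  expect_equal(pearson_correlation(1:10, 2 * (1:10) + 1), 1)
  expect_equal(pearson_correlation(1:10, -(1:10)), -1)
  set.seed(6)
  a <- rnorm(50); b <- rnorm(50)
  oracle <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_correlation(a, b), oracle, tolerance = 1e-12)
  expect_error(pearson_correlation(rep(1, 5), 1:5), "variance")
})
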