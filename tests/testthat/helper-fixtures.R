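# Shared fixtures: parametric hazard schedules, stationary registration
# datasets, and small synthetic worlds, all built in code.

siler_mx <- function(grid, a1 = 0.08, b1 = 1.1, a2 = 1e-3, a3 = 1e-4,
                     b3 = 0.095) {
  demrecon:::siler_interval_mx(grid$age_start, grid$age_width, a1, b1, a2, a3, b3)
}

gompertz_mx <- function(grid, A = 5e-5, B = 0.09) {
  mid <- ifelse(is.finite(grid$age_width),
                grid$age_start + grid$age_width / 2, grid$age_start + 4)
  A * exp(B * mid)
}

# stationary population with registered deaths thinned to `c_thin` and the
# second census's coverage scaled by `k_cov`
stationary_registration <- function(c_thin = 1, k_cov = 1, T = 10,
                                    exaggerate_old = 1, ages = seq(0, 85, 5)) {
  grid <- build_age_grid(cbind(ages, c(rep(5, length(ages) - 1), Inf)))
  lt <- lifetable_from_mx(siler_mx(grid), grid, "constant_hazard", radix = 1e5)
  N <- lt$Lx
  D <- lt$dx * T * c_thin
  D[ages >= 75] <- D[ages >= 75] * exaggerate_old
  registration_dataset(
    census1 = data.frame(age_start = ages, count = N),
    census2 = data.frame(age_start = ages, count = N * k_cov),
    deaths = data.frame(age_start = ages, count = D),
    date1 = 2000, date2 = 2000 + T
  )
}

# registration data whose growth-balance diagnostic is exactly linear:
# equal censuses, and group deaths defined so D(x+) = c * entry(x)
linear_registration <- function(c_true = 0.7, ages = seq(0, 85, 5)) {
  m <- length(ages)
  N <- 1e5 * exp(-0.04 * ages)
  entry <- c(NA, (N[-m] + N[-1]) / 10)
  D <- numeric(m)
  D[2:(m - 1)] <- c_true * (entry[2:(m - 1)] - entry[3:m])
  D[m] <- c_true * entry[m]
  T <- 10
  registration_dataset(
    census1 = data.frame(age_start = ages, count = N),
    census2 = data.frame(age_start = ages, count = N),
    deaths = data.frame(age_start = ages, count = D * T),
    date1 = 2000, date2 = 2000 + T
  )
}

# small world used by several suites (memoised per session)
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- build_world(world_config(n_locations = 2, seed = 42))
    }
    cache
  }
})

# small projection inputs shared by the population and acceptance suites
proj_inputs <- function(H = 20, ages = seq(0, 60, by = 5), seed = 7,
                        mort_scale = 1) {
  set.seed(seed)
  n <- length(ages)
  grid <- build_age_grid(cbind(ages, c(rep(5, n - 1), Inf)))
  mxv <- siler_mx(grid, a1 = 0.1) * mort_scale
  list(
    ages = ages, n = n, H = H,
    baseline = cbind(f = exp(seq(log(5000), log(800), length.out = n)),
                     m = exp(seq(log(5200), log(700), length.out = n))),
    asfr = matrix(rep(c(0.01, 0.08, 0.15, 0.14, 0.1, 0.05, 0.02, 0.005, 0.001),
                      each = H), H, 9),
    mx = array(rep(mxv, each = H), c(H, n, 2))
  )
}

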