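# Synthetic demographic worlds: scripted ground-truth histories (fertility,
# mortality, population, migration, stage labels) plus the noisy
# multi-source observations (vital registration, censuses, complete and
# summary birth histories, sibling histories) that the estimation modules
# consume in validation.

logistic_path <- function(years, start, end, midpoint, steepness = 0.15) {
  start + (end - start) / (1 + exp(-steepness * (years - midpoint)))
}

#' Configuration of a synthetic world
#'
#' Defaults describe a "classical transition" over 1950-2019: total
#' fertility falling from 6.5 to 1.8 births per woman, under-5 mortality
#' from 0.25 to 0.02 and adult mortality (45q15) from 0.45 to 0.08, with
#' the mortality decline leading the fertility decline by two decades.
#' Observation defaults are benign (complete registration, 3% census
#' coverage error at decennial censuses); scenario presets perturb them.
#'
#' @param n_locations number of locations (small deterministic parameter
#'   jitter differentiates them); locations are `loc1..locN` grouped under
#'   two regions in the toy hierarchy.
#' @param years calendar years of the world.
#' @param tfr list `start`, `end`, `midpoint`, `steepness` of the logistic
#'   TFR path.
#' @param asfr_shape relative age pattern over the nine maternal groups
#'   (normalised internally).
#' @param srb sex ratio at birth.
#' @param q5,q45 logistic path parameters for under-5 and adult mortality
#'   (female; male targets are scaled up by `male_q5_factor`,
#'   `male_q45_factor`).
#' @param male_q5_factor,male_q45_factor male-to-female target ratios.
#' @param migration `list(scenario = "none"|"emigration_wave"|
#'   "immigration_wave", level, start, length)`: `level` is the annual net
#'   migrant total at the wave peak as a fraction of population.
#' @param hiv `list(enabled, amplitude, peak_year, sd_years)`: an extra
#'   adult (15-59) death-rate bump, Gaussian in time.
#' @param shocks data.frame `year`, `total_deaths_frac` (fraction of that
#'   year's population) and `cause`, or `NULL`.
#' @param observation list: `vr_completeness` (`list(start, end, midpoint)`
#'   logistic path, constant if `start == end`), `census_years`,
#'   `census_coverage_sd`, `survey_years`, `n_mothers`, `n_respondents`,
#'   `sibling_frailty_sd`.
#' @param baseline_size radix population per location at the first year.
#' @param seed master seed; all streams derive from it.
#' @return list of class `world_config`.
#' @export
world_config <- function(n_locations = 2, years = 1950:2019,
                         tfr = list(start = 6.5, end = 1.8, midpoint = 1995,
                                    steepness = 0.12),
                         asfr_shape = c(0.02, 0.12, 0.25, 0.24, 0.18, 0.11,
                                        0.05, 0.02, 0.01),
                         srb = 1.05,
                         q5 = list(start = 0.25, end = 0.02, midpoint = 1975,
                                   steepness = 0.10),
                         q45 = list(start = 0.45, end = 0.08, midpoint = 1975,
                                    steepness = 0.10),
                         male_q5_factor = 1.15, male_q45_factor = 1.25,
                         migration = list(scenario = "none", level = 0.005,
                                          start = 1985, length = 15),
                         hiv = list(enabled = FALSE, amplitude = 0.008,
                                    peak_year = 1998, sd_years = 6),
                         shocks = NULL,
                         observation = list(vr_completeness = list(start = 1,
                                                                   end = 1,
                                                                   midpoint = 1985),
                                            census_years = seq(1950, 2010, 10),
                                            census_coverage_sd = 0.03,
                                            survey_years = c(1990, 2000, 2010),
                                            n_mothers = 2000,
                                            n_respondents = 1500,
                                            sibling_frailty_sd = 0),
                         baseline_size = 1e6, seed = 1L) {
  cfg <- as.list(environment())
  stopifnot(all(cfg$asfr_shape >= 0), cfg$srb > 0,
            cfg$observation$vr_completeness$start > 0,
            cfg$observation$vr_completeness$start <= 1,
            cfg$observation$vr_completeness$end > 0,
            cfg$observation$vr_completeness$end <= 1)
  if (!is.null(cfg$shocks) && !all(cfg$shocks$year %in% years)) {
    stop("shock years outside the world's years", call. = FALSE)
  }
  if (isTRUE(cfg$hiv$enabled) &&
      (cfg$hiv$peak_year < min(years) || cfg$hiv$peak_year > max(years))) {
    stop("HIV peak outside the world's years", call. = FALSE)
  }
  cfg$asfr_shape <- cfg$asfr_shape / sum(cfg$asfr_shape)
  structure(cfg, class = "world_config")
}

#' Scenario presets
#'
#' @param name one of `"classical_transition"`, `"hiv_epidemic"`,
#'   `"conflict_shock"`, `"incomplete_vr"`, `"emigration_wave"`.
#' @param ... overrides passed to [world_config()].
#' @return a [world_config()].
#' @export
scenario_preset <- function(name = c("classical_transition", "hiv_epidemic",
                                     "conflict_shock", "incomplete_vr",
                                     "emigration_wave"), ...) {
  name <- match.arg(name)
  extra <- switch(name,
    classical_transition = list(),
    hiv_epidemic = list(hiv = list(enabled = TRUE, amplitude = 0.008,
                                   peak_year = 1998, sd_years = 6)),
    conflict_shock = list(shocks = data.frame(year = 1994,
                                              total_deaths_frac = 0.02,
                                              cause = "conflict")),
    incomplete_vr = list(observation = utils::modifyList(
      formals(world_config)$observation |> eval(),
      list(vr_completeness = list(start = 0.5, end = 0.9, midpoint = 1985)))),
    emigration_wave = list(migration = list(scenario = "emigration_wave",
                                            level = 0.008, start = 1985,
                                            length = 15))
  )
  do.call(world_config, utils::modifyList(extra, list(...)))
}

# aggregate a gbd23 life table to the world's 5-year population grid
gbd23_to_pop_mx <- function(lt, pop_ages) {
  n <- length(pop_ages)
  out <- numeric(n)
  grp <- findInterval(lt$age_start, c(pop_ages, Inf))
  for (i in seq_len(n)) {
    sel <- grp == i
    out[i] <- sum(lt$dx[sel]) / sum(lt$Lx[sel])
  }
  out
}

world_mortality <- function(cfg, lib, jit) {
  years <- cfg$years; H <- length(years)
  pop_ages <- seq(0, 80, by = 5)
  q5f <- pmin(pmax(logistic_path(years, cfg$q5$start * jit, cfg$q5$end * jit,
                                 cfg$q5$midpoint, cfg$q5$steepness), 1e-4), 0.9)
  q45f <- pmin(pmax(logistic_path(years, cfg$q45$start * jit, cfg$q45$end * jit,
                                  cfg$q45$midpoint, cfg$q45$steepness), 1e-3), 0.9)
  q5m <- pmin(q5f * cfg$male_q5_factor, 0.9)
  q45m <- pmin(q45f * cfg$male_q45_factor, 0.9)
  mx5 <- array(0, c(H, length(pop_ages), 2))
  lts <- vector("list", H)
  for (t in seq_len(H)) {
    ltf <- fit_relational(select_standard(lib, list(q5_0 = q5f[t], q45_15 = q45f[t]), 3)$lx,
                          list(q5_0 = q5f[t], q45_15 = q45f[t]))$lt
    ltm <- fit_relational(select_standard(lib, list(q5_0 = q5m[t], q45_15 = q45m[t]), 3)$lx,
                          list(q5_0 = q5m[t], q45_15 = q45m[t]))$lt
    mx5[t, , 1] <- gbd23_to_pop_mx(ltf, pop_ages)
    mx5[t, , 2] <- gbd23_to_pop_mx(ltm, pop_ages)
    lts[[t]] <- list(f = ltf, m = ltm)
  }
  if (isTRUE(cfg$hiv$enabled)) {
    bump <- cfg$hiv$amplitude * exp(-(years - cfg$hiv$peak_year)^2 /
                                      (2 * cfg$hiv$sd_years^2))
    adult <- pop_ages >= 15 & pop_ages < 60
    for (t in seq_len(H)) mx5[t, adult, ] <- mx5[t, adult, ] + bump[t]
  }
  w0 <- t(vapply(lts, function(l) {
    c(f = (l$f$lx[1] - lx_at(l$f, 1)) / (l$f$lx[1] - lx_at(l$f, 5)),
      m = (l$m$lx[1] - lx_at(l$m, 1)) / (l$m$lx[1] - lx_at(l$m, 5)))
  }, numeric(2)))
  list(mx5 = mx5, lts = lts, pop_ages = pop_ages,
       q5 = cbind(f = q5f, m = q5m), q45 = cbind(f = q45f, m = q45m),
       infant_share = w0)
}

world_migration <- function(cfg, H, n_age, years, pop_total) {
  mig <- array(0, c(H, n_age, 2))
  if (cfg$migration$scenario == "none") return(mig)
  sgn <- if (cfg$migration$scenario == "emigration_wave") -1 else 1
  shape <- exp(-((seq_len(n_age) * 5 - 2.5 - 25) / 12)^2) + 0.25
  shape <- shape / sum(shape)
  on <- years >= cfg$migration$start &
    years < cfg$migration$start + cfg$migration$length
  for (t in which(on)) {
    lv <- sgn * cfg$migration$level * pop_total
    mig[t, , 1] <- 0.5 * lv * shape
    mig[t, , 2] <- 0.5 * lv * shape
  }
  mig
}

#' Build the ground truth of a synthetic world
#'
#' Constructs, per location, the true fertility and mortality schedules
#' (mortality via the relational model life table machinery), runs the
#' cohort-component projection for the population and event ledgers,
#' applies any shock events (disaggregated by a young-adult-male conflict
#' pattern when the cause is `"conflict"`, proportional to population
#' otherwise), and derives crude-rate trajectories and ground-truth
#' transition stage labels (the stage definitions applied to the
#' noise-free rate series). Deterministic given the seed.
#'
#' @param cfg a [world_config()].
#' @return a `truth_bundle`: list with `cfg`, `locations`, `years`,
#'   `pop_ages`, `hierarchy`, and per-location entries carrying `asfr`,
#'   `mx5`, `lifetables`, `pop`, `ledger`, `deaths_age`, `person_years`,
#'   `migration`, `q5`, `q45`, `rates` (CBR/CDR/NRI/net migration rate per
#'   1000) and `labels`.
#' @export
build_world <- function(cfg) {
  lib <- standard_library()
  years <- cfg$years; H <- length(years)
  locs <- paste0("loc", seq_len(cfg$n_locations))
  hierarchy <- data.frame(
    location = c("global", "regionA", "regionB", locs),
    parent = c(NA, "global", "global",
               rep(c("regionA", "regionB"), length.out = cfg$n_locations))
  )
  out <- list(cfg = cfg, locations = locs, years = years,
              hierarchy = hierarchy)
  world <- list()
  for (li in seq_along(locs)) {
    jit <- 1 + 0.1 * ((derive_seed(cfg$seed, c("jit", li)) %% 11) - 5) / 5
    mort <- world_mortality(cfg, lib, jit)
    pop_ages <- mort$pop_ages
    n_age <- length(pop_ages)
    tfr_path <- logistic_path(years, cfg$tfr$start * jit, cfg$tfr$end,
                              cfg$tfr$midpoint, cfg$tfr$steepness)
    asfr <- outer(tfr_path / 5, cfg$asfr_shape)
    # baseline age structure from the first year's life tables
    struct_f <- mort$lts[[1]]$f$Lx; struct_m <- mort$lts[[1]]$m$Lx
    to5 <- function(Lx, lt) {
      grp <- findInterval(lt$age_start, c(pop_ages, Inf))
      as.numeric(tapply(Lx, grp, sum))
    }
    bf <- to5(struct_f, mort$lts[[1]]$f); bm <- to5(struct_m, mort$lts[[1]]$m)
    base <- cbind(f = bf / sum(bf + bm), m = bm / sum(bf + bm)) * cfg$baseline_size
    # burn-in under the first year's rates so the world opens on the stable
    # age structure of its initial regime (no cohort waves from the seed)
    burn <- project_ccmpp(base, pop_ages,
                          matrix(asfr[1, ], 60, 9, byrow = TRUE),
                          array(rep(mort$mx5[1, , ], each = 60), c(60, n_age, 2)),
                          horizon = 60, detail = FALSE)
    base <- burn$pop[61, , ] * (cfg$baseline_size / sum(burn$pop[61, , ]))
    colnames(base) <- c("f", "m")
    mig <- world_migration(cfg, H, n_age, years, cfg$baseline_size)
    proj <- project_ccmpp(base, pop_ages, asfr, mort$mx5, migration = mig,
                          srb = cfg$srb)
    deaths_age <- proj$deaths_age
    shock_deaths <- rep(0, H)
    if (!is.null(cfg$shocks)) {
      for (s in seq_len(nrow(cfg$shocks))) {
        t <- match(cfg$shocks$year[s], years)
        popdf <- data.frame(sex = rep(c("f", "m"), each = n_age),
                            age_start = rep(pop_ages, 2),
                            count = c(proj$pop[t, , 1], proj$pop[t, , 2]))
        pat <- shock_pattern(cfg$shocks$cause[s], pop_ages)
        total <- cfg$shocks$total_deaths_frac[s] * sum(popdf$count)
        al <- disaggregate_shock(total, popdf, pat)
        deaths_age[t, , 1] <- deaths_age[t, , 1] + al$deaths[al$sex == "f"]
        deaths_age[t, , 2] <- deaths_age[t, , 2] + al$deaths[al$sex == "m"]
        shock_deaths[t] <- shock_deaths[t] + total
      }
    }
    ledger <- proj$ledger
    ledger$deaths <- ledger$deaths + shock_deaths
    py_tot <- apply(proj$person_years, 1, sum)
    rates <- data.frame(
      year = years,
      cbr = 1000 * ledger$births / py_tot,
      cdr = 1000 * ledger$deaths / py_tot,
      net_migration_rate = 1000 * ledger$net_migration / py_tot
    )
    rates$nri <- rates$cbr - rates$cdr
    labels <- classify_trajectory(rates)
    world[[locs[li]]] <- list(
      asfr = asfr, tfr = tfr_path, srb = cfg$srb,
      mx5 = mort$mx5, lifetables = mort$lts,
      q5 = mort$q5, q45 = mort$q45, infant_share = mort$infant_share,
      pop = proj$pop, ledger = ledger, deaths_age = deaths_age,
      person_years = proj$person_years, migration = mig,
      rates = rates, labels = labels
    )
  }
  out$pop_ages <- seq(0, 80, by = 5)
  out$world <- world
  structure(out, class = "truth_bundle")
}

#' @export
print.truth_bundle <- function(x, ...) {
  cat("<truth_bundle> ", length(x$locations), " locations, ",
      min(x$years), "-", max(x$years), "\n", sep = "")
  invisible(x)
}

#' Global age-sex pattern rates for shock disaggregation
#'
#' @param cause `"conflict"` (young-adult male concentration) or anything
#'   else (uniform rates, i.e. allocation proportional to population).
#' @param pop_ages 5-year group starts.
#' @return data.frame `sex`, `age_start`, `rate_weight`.
#' @export
shock_pattern <- function(cause, pop_ages = seq(0, 80, by = 5)) {
  base <- rep(1, length(pop_ages))
  if (identical(cause, "conflict")) {
    male <- 0.3 + 3 * exp(-((pop_ages + 2.5 - 27) / 10)^2)
    female <- 0.3 + 0.8 * exp(-((pop_ages + 2.5 - 27) / 12)^2)
  } else {
    male <- base; female <- base
  }
  data.frame(sex = rep(c("f", "m"), each = length(pop_ages)),
             age_start = rep(pop_ages, 2),
             rate_weight = c(female, male))
}

vr_completeness_path <- function(cfg) {
  vc <- cfg$observation$vr_completeness
  if (vc$start == vc$end) rep(vc$start, length(cfg$years))
  else logistic_path(cfg$years, vc$start, vc$end, vc$midpoint, 0.15)
}

#' Administrative observations: vital registration and censuses
#'
#' Registered deaths are binomial thinnings of the true death counts with
#' the completeness path `c(t)` (exact when `c = 1`); registered births use
#' complete registration; census counts are the true populations times
#' log-normal coverage noise at the census dates (exact when the coverage
#' SD is 0).
#'
#' @param truth a [build_world()] bundle.
#' @param seed observation-stage seed (defaults to the world seed).
#' @return list with `vr_deaths` (location, year, sex, age_start, count),
#'   `vr_births` (location, year, count), `censuses` (location, year, sex,
#'   age_start, count), and `completeness` (location, year, c).
#' @export
observe_admin <- function(truth, seed = NULL) {
  cfg <- truth$cfg
  if (is.null(seed)) seed <- cfg$seed
  cpath <- vr_completeness_path(cfg)
  sd_cov <- cfg$observation$census_coverage_sd
  ages <- truth$pop_ages
  vr_deaths <- list(); censuses <- list(); vr_births <- list()
  for (loc in truth$locations) {
    w <- truth$world[[loc]]
    set.seed(derive_seed(seed, c("admin", loc)))
    for (t in seq_along(truth$years)) {
      D <- w$deaths_age[t, , ]
      obs <- if (cpath[t] == 1) D else
        matrix(stats::rbinom(length(D), round(D), cpath[t]), nrow(D))
      vr_deaths[[length(vr_deaths) + 1]] <- data.frame(
        location = loc, year = truth$years[t],
        sex = rep(c("f", "m"), each = length(ages)),
        age_start = rep(ages, 2), count = c(obs[, 1], obs[, 2]))
      vr_births[[length(vr_births) + 1]] <- data.frame(
        location = loc, year = truth$years[t], count = w$ledger$births[t])
    }
    for (cy in cfg$observation$census_years) {
      t <- match(cy, truth$years)
      if (is.na(t)) next
      P <- w$pop[t, , ]
      noise <- if (sd_cov == 0) 1 else
        exp(matrix(stats::rnorm(length(P), 0, sd_cov), nrow(P)))
      censuses[[length(censuses) + 1]] <- data.frame(
        location = loc, year = cy,
        sex = rep(c("f", "m"), each = length(ages)),
        age_start = rep(ages, 2), count = c((P * noise)[, 1], (P * noise)[, 2]))
    }
  }
  list(vr_deaths = do.call(rbind, vr_deaths),
       vr_births = do.call(rbind, vr_births),
       censuses = do.call(rbind, censuses),
       completeness = data.frame(year = truth$years, c = cpath))
}

simulate_mother <- function(age_at_survey, survey_t, asfr, q5, w0, years, srb) {
  # one mother's birth history: annual fertility draws over her reproductive
  # life; each child's under-5 fate is a single draw against the period
  # cohort probability q5 at birth, with the death age drawn from the
  # life-table under-5 distribution (infant share w0, remainder uniform
  # over ages 1-4)
  births <- list()
  for (t in seq_len(survey_t)) {
    age <- age_at_survey - (survey_t - t)
    if (age < 10 || age >= 55) next
    grp <- findInterval(age, seq(10, 55, by = 5))
    if (stats::runif(1) < asfr[t, grp]) {
      sex <- if (stats::runif(1) < 1 / (1 + srb)) 1 else 2
      dies <- stats::runif(1) < q5[t, sex]
      death_age <- NA_real_
      if (dies) {
        death_age <- if (stats::runif(1) < w0[t, sex]) stats::runif(1)
        else stats::runif(1, 1, 5)
      }
      age_now <- survey_t - t
      # deaths after the survey date are not yet observed
      died_obs <- dies && death_age < age_now + stats::runif(1)
      births[[length(births) + 1]] <- data.frame(
        birth_t = t, sex = sex, died_under5 = died_obs,
        death_age = ifelse(died_obs, death_age, NA_real_),
        observed_age = age_now)
    }
  }
  if (!length(births)) return(NULL)
  do.call(rbind, births)
}

#' Survey observations: birth histories and sibling histories
#'
#' Samples mothers (for complete and summary birth histories) and adult
#' respondents (for sibling histories) from the true population and
#' simulates individual event histories from the true period rates.
#' Sibling survival after age 15 uses the period adult hazard implied by
#' 45q15, optionally multiplied by a shared log-normal sibship frailty
#' (clustered mortality); respondents are sampled with probability
#' proportional to the number of surviving adult members of the sibship,
#' reproducing the selection bias the weighted estimator corrects.
#'
#' @param truth a [build_world()] bundle.
#' @param survey_year calendar year of the survey.
#' @param location location id.
#' @param seed survey-stage seed.
#' @return list with `cbh` (child-level records), `sbh` (one row per
#'   maternal age group: `maternal_age_start`, `women`, `ceb`,
#'   `surviving`, `survey_date`), and `siblings` (one row per reported
#'   sibling, see [sibling_45q15()]).
#' @export
observe_surveys <- function(truth, survey_year, location = truth$locations[1],
                            seed = NULL) {
  cfg <- truth$cfg
  if (is.null(seed)) seed <- cfg$seed
  w <- truth$world[[location]]
  years <- truth$years
  st <- match(survey_year, years)
  if (is.na(st)) stop("survey year outside the world", call. = FALSE)
  set.seed(derive_seed(seed, c("survey", location, survey_year)))
  n_m <- cfg$observation$n_mothers
  # mothers aged 15-49 at survey, sampled from the female population
  pf <- w$pop[st, , 1]
  wa <- truth$pop_ages >= 15 & truth$pop_ages < 50
  pr <- pf[wa] / sum(pf[wa])
  grp_draw <- sample(which(wa), n_m, replace = TRUE, prob = pr)
  mother_age <- truth$pop_ages[grp_draw] + stats::runif(n_m, 0, 5)
  cbh <- list(); sbh_tab <- list()
  for (i in seq_len(n_m)) {
    h <- simulate_mother(mother_age[i], st, w$asfr, w$q5, w$infant_share,
                         years, w$srb)
    if (!is.null(h)) { h$mother_id <- i; h$mother_age <- mother_age[i]; cbh[[length(cbh) + 1]] <- h }
  }
  cbh <- if (length(cbh)) do.call(rbind, cbh) else NULL
  magrp <- 5 * (mother_age %/% 5)
  sbh <- do.call(rbind, lapply(seq(15, 45, by = 5), function(a) {
    sel_m <- which(magrp == a)
    kids <- if (is.null(cbh)) NULL else cbh[cbh$mother_id %in% sel_m, , drop = FALSE]
    data.frame(maternal_age_start = a, women = length(sel_m),
               ceb = if (is.null(kids)) 0 else nrow(kids),
               surviving = if (is.null(kids)) 0 else sum(!kids$died_under5),
               survey_date = survey_year)
  }))
  # sibling histories: sibships of adults born 15-60 years before survey
  n_r <- cfg$observation$n_respondents
  fr_sd <- cfg$observation$sibling_frailty_sd
  q45_path <- (w$q45[, "f"] + w$q45[, "m"]) / 2
  h_adult <- -log(1 - q45_path) / 45
  sib <- list()
  made <- 0; rid <- 0
  while (rid < n_r && made < n_r * 20) {
    made <- made + 1
    size <- 1 + stats::rpois(1, 2.5)
    anchor_by <- st - sample(20:55, 1)
    byrs <- anchor_by + sample(-8:8, size, replace = TRUE)
    frail <- if (fr_sd > 0) exp(stats::rnorm(1, -fr_sd^2 / 2, fr_sd)) else 1
    death_year <- rep(NA_real_, size)
    for (s in seq_len(size)) {
      if (byrs[s] >= st) { byrs[s] <- st - 1 }
      # child survival once, then annual adult hazard from age 15
      tb <- max(byrs[s], 1)
      if (stats::runif(1) < w$q5[tb, 1]) { death_year[s] <- byrs[s] + 2; next }
      for (t in (byrs[s] + 15):(st - 1)) {
        if (t < 1) next
        if (t > length(years)) break
        age <- t - byrs[s]
        if (age >= 60) break
        if (stats::runif(1) < 1 - exp(-frail * h_adult[min(t, length(years))])) {
          death_year[s] <- t; break
        }
      }
    }
    age_at_survey <- st - byrs
    potential <- is.na(death_year) & age_at_survey >= 15 & age_at_survey < 50
    n_surv <- sum(potential)
    if (n_surv == 0) next     # unobservable sibship
    # sample the sibship with probability proportional to survivors
    if (stats::runif(1) > n_surv / size) next
    rid <- rid + 1
    resp <- sample(which(potential), 1)
    others <- setdiff(seq_len(size), resp)
    if (!length(others)) next
    sib[[length(sib) + 1]] <- data.frame(
      respondent_id = rid, birth_year = years[1] - 1 + byrs[others],
      death_year = ifelse(is.na(death_year[others]), NA,
                          years[1] - 1 + death_year[others]),
      sibship_size = size, surviving_respondents = n_surv,
      survey_year = survey_year)
  }
  list(cbh = cbh, sbh = sbh,
       siblings = if (length(sib)) do.call(rbind, sib) else NULL)
}

#' Pool a truth bundle into a vital event series
#'
#' @param truth a [build_world()] bundle.
#' @return a [vital_series()] with one all-age row per location-year.
#' @export
truth_vital_series <- function(truth) {
  rows <- list()
  for (loc in truth$locations) {
    w <- truth$world[[loc]]
    rows[[loc]] <- data.frame(
      location = loc, year = truth$years, sex = "total", age_start = 0,
      person_years = apply(w$person_years, 1, sum),
      deaths = w$ledger$deaths, births = w$ledger$births)
  }
  vital_series(do.call(rbind, rows))
}
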