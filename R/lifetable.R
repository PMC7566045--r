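#' Average-age-at-death coefficients for young ages
#'
#' Piecewise-linear rules, in the Coale-Demeny style, giving the mean years
#' lived within the interval by those dying in it (ax) for the infant
#' interval and ages 1-4, as linear functions of the infant death rate 1m0
#' below a threshold and constants above it. The shipped defaults are the
#' classic values for males and females, with `"total"` their average; the
#' table is configurable because published conventions differ at the margins.
#'
#' @param sex one of `"total"`, `"female"`, `"male"`.
#' @return a list with components `a0` and `a1`, each
#'   `c(threshold, intercept, slope, high)`: ax = intercept + slope * 1m0
#'   when 1m0 < threshold, else `high`.
#' @export
ax_coefficients <- function(sex = c("total", "female", "male")) {
  sex <- match.arg(sex)
  tab <- list(
    male   = list(a0 = c(0.107, 0.045, 2.684, 0.330),
                  a1 = c(0.107, 1.651, -2.816, 1.352)),
    female = list(a0 = c(0.107, 0.053, 2.800, 0.350),
                  a1 = c(0.107, 1.522, -1.518, 1.361)),
    total  = list(a0 = c(0.107, 0.049, 2.742, 0.340),
                  a1 = c(0.107, 1.5865, -2.167, 1.3565))
  )
  tab[[sex]]
}

apply_ax_rule <- function(co, m) {
  if (m < co[1]) co[2] + co[3] * m else co[4]
}

# default ax vector for the "midpoint+infant" rule
default_ax <- function(mx, grid, coefs) {
  starts <- grid$age_start
  widths <- grid$age_width
  k <- length(starts)
  ax <- widths / 2
  ax[k] <- NA_real_ # open interval: ax not used (Lx = lx / mx)
  # infant rate on whatever under-1 representation the grid uses
  u1 <- which(starts < 1 & widths < Inf)
  if (length(u1)) {
    m0 <- sum(mx[u1] * widths[u1]) / sum(widths[u1])
    a0 <- apply_ax_rule(coefs$a0, m0)
    if (length(u1) == 1 && widths[u1] == 1) {
      ax[u1] <- a0
    } else {
      # neonatal splits keep midpoint ax; the post-neonatal interval absorbs
      # the infant mean age at death, shifted to its own origin
      last <- u1[length(u1)]
      ax[last] <- min(max(a0 - starts[last], 0.05 * widths[last]),
                      0.95 * widths[last])
    }
    i14 <- which(starts == 1 & widths == 4)
    if (length(i14)) ax[i14] <- apply_ax_rule(coefs$a1, m0)
  }
  ax
}

#' Build a life table from age-specific death rates
#'
#' Converts a schedule of central death rates mx on an age grid into the
#' full set of life-table columns (radix 100 000 by default).
#'
#' Two conversion rules are available:
#' * `"midpoint+infant"` (default): `qx = n*mx / (1 + (n - ax)*mx)` with
#'   `ax = n/2` for closed intervals from age 5 and Coale-Demeny-style
#'   infant/child ax derived from the infant death rate (see
#'   [ax_coefficients()]).
#' * `"constant_hazard"`: `qx = 1 - exp(-n*mx)` with the exact
#'   exponential-survival ax, so that a flat hazard mu yields e0 = 1/mu
#'   exactly and back-calculated dx/Lx reproduces mx to machine precision.
#'
#' In both rules `Lx = n*l(x+n) + ax*dx` for closed intervals, the open
#' interval has `qx = 1` and `Lx = lx/mx`, `Tx` cumulates `Lx` from the
#' bottom and `ex = Tx/lx`.
#'
#' @param mx non-negative death rates, one per grid interval; the terminal
#'   rate must be positive.
#' @param grid an [build_age_grid()] grid (or a name accepted by it).
#' @param ax_rule `"midpoint+infant"` or `"constant_hazard"`.
#' @param sex used to pick default ax coefficients.
#' @param radix survivors at exact age 0.
#' @param ax_coefs optional override of [ax_coefficients()].
#' @return a `life_table`: data.frame with columns `age_start`, `age_width`,
#'   `mx`, `ax`, `qx`, `lx`, `dx`, `Lx`, `Tx`, `ex`.
#' @export
#' @examples
#' g <- build_age_grid("single_year_0_110")
#' lt <- lifetable_from_mx(rep(0.01, nrow(g)), g, ax_rule = "constant_hazard")
#' lt$ex[1] # 100
lifetable_from_mx <- function(mx, grid,
                              ax_rule = c("midpoint+infant", "constant_hazard"),
                              sex = "total", radix = 1e5, ax_coefs = NULL) {
  grid <- stopifnot_grid(grid)
  ax_rule <- match.arg(ax_rule)
  k <- nrow(grid)
  if (length(mx) != k) stop("mx must have one value per age interval", call. = FALSE)
  if (any(mx < 0)) stop("negative mx", call. = FALSE)
  if (mx[k] <= 0) stop("terminal mx must be > 0", call. = FALSE)
  n <- grid$age_width

  if (ax_rule == "constant_hazard") {
    qx <- 1 - exp(-n * mx)
    ax <- ifelse(mx > 0 & is.finite(n), 1 / mx - n / expm1(n * mx), n / 2)
    ax[k] <- 1 / mx[k]
  } else {
    if (is.null(ax_coefs)) ax_coefs <- ax_coefficients(sex)
    ax <- default_ax(mx, grid, ax_coefs)
    qx <- n * mx / (1 + (n - ax) * mx)
    qx <- pmin(qx, 1)
  }
  qx[k] <- 1

  lx <- radix * cumprod(c(1, 1 - qx[-k]))
  dx <- lx * qx
  Lx <- n * c(lx[-1], 0) + ax * dx
  Lx[k] <- lx[k] / mx[k]
  # zero-rate closed intervals: full person-years
  zero <- which(mx[-k] == 0)
  if (length(zero)) Lx[zero] <- n[zero] * lx[zero]
  Tx <- rev(cumsum(rev(Lx)))
  ex <- ifelse(lx > 0, Tx / lx, 0)

  structure(
    data.frame(age_start = grid$age_start, age_width = n,
               mx = mx, ax = ax, qx = qx, lx = lx, dx = dx,
               Lx = Lx, Tx = Tx, ex = ex),
    class = c("life_table", "data.frame"),
    ax_rule = ax_rule, sex = sex, radix = radix
  )
}

#' @export
print.life_table <- function(x, ...) {
  summ <- tryCatch(summary_probabilities(x), error = function(e) NULL)
  cat("<life_table> ", nrow(x), " age groups, e0 = ", round(x$ex[1], 2), sep = "")
  if (!is.null(summ)) {
    cat(", 5q0 = ", signif(summ$q5_0, 4), ", 45q15 = ", signif(summ$q45_15, 4), sep = "")
  }
  cat("\n")
  invisible(x)
}

lt_grid <- function(lt) {
  structure(data.frame(age_start = lt$age_start, age_width = lt$age_width),
            class = c("age_grid", "data.frame"))
}

#' Survivorship at an exact age
#'
#' @param lt a [lifetable_from_mx()] life table.
#' @param age exact age in years.
#' @param interpolate if `TRUE`, ages strictly inside an interval are filled
#'   by monotone interpolation of log-survivorship; otherwise non-boundary
#'   ages are an error.
#' @return lx at the exact age (same radix as the table).
#' @export
lx_at <- function(lt, age, interpolate = FALSE) {
  bounds <- lt$age_start
  i <- match(TRUE, abs(bounds - age) < 1e-9)
  if (!is.na(i)) return(lt$lx[i])
  if (!interpolate) {
    stop("exact age ", age, " is not a grid boundary (set interpolate = TRUE)",
         call. = FALSE)
  }
  pos <- lt$lx > 0
  f <- stats::splinefun(bounds[pos], log(lt$lx[pos]), method = "monoH.FC")
  exp(f(age))
}

#' Summary probabilities of death and life expectancies
#'
#' Computes under-5 mortality `5q0 = 1 - l5/l0`, adult mortality
#' `45q15 = 1 - l60/l15`, and remaining life expectancy at requested exact
#' ages.
#'
#' @inheritParams lx_at
#' @param ex_ages exact ages at which to report ex (must be grid starts).
#' @return list with `q5_0`, `q45_15` and `ex` (named by age).
#' @export
summary_probabilities <- function(lt, ex_ages = 0, interpolate = FALSE) {
  l0 <- lt$lx[1]
  q5 <- 1 - lx_at(lt, 5, interpolate) / l0
  q45 <- 1 - lx_at(lt, 60, interpolate) / lx_at(lt, 15, interpolate)
  ex <- vapply(ex_ages, function(a) {
    i <- match(TRUE, abs(lt$age_start - a) < 1e-9)
    if (is.na(i)) stop("ex requested at non-boundary age ", a, call. = FALSE)
    lt$ex[i]
  }, numeric(1))
  names(ex) <- paste0("ex_", ex_ages)
  list(q5_0 = q5, q45_15 = q45, ex = ex)
}

#' Expand an abridged life table to single-year ages
#'
#' Survivorship is carried to integer ages by monotone piecewise-cubic
#' interpolation of log(lx) through the abridged boundaries (so boundary lx
#' values are preserved exactly and monotonicity cannot be violated); above
#' the last closed boundary the terminal hazard is applied as a constant.
#' Single-year rates are recovered as interval hazards
#' `mx = log(lx / l(x+1))` and the table rebuilt under the constant-hazard
#' rule, so a constant-hazard abridged input yields the same constant rate
#' at every single year.
#'
#' @param lt an abridged `life_table` with non-increasing lx.
#' @param max_age open-interval start of the output grid.
#' @return a `life_table` on the single-year grid `0..max_age`+.
#' @export
abridged_to_single_year <- function(lt, max_age = 110) {
  if (is.unsorted(rev(lt$lx))) stop("input lx must be non-increasing", call. = FALSE)
  top <- lt$age_start[nrow(lt)]
  m_open <- lt$mx[nrow(lt)]
  pos <- lt$lx > 0
  f <- stats::splinefun(lt$age_start[pos], log(lt$lx[pos]), method = "monoH.FC")
  ages <- 0:max_age
  loglx <- numeric(length(ages))
  inside <- ages <= max(lt$age_start[pos])
  loglx[inside] <- f(ages[inside])
  loglx[!inside] <- f(top) - m_open * (ages[!inside] - top)
  lx <- exp(loglx)
  mx1 <- c(loglx[-length(loglx)] - loglx[-1], m_open)
  mx1 <- pmax(mx1, 1e-12)
  grid <- build_age_grid(cbind(ages, c(rep(1, length(ages) - 1), Inf)))
  out <- lifetable_from_mx(mx1, grid, ax_rule = "constant_hazard",
                           sex = attr(lt, "sex") %||% "total",
                           radix = attr(lt, "radix") %||% lt$lx[1])
  # conserve each source group's person-years: the interpolant fixes lx at
  # the boundaries but not the within-group area, so rescale Lx per source
  # group (and refresh the dependent columns) to reproduce the abridged
  # expectancies
  scale <- out$lx[1] / lt$lx[1]
  bnd <- lt$age_start[lt$age_start == floor(lt$age_start)]
  src_single <- findInterval(out$age_start + 1e-12, bnd)
  src_abr <- findInterval(lt$age_start + 1e-12, bnd)
  for (gi in unique(src_single)) {
    rows <- which(src_single == gi)
    tgt <- sum(lt$Lx[src_abr == gi]) * scale
    cur <- sum(out$Lx[rows])
    if (cur > 0 && tgt > 0) out$Lx[rows] <- out$Lx[rows] * (tgt / cur)
  }
  closed <- is.finite(out$age_width)
  lead_lx <- c(out$lx[-1], 0)
  out$ax[closed] <- ifelse(out$dx[closed] > 0,
                           (out$Lx[closed] - lead_lx[closed]) / out$dx[closed],
                           out$ax[closed])
  out$mx[closed] <- ifelse(out$Lx[closed] > 0,
                           out$dx[closed] / out$Lx[closed], out$mx[closed])
  out$mx[!closed] <- out$lx[!closed] / out$Lx[!closed]
  out$Tx <- rev(cumsum(rev(out$Lx)))
  out$ex <- ifelse(out$lx > 0, out$Tx / out$lx, 0)
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Constrain detailed under-5 probabilities to a target 5q0
#'
#' The four provisional probabilities (early neonatal, late neonatal,
#' post-neonatal, 1-4 years) are adjusted by a single scalar k applied to
#' their hazards `-log(1-q)`, chosen so that the combined probability
#' `1 - prod(1 - q')` equals the target. Because the hazards scale jointly,
#' k has the closed form `log(1 - target) / sum(log(1 - q))`, which solves
#' the constraint exactly; the ordering of the four inputs is preserved.
#'
#' @param q provisional probabilities in \[0, 1).
#' @param target target combined probability in \[0, 1).
#' @return list with `q` (adjusted probabilities) and `k` (hazard scalar).
#' @export
constrain_under5_detail <- function(q, target) {
  if (any(q < 0 | q >= 1)) stop("provisional q must lie in [0,1)", call. = FALSE)
  if (target < 0 || target >= 1) stop("target must lie in [0,1)", call. = FALSE)
  if (target == 0) return(list(q = rep(0, length(q)), k = 0))
  h <- -log1p(-q)
  if (sum(h) == 0) stop("all provisional q are zero with nonzero target", call. = FALSE)
  k <- log1p(-target) / -sum(h)
  list(q = -expm1(-k * h), k = k)
}

#' Vital event series
#'
#' A validated long table of person-years, deaths and births by location,
#' year, sex and age interval, used for crude-rate bookkeeping.
#'
#' @param df data.frame with columns `location`, `year`, `sex`, `age_start`,
#'   `person_years`, `deaths`, `births` (births may be 0 outside maternal
#'   ages).
#' @return the validated data.frame with class `vital_series`.
#' @export
vital_series <- function(df) {
  need <- c("location", "year", "sex", "age_start", "person_years", "deaths", "births")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("vital_series missing columns: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  if (any(df$person_years < 0) || any(df$deaths < 0) || any(df$births < 0)) {
    stop("vital_series counts must be >= 0", call. = FALSE)
  }
  structure(df, class = c("vital_series", "data.frame"))
}

#' Crude birth, death and natural-increase rates
#'
#' @param vs a [vital_series()].
#' @param location,year the cell to summarise (all sexes and ages pooled).
#' @return list with `cbr`, `cdr`, `nri`, each per 1000 person-years
#'   (`nri = cbr - cdr`).
#' @export
crude_rates <- function(vs, location, year) {
  sub <- vs[vs$location == location & vs$year == year, , drop = FALSE]
  py <- sum(sub$person_years)
  if (py <= 0) stop("zero person-years for ", location, "/", year, call. = FALSE)
  cbr <- 1000 * sum(sub$births) / py
  cdr <- 1000 * sum(sub$deaths) / py
  list(cbr = cbr, cdr = cdr, nri = cbr - cdr)
}

#' Write / read life tables as CSV
#'
#' Serialisation with one row per age interval and an empty `age_width`
#' field for the open interval.
#'
#' @param lt a `life_table`.
#' @param path file path.
#' @param location,year,sex identifying columns written alongside.
#' @export
write_lifetable_csv <- function(lt, path, location = "loc", year = NA, sex = "total") {
  out <- cbind(location = location, year = year, sex = sex, as.data.frame(lt))
  out$age_width[is.infinite(out$age_width)] <- NA
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_lifetable_csv
#' @export
read_lifetable_csv <- function(path) {
  df <- utils::read.csv(path)
  df$age_width[is.na(df$age_width)] <- Inf
  structure(df[, c("age_start", "age_width", "mx", "ax", "qx", "lx", "dx", "Lx", "Tx", "ex")],
            class = c("life_table", "data.frame"),
            location = df$location[1], year = df$year[1], sex = df$sex[1])
}
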