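# Small numerical helpers shared across modules.

logit <- function(p) log(p / (1 - p))

inv_logit <- function(x) 1 / (1 + exp(-x))

#' Annualised (continuous) rate of change
#'
#' Log rate of change per year between two positive values, the convention
#' used for "annualised rate of change" summaries such as population growth
#' over 2010-19 (for which the elapsed time is 9 years).
#'
#' @param v_start,v_end positive values at the start and end of the interval.
#' @param n_years elapsed time in years (> 0).
#' @return rate per year; `v_start * exp(rate * n_years)` reproduces `v_end`.
#' @export
#' @examples
#' annualized_rate_of_change(100, 100 * exp(1), 10) # 0.1 per year
annualized_rate_of_change <- function(v_start, v_end, n_years) {
  if (any(v_start <= 0) || any(v_end <= 0)) {
    stop("annualized_rate_of_change() requires positive values", call. = FALSE)
  }
  if (n_years <= 0) stop("n_years must be > 0", call. = FALSE)
  log(v_end / v_start) / n_years
}

#' Pearson product-moment correlation
#'
#' Thin wrapper used when correlating summary indices (e.g. the
#' Socio-demographic Index against healthy life expectancy).
#'
#' @param a,b numeric vectors of equal length (>= 3), each with nonzero
#'   variance.
#' @return the correlation coefficient in \[-1, 1\].
#' @export
pearson_correlation <- function(a, b) {
  if (length(a) != length(b) || length(a) < 3) {
    stop("need equal-length series with at least 3 points", call. = FALSE)
  }
  if (stats::sd(a) == 0 || stats::sd(b) == 0) {
    stop("zero variance series", call. = FALSE)
  }
  stats::cor(a, b)
}

# Deterministic per-(stream, key) seed derived from a master seed, kept below
# 2^31 so it is always a valid R integer.
derive_seed <- function(master, key) {
  h <- sum(utf8ToInt(paste0(key, collapse = "|")) * seq_along(utf8ToInt(paste0(key, collapse = "|"))))
  as.integer((as.double(master) * 48271 + h) %% 2147483629L)
}
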