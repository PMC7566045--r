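# Summary birth histories: Brass-type conversion of children ever born /
# children surviving by maternal age into under-5 mortality estimates with
# reference dates.

#' Brass-type multiplier coefficients for summary birth histories
#'
#' The classic Trussell variant ("West" family): for maternal age group i
#' the proportion of children dead D(i) is mapped to a probability of dying
#' by exact child age x(i) through the multiplier
#' `k(i) = a + b*(P1/P2) + c*(P2/P3)`, where P1..P3 are mean parities of
#' women 15-19, 20-24, 25-29; the reference time (years before the survey
#' to which the estimate pertains) uses the companion coefficients
#' `t(i) = at + bt*(P1/P2) + ct*(P2/P3)`. The table is configuration: any
#' data.frame with the same columns can be swapped in (e.g. an identity
#' table with `x = 5`, `a = 1`, `b = c = 0` for testing).
#'
#' @return data.frame with columns `maternal_age_start`, `x`, `a`, `b`,
#'   `c`, `at`, `bt`, `ct`.
#' @export
trussell_coefficients <- function() {
  data.frame(
    maternal_age_start = seq(15, 45, by = 5),
    x  = c(1, 2, 3, 5, 10, 15, 20),
    a  = c(1.1415, 1.2563, 1.1851, 1.1720, 1.1865, 1.1746, 1.1639),
    b  = c(-2.7070, -0.5381, 0.0633, 0.2341, 0.3080, 0.3314, 0.3190),
    c  = c(0.7663, -0.2637, -0.4177, -0.4272, -0.4452, -0.4537, -0.4435),
    at = c(1.0970, 1.3062, 1.5305, 1.9991, 2.7632, 4.3468, 7.5242),
    bt = c(5.5628, 5.5677, 2.5528, -2.4261, -8.4065, -13.2436, -14.2013),
    ct = c(-1.9956, 0.2962, 4.8962, 10.4282, 16.1787, 20.1990, 20.0162)
  )
}

default_child_standard <- function() {
  # mid-mortality member of the synthetic standard library, expanded to
  # exact child ages by monotone log-survivorship interpolation
  lib <- standard_library(3, 3)
  s <- lib[[5]]
  grid <- attr(lib, "grid")
  lt <- lifetable_from_mx(s$mx, grid, ax_rule = "constant_hazard", radix = 1)
  function(x) 1 - lx_at(lt, x, interpolate = TRUE)  # q(x) of the standard
}

#' Convert summary birth histories to under-5 mortality
#'
#' Mean parities define the parity ratios P1/P2 and P2/P3; each used
#' maternal age group's proportion of children dead is multiplied by its
#' Brass-type coefficient to give q(x) at the group's index child age, and
#' q(x) is converted to q(5) through a one-parameter (level) logit shift of
#' a standard child mortality schedule. Reference dates come from the
#' companion time-location coefficients.
#'
#' @param records data.frame with one row per maternal 5-year age group:
#'   `maternal_age_start`, `women`, `ceb` (children ever born),
#'   `surviving`, `survey_date`. Groups 15-29 must be present (they define
#'   the parity ratios) even if not used for estimates.
#' @param coefficients a table as [trussell_coefficients()] (the default).
#' @param standard_q optional function `q(x)` giving the standard's
#'   probability of dying by exact child age x; default a mid-level member
#'   of the synthetic standard library. Ignored for rows with `x = 5`.
#' @param use_groups maternal age-group starts used for estimates
#'   (default 20, 25, 30).
#' @return data.frame with `maternal_age_start`, `x`, `qx`, `q5`,
#'   `reference_date`.
#' @export
sbh_to_u5mr <- function(records, coefficients = trussell_coefficients(),
                        standard_q = NULL, use_groups = c(20, 25, 30)) {
  req <- c("maternal_age_start", "women", "ceb", "surviving", "survey_date")
  if (!all(req %in% names(records))) {
    stop("records need columns: ", paste(req, collapse = ", "), call. = FALSE)
  }
  if (any(records$surviving > records$ceb)) {
    stop("surviving children exceed children ever born", call. = FALSE)
  }
  g <- function(a) records[records$maternal_age_start == a, , drop = FALSE]
  parity <- function(a) { r <- g(a); sum(r$ceb) / sum(r$women) }
  P1 <- parity(15); P2 <- parity(20); P3 <- parity(25)
  if (!is.finite(P2 / P3) || P2 == 0) stop("zero parities; cannot form ratios", call. = FALSE)
  pr12 <- P1 / P2; pr23 <- P2 / P3
  use <- records[records$maternal_age_start %in% use_groups, , drop = FALSE]
  if (sum(use$ceb) == 0) stop("zero children ever born in used groups", call. = FALSE)
  co <- coefficients[match(use$maternal_age_start, coefficients$maternal_age_start), ]
  D <- ifelse(use$ceb > 0, 1 - use$surviving / use$ceb, NA)
  k <- pmax(co$a + co$b * pr12 + co$c * pr23, 0.1)
  qx <- pmin(pmax(k * D, 0), 0.99)
  tt <- co$at + co$bt * pr12 + co$ct * pr23
  if (is.null(standard_q)) standard_q <- default_child_standard()
  q5 <- vapply(seq_along(qx), function(i) {
    if (is.na(qx[i])) return(NA_real_)
    if (co$x[i] == 5) return(qx[i])
    if (qx[i] == 0) return(0)
    alpha <- logit(qx[i]) - logit(standard_q(co$x[i]))
    inv_logit(alpha + logit(standard_q(5)))
  }, numeric(1))
  data.frame(maternal_age_start = use$maternal_age_start, x = co$x,
             qx = qx, q5 = q5,
             reference_date = use$survey_date - tt)
}
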