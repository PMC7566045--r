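# Readers for transcriptions of published results tables (point estimates
# with 95% uncertainty intervals in "a (b to c)" style), the toy location
# hierarchy, additive-consistency checks and derived indicators.

#' The standard location hierarchy preset
#'
#' Global, the seven super-regions, and the 21 regions of the standard
#' burden-of-disease location hierarchy (country level omitted in the
#' preset; rows may extend it).
#'
#' @return data.frame `location`, `level`, `parent`.
#' @export
gbd_hierarchy <- function() {
  sr <- c("Central Europe, eastern Europe, and central Asia", "High income",
          "Latin America and Caribbean", "North Africa and Middle East",
          "South Asia", "Southeast Asia, east Asia, and Oceania",
          "Sub-Saharan Africa")
  regions <- list(
    `Central Europe, eastern Europe, and central Asia` =
      c("Central Asia", "Central Europe", "Eastern Europe"),
    `High income` = c("Australasia", "High-income Asia Pacific",
                      "High-income North America", "Southern Latin America",
                      "Western Europe"),
    `Latin America and Caribbean` = c("Andean Latin America", "Caribbean",
                                      "Central Latin America",
                                      "Tropical Latin America"),
    `North Africa and Middle East` = "North Africa and Middle East",
    `South Asia` = "South Asia",
    `Southeast Asia, east Asia, and Oceania` = c("East Asia", "Oceania",
                                                 "Southeast Asia"),
    `Sub-Saharan Africa` = c("Central sub-Saharan Africa",
                             "Eastern sub-Saharan Africa",
                             "Southern sub-Saharan Africa",
                             "Western sub-Saharan Africa")
  )
  rbind(
    data.frame(location = "Global", level = "global", parent = NA),
    data.frame(location = sr, level = "super-region", parent = "Global"),
    do.call(rbind, lapply(sr, function(s) {
      data.frame(location = regions[[s]], level = "region", parent = s)
    }))
  )
}

#' Parse a published "value (lower to upper)" string
#'
#' Accepts middle-dot decimals, Unicode minus signs, thin or narrow
#' no-break spaces as thousands separators, and either "b to c" or an
#' en-dash "b-c" inside the parentheses; bare numbers parse with `NA`
#' bounds.
#'
#' @param s character vector.
#' @return data.frame `value`, `lower`, `upper`.
#' @export
parse_ui_string <- function(s) {
  clean <- function(x) {
    x <- gsub("\u00b7", ".", x)    # middle-dot decimal
    x <- gsub("\u2212", "-", x)    # unicode minus
    # ordinary, no-break, thin and narrow spaces used as thousands separators
    x <- gsub("[\u0020\u00a0\u2008\u2009\u202f]", "", x)
    x <- gsub("%", "", x)
    x
  }
  one <- function(x) {
    x <- trimws(x)
    m <- regmatches(x, regexec("^(.*?)\\((.*)\\)$", x))[[1]]
    if (length(m) == 3) {
      v <- as.numeric(clean(m[2]))
      inner <- m[3]
      parts <- if (grepl("to", inner)) strsplit(inner, "to")[[1]] else
        strsplit(inner, "–|—")[[1]]
      if (length(parts) != 2) stop("malformed UI string: ", x, call. = FALSE)
      lo <- as.numeric(clean(parts[1])); hi <- as.numeric(clean(parts[2]))
    } else {
      v <- as.numeric(clean(x)); lo <- NA_real_; hi <- NA_real_
    }
    if (is.na(v)) stop("malformed value string: ", x, call. = FALSE)
    c(v, lo, hi)
  }
  out <- t(vapply(s, one, numeric(3)))
  data.frame(value = out[, 1], lower = out[, 2], upper = out[, 3],
             row.names = NULL)
}

#' Read a transcribed results table
#'
#' @param file CSV with columns `location`, `level`, `parent`, `metric`,
#'   `year`, `value` (the published string, UI included).
#' @param hierarchy optional hierarchy (as [gbd_hierarchy()]); when given,
#'   locations other than country-level rows must appear in it, and when
#'   `validate_preset = TRUE` the preset's 7 super-regions / 21 regions
#'   counts are asserted.
#' @param validate_preset check the hierarchy shape.
#' @return data.frame of typed rows (`value`, `lower`, `upper` numeric);
#'   rows with a UI satisfy `lower <= value <= upper`.
#' @export
read_results_table <- function(file, hierarchy = NULL, validate_preset = FALSE) {
  raw <- utils::read.csv(file, encoding = "UTF-8", check.names = FALSE)
  need <- c("location", "level", "parent", "metric", "year", "value")
  if (!all(need %in% names(raw))) {
    stop("table must have columns: ", paste(need, collapse = ", "), call. = FALSE)
  }
  parsed <- parse_ui_string(raw$value)
  out <- cbind(raw[setdiff(names(raw), "value")], parsed)
  bad <- !is.na(out$lower) & !(out$lower <= out$value & out$value <= out$upper)
  if (any(bad)) stop("UI bounds do not bracket the value in ", sum(bad),
                     " rows", call. = FALSE)
  if (!is.null(hierarchy)) {
    if (validate_preset) {
      stopifnot(sum(hierarchy$level == "super-region") == 7,
                sum(hierarchy$level == "region") == 21)
    }
    known <- out$level == "country" | out$location %in% hierarchy$location
    if (!all(known)) {
      stop("unknown locations: ",
           paste(unique(out$location[!known]), collapse = "; "), call. = FALSE)
    }
  }
  out
}

#' Check additive consistency across the hierarchy
#'
#' For an additive count metric, sums the children of each parent present
#' in the rows and reports absolute and relative discrepancies against
#' the parent's printed value.
#'
#' @param rows typed rows from [read_results_table()].
#' @param metric metric name (must be additive: populations, deaths,
#'   livebirths).
#' @param year the year to check.
#' @param parent parent location (default "Global").
#' @return list with `parent_value`, `child_sum`, `abs_discrepancy`,
#'   `rel_discrepancy`, `n_children`.
#' @export
aggregate_check <- function(rows, metric, year, parent = "Global") {
  sub <- rows[rows$metric == metric & rows$year == year, , drop = FALSE]
  pv <- sub$value[sub$location == parent]
  ch <- sub$value[!is.na(sub$parent) & sub$parent == parent]
  if (length(pv) != 1) stop("parent row missing for ", metric, call. = FALSE)
  if (!length(ch)) stop("no child rows under ", parent, call. = FALSE)
  cs <- sum(ch)
  list(parent_value = pv, child_sum = cs,
       abs_discrepancy = abs(cs - pv),
       rel_discrepancy = abs(cs - pv) / pv,
       n_children = length(ch))
}

#' Derived indicators from a results table
#'
#' @param rows typed rows from [read_results_table()].
#' @return a list of helper closures: `share(child, parent, metric, year)`
#'   (child / parent x 100, rounded to 1 decimal), `sex_gap(metric_female,
#'   metric_male, location, year)` (female minus male), and
#'   `threshold_count(values, threshold, rule)` with rule
#'   `"strictly_less"` or `"at_most"`.
#' @export
derived_indicators <- function(rows) {
  get1 <- function(loc, metric, year) {
    v <- rows$value[rows$location == loc & rows$metric == metric &
                      rows$year == year]
    if (length(v) != 1) stop("cell not found: ", loc, "/", metric, "/", year,
                             call. = FALSE)
    v
  }
  list(
    share = function(child, parent, metric, year) {
      p <- get1(parent, metric, year)
      if (p == 0) stop("division by zero", call. = FALSE)
      round(100 * get1(child, metric, year) / p, 1)
    },
    sex_gap = function(metric_female, metric_male, location, year) {
      get1(location, metric_female, year) - get1(location, metric_male, year)
    },
    threshold_count = function(values, threshold, rule = c("strictly_less", "at_most")) {
      rule <- match.arg(rule)
      if (rule == "strictly_less") sum(values < threshold) else sum(values <= threshold)
    },
    get = get1
  )
}

#' Path to a shipped transcription fixture
#'
#' @param name file name under the package's `extdata` (e.g.
#'   `"table1_superregions.csv"`).
#' @return absolute path.
#' @export
demrecon_extdata <- function(name) {
  p <- system.file("extdata", name, package = "demrecon")
  if (p == "") stop("no such fixture: ", name, call. = FALSE)
  p
}
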