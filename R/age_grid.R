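#' Age grids
#'
#' An `age_grid` is an ordered set of contiguous age intervals
#' `[start, start + width)` starting at exact age 0, whose last interval is
#' open-ended (`width = Inf`). Two named grids are provided:
#'
#' * `"gbd23"` -- the 23-group grid used throughout burden-of-disease
#'   demography: early neonatal (0-6 days), late neonatal (7-27 days),
#'   post-neonatal (28-364 days), 1-4 years, then 5-year groups up to 90-94,
#'   and 95+. Day-based widths are expressed in years with a 365-day year
#'   (7/365, 21/365, 337/365) so that person-year columns stay in years.
#' * `"single_year_0_110"` -- single-year ages 0, 1, ..., 109 plus 110+
#'   (111 intervals).
#'
#' @param spec a grid name (`"gbd23"`, `"single_year_0_110"`) or a
#'   two-column matrix / data.frame of `(start, width)` rows; the terminal
#'   width may be `Inf` or `NA` to mark the open interval (if the last given
#'   width is finite it is replaced by `Inf`).
#' @return an object of class `age_grid`: a data.frame with columns
#'   `age_start` and `age_width` (terminal width `Inf`).
#' @export
#' @examples
#' g <- build_age_grid("gbd23")
#' nrow(g)             # 23
#' g$age_start[23]     # 95
build_age_grid <- function(spec) {
  if (is.character(spec) && length(spec) == 1) {
    starts <- switch(spec,
      gbd23 = c(0, 7 / 365, 28 / 365, 1, seq(5, 95, by = 5)),
      single_year_0_110 = 0:110,
      stop("unknown grid name: ", spec, call. = FALSE)
    )
    widths <- c(diff(starts), Inf)
  } else {
    m <- as.matrix(as.data.frame(spec))
    if (ncol(m) != 2) stop("explicit grid needs (start, width) pairs", call. = FALSE)
    starts <- as.numeric(m[, 1])
    widths <- as.numeric(m[, 2])
    widths[length(widths)] <- Inf
    if (is.unsorted(starts, strictly = TRUE)) {
      stop("age intervals must be ordered by start", call. = FALSE)
    }
    if (starts[1] != 0) stop("age grid must start at exact age 0", call. = FALSE)
    up <- starts + widths
    if (any(abs(up[-length(up)] - starts[-1]) > 1e-9)) {
      stop("age intervals must be contiguous and non-overlapping", call. = FALSE)
    }
    if (any(widths[-length(widths)] <= 0)) stop("age widths must be > 0", call. = FALSE)
  }
  structure(
    data.frame(age_start = starts, age_width = widths),
    class = c("age_grid", "data.frame")
  )
}

#' @export
print.age_grid <- function(x, ...) {
  cat("<age_grid> ", nrow(x), " intervals, terminal open at ",
      x$age_start[nrow(x)], "+\n", sep = "")
  invisible(x)
}

is_age_grid <- function(x) inherits(x, "age_grid")

# exact-age upper boundaries of the closed intervals
grid_boundaries <- function(grid) {
  with(grid, age_start[-1])
}

stopifnot_grid <- function(grid) {
  if (!is_age_grid(grid)) grid <- build_age_grid(grid)
  grid
}
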