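#' Thermal optimum of a fitted response curve
#'
#' Temperature of the global maximum of a model family's curve on a
#' search interval, found by a dense grid scan followed by local
#' refinement with [stats::optimize()].
#'
#' @param key Registry key (see [rate_model()]).
#' @param pars Named numeric parameter vector for that family.
#' @param interval Search interval in degrees Celsius.
#' @param tol Temperature tolerance of the refinement (degrees Celsius).
#' @return The optimum temperature (degrees Celsius), or `NA` with a
#'   warning when the curve has no interior maximum on the interval
#'   (flat or monotone).
#' @examples
#' thermal_optimum("briere", c(a = 1e-4, m = 2, t_low = 8, t_max = 33))
#' @export
thermal_optimum <- function(key, pars, interval = c(-5, 50), tol = 0.01) {
  fam <- rate_model(key)
  grid <- seq(interval[1], interval[2], length.out = 4001)
  vals <- fam$fn(grid, pars)
  if (diff(range(vals)) < 1e-12 * max(1, max(abs(vals)))) {
    warning("curve is flat on the search interval; no optimum")
    return(NA_real_)
  }
  i <- which.max(vals)
  if (i == 1L || i == length(grid)) {
    warning("maximum sits on the interval boundary; no interior optimum")
    return(NA_real_)
  }
  opt <- stats::optimize(function(x) fam$fn(x, pars),
                         lower = grid[i - 1L], upper = grid[i + 1L],
                         maximum = TRUE, tol = tol / 10)
  opt$maximum
}

#' Thermal thresholds of a development-rate curve
#'
#' Lower and upper temperatures at which the rate curve crosses zero on
#' either side of its optimum ("development theoretically not possible"
#' beyond them). For the Briere family the thresholds are the `t_low`
#' and `t_max` parameters and are returned exactly; for Lactin-1 the
#' upper root is `t_max` analytically. Other families are solved
#' numerically with [stats::uniroot()] after a grid sign-change scan.
#'
#' @inheritParams thermal_optimum
#' @return Named numeric vector `c(lower =, upper =)`; a side with no
#'   sign change on the interval is `NA` (e.g. the Logan curve only
#'   decays towards zero at low temperature, it never crosses it).
#' @examples
#' thermal_thresholds("briere", c(a = 1e-4, m = 2, t_low = 8, t_max = 33))
#' @export
thermal_thresholds <- function(key, pars, interval = c(-5, 50), tol = 0.01) {
  fam <- rate_model(key)
  if (key == "briere")
    return(c(lower = unname(pars[["t_low"]]), upper = unname(pars[["t_max"]])))
  if (key == "lactin1") {
    lower <- .root_below(fam, pars, interval, tol,
                         opt = thermal_optimum(key, pars, interval, tol))
    return(c(lower = lower, upper = unname(pars[["t_max"]])))
  }
  opt <- suppressWarnings(thermal_optimum(key, pars, interval, tol))
  if (is.na(opt)) return(c(lower = NA_real_, upper = NA_real_))
  c(lower = .root_below(fam, pars, interval, tol, opt),
    upper = .root_above(fam, pars, interval, tol, opt))
}

# Locate the zero-crossing nearest the optimum within [lo, hi].
# pick = "last" takes the crossing closest to hi (lower-threshold search,
# hi = optimum); pick = "first" the one closest to lo (upper-threshold
# search, lo = optimum).
.scan_root <- function(fam, pars, lo, hi, tol, pick) {
  grid <- seq(lo, hi, length.out = 2001)
  vals <- fam$fn(grid, pars)
  sgn <- sign(vals)
  flip <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  if (!length(flip)) return(NA_real_)
  i <- if (pick == "last") flip[length(flip)] else flip[1]
  stats::uniroot(function(x) fam$fn(x, pars),
                 lower = grid[i], upper = grid[i + 1L],
                 tol = tol / 10)$root
}

.root_below <- function(fam, pars, interval, tol, opt) {
  if (is.na(opt) || opt <= interval[1]) return(NA_real_)
  .scan_root(fam, pars, interval[1], opt, tol, pick = "last")
}

.root_above <- function(fam, pars, interval, tol, opt) {
  if (is.na(opt) || opt >= interval[2]) return(NA_real_)
  .scan_root(fam, pars, opt, interval[2], tol, pick = "first")
}
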