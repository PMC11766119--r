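# Valid model-evaluation domain is wider than any rearing data so that
# threshold searches can bracket zero-crossings.
.TEMP_DOMAIN <- c(-10, 60)

.check_temp <- function(t) {
  if (!is.numeric(t) || anyNA(t) || any(!is.finite(t)))
    stop("temperature must be finite numeric (degrees Celsius)", call. = FALSE)
  invisible(t)
}

.check_finite <- function(...) {
  vals <- c(...)
  if (anyNA(vals) || any(!is.finite(vals)))
    stop("model parameters must be finite", call. = FALSE)
  invisible(vals)
}

#' Logan temperature-dependent development rate
#'
#' Exponential rise with a sharp decline approaching the upper thermal
#' threshold `t_max`:
#' \deqn{G(T) = \psi\,[\exp(\rho T) - \exp(\rho T_M - (T_M - T)/\Delta T)]}
#' The curve is exactly zero at `T = t_max` and has no finite lower
#' threshold (it decays to zero as temperature falls).
#'
#' @param t Temperature in degrees Celsius (vectorised).
#' @param psi Empirical scale parameter.
#' @param rho Empirical exponent (per degree Celsius).
#' @param t_max Upper thermal threshold (degrees Celsius) above which
#'   development is theoretically not possible.
#' @param delta_t Width (degrees Celsius) of the high-temperature decline;
#'   must be positive.
#' @return Development rate in day^-1. Raw model output: may be negative
#'   above `t_max`; consumers clip explicitly where needed.
#' @examples
#' logan_rate(28, psi = 0.08, rho = 0.093, t_max = 32.6, delta_t = 1.5)
#' @export
logan_rate <- function(t, psi, rho, t_max, delta_t) {
  .check_temp(t)
  .check_finite(psi, rho, t_max, delta_t)
  if (delta_t <= 0) stop("delta_t must be > 0", call. = FALSE)
  psi * (exp(rho * t) - exp(rho * t_max - (t_max - t) / delta_t))
}

#' Briere temperature-dependent development rate
#'
#' \deqn{G(T) = a\,T\,(T - T_L)\,(T_M - T)^{1/m}} inside the thermal window
#' `[t_low, t_max]`, and 0 outside it (development is biologically absent
#' beyond the thresholds; this also avoids complex roots of the exponent).
#'
#' @inheritParams logan_rate
#' @param a Empirical scale parameter.
#' @param m Shape exponent of the high-temperature branch; must be nonzero.
#' @param t_low,t_max Lower and upper thermal thresholds (degrees Celsius),
#'   `t_low < t_max`.
#' @return Development rate in day^-1 (zero outside the thresholds).
#' @examples
#' briere_rate(20, a = 1e-4, m = 2, t_low = 8, t_max = 33)
#' @export
briere_rate <- function(t, a, m, t_low, t_max) {
  .check_temp(t)
  .check_finite(a, m, t_low, t_max)
  if (t_low >= t_max) stop("t_low must be < t_max", call. = FALSE)
  if (m == 0) stop("m must be nonzero", call. = FALSE)
  out <- numeric(length(t))
  inside <- t >= t_low & t <= t_max
  ti <- t[inside]
  out[inside] <- a * ti * (ti - t_low) * (t_max - ti)^(1 / m)
  out
}

#' Sharpe-De Michele enzyme-kinetic development rate
#'
#' The only non-empirical member of the catalogue, derived from enzyme
#' kinetics with low- and high-temperature inactivation terms:
#' \deqn{G(T) = \frac{T \exp(A - B/T)}{1 + \exp(C - D/T) + \exp(E - F/T)}}
#' The default evaluates with `T` in degrees Celsius, the form under which
#' the published D. suzukii egg coefficients reproduce the observed egg
#' rate (about 1.3 day^-1 at 26 C); `kelvin = TRUE` evaluates the
#' original-literature absolute-temperature form instead.
#'
#' The six coefficients are strongly correlated; standard errors of fits
#' are frequently unreliable (see [fit_model()], which flags them).
#'
#' @inheritParams logan_rate
#' @param a_,b_,c_,d_,e_,f_ Enzyme-kinetic coefficients.
#' @param kelvin If `TRUE`, convert `t` to Kelvin before evaluating.
#' @return Development rate in day^-1.
#' @examples
#' sharpe_demichele_rate(26, 4.78, -113.99, 20.44, 272.13, 6.76, -137.53)
#' @export
sharpe_demichele_rate <- function(t, a_, b_, c_, d_, e_, f_, kelvin = FALSE) {
  .check_temp(t)
  .check_finite(a_, b_, c_, d_, e_, f_)
  tt <- if (kelvin) t + 273.15 else t
  if (any(tt == 0))
    stop("temperature gives a zero denominator (singular at T = 0)",
         call. = FALSE)
  tt * exp(a_ - b_ / tt) / (1 + exp(c_ - d_ / tt) + exp(e_ - f_ / tt))
}

#' Lactin temperature-dependent development rate
#'
#' \deqn{G(T) = \exp(a T) - \exp(a T_M - (T_M - T)/\Delta T) + \lambda}
#' With `lam = 0` this is the Lactin-1 function, which vanishes exactly at
#' `t_max`; the additive offset `lam` gives the Lactin-2 variant,
#' for which `G(t_max) = lam`.
#'
#' @inheritParams logan_rate
#' @param a Empirical exponent (per degree Celsius).
#' @param lam Additive offset (Lactin-2); 0 for Lactin-1.
#' @return Development rate in day^-1 (raw, unclipped).
#' @examples
#' lactin_rate(27, a = 0.14, t_max = 33.9, delta_t = 6.9, lam = -0.3)
#' @export
lactin_rate <- function(t, a, t_max, delta_t, lam = 0) {
  .check_temp(t)
  .check_finite(a, t_max, delta_t, lam)
  if (delta_t <= 0) stop("delta_t must be > 0", call. = FALSE)
  exp(a * t) - exp(a * t_max - (t_max - t) / delta_t) + lam
}

#' Quartic "bathtub" temperature-dependent mortality
#'
#' Fourth-order polynomial describing the U-shaped mortality-temperature
#' profile, \eqn{M(T) = a_m T^4 + b_m T^3 + c_m T^2 + d_m T + e_m}.
#' The coefficients have no direct biological meaning. Output is raw and
#' unclipped: the polynomial can go negative between its minima, and such
#' values are a real diagnostic (they motivated discarding this family for
#' one larval stage in the source dataset), so consumers clip to [0, 1]
#' explicitly where a proportion is required.
#'
#' @inheritParams logan_rate
#' @param am,bm,cm,dm,em Polynomial coefficients (quartic to constant).
#' @return Mortality rate (dimensionless proportion scale), unclipped.
#' @export
bathtub_mortality <- function(t, am, bm, cm, dm, em) {
  .check_temp(t)
  .check_finite(am, bm, cm, dm, em)
  am * t^4 + bm * t^3 + cm * t^2 + dm * t + em
}

#' Kim-Lee temperature-dependent mortality
#'
#' \deqn{M(T) = 1 - k \exp\!\big(1 + x - e^{x}\big), \quad
#'   x = (T_{opt} - T)/\rho_T}
#' where `t_opt_survival` is the temperature of minimal mortality and
#' `M(t_opt_survival) = 1 - k`. The double exponential saturates mortality
#' to 1 away from the optimum; IEEE overflow of the inner exponential
#' propagates to exactly that limit.
#'
#' @inheritParams logan_rate
#' @param k Survival scale at the optimum (0 < k <= 1 expected).
#' @param rho_t Thermal width (degrees Celsius); must be nonzero.
#' @param t_opt_survival Temperature of minimal mortality (degrees Celsius).
#' @return Mortality proportion (raw; in [1 - k, 1] for valid k).
#' @export
kimlee_mortality <- function(t, k, rho_t, t_opt_survival) {
  .check_temp(t)
  .check_finite(k, rho_t, t_opt_survival)
  if (rho_t == 0) stop("rho_t must be nonzero", call. = FALSE)
  x <- (t_opt_survival - t) / rho_t
  inner <- exp(x)                     # may overflow to Inf
  out <- 1 - k * exp(1 + x - inner)   # exp(-Inf) = 0 -> mortality 1
  out[is.nan(out)] <- 1
  out
}

#' Gaussian-like temperature-dependent fertility
#'
#' Lifetime egg production per female as a function of rearing
#' temperature:
#' \deqn{\beta(T) = \alpha\,\frac{\gamma + 1}{\pi\,\lambda^{2\gamma+2}}
#'   \left(\lambda^2 - (T - \tau)^2 + \delta^2\right)^{\gamma}}
#' `tau` is the optimal temperature for egg production (the curve maximum
#' sits at `T = tau` for `gamma_ > 0`). Where the base
#' \eqn{\lambda^2 - (T-\tau)^2 + \delta^2} is negative the power is not
#' real for non-integer `gamma_`; fertility is defined as 0 there
#' (outside the reproductive thermal window). Evaluation is carried out
#' in log space so that large `gamma_`/`lam` combinations do not overflow.
#'
#' @inheritParams logan_rate
#' @param alpha Scale (total-egg units).
#' @param gamma_ Shape exponent.
#' @param lam Width parameter; must be nonzero.
#' @param tau Optimal temperature for egg production (degrees Celsius).
#' @param delta Secondary shape parameter (degrees Celsius).
#' @return Eggs per female (vectorised over `t`).
#' @examples
#' fertility_curve(24, alpha = pi, gamma_ = 1, lam = 1, tau = 24, delta = 0)
#' @export
fertility_curve <- function(t, alpha, gamma_, lam, tau, delta) {
  .check_temp(t)
  .check_finite(alpha, gamma_, lam, tau, delta)
  if (lam == 0) stop("lam must be nonzero", call. = FALSE)
  base <- lam^2 - (t - tau)^2 + delta^2
  out <- numeric(length(t))
  pos <- base > 0
  if (any(pos)) {
    lognorm <- log(alpha) + log(gamma_ + 1) - log(pi) -
      (2 * gamma_ + 2) * log(abs(lam))
    out[pos] <- exp(lognorm + gamma_ * log(base[pos]))
  }
  out
}
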