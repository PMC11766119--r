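#' Model registry
#'
#' Addressable catalogue of every temperature-response family in the
#' package. Each entry carries the parameter names, a vectorised
#' evaluator taking a named parameter vector, the response kind the
#' family is meant for, and data-driven default box bounds used by the
#' multi-start fitter.
#'
#' @param key One of `"logan"`, `"briere"`, `"sharpe_demichele"`,
#'   `"lactin1"`, `"lactin2"`, `"bathtub"`, `"kimlee"`,
#'   `"fertility_gaussianlike"`; or `NULL` to list all keys.
#' @return For a single `key`, a list with elements `key`, `label`,
#'   `par_names`, `fn(t, pars)`, `kind`, and `bounds(temperature,
#'   response)` returning `list(lower, upper)` named vectors. With
#'   `key = NULL`, the character vector of registry keys.
#' @examples
#' rate_model("logan")$par_names
#' rate_model()
#' @export
rate_model <- function(key = NULL) {
  if (is.null(key)) return(names(.MODEL_REGISTRY))
  if (!key %in% names(.MODEL_REGISTRY))
    stop("unknown model key: ", key, " (see rate_model())", call. = FALSE)
  .MODEL_REGISTRY[[key]]
}

#' Keys of the development-rate families
#' @return Character vector of registry keys usable for development and
#'   longevity fitting.
#' @export
development_model_keys <- function() {
  c("logan", "briere", "sharpe_demichele", "lactin1", "lactin2")
}

#' Keys of the mortality families
#' @return Character vector of registry keys for mortality fitting.
#' @export
mortality_model_keys <- function() {
  c("bathtub", "kimlee")
}

# Bounds heuristics. Thresholds are anchored to the span of the observed
# temperatures; scale parameters to the span of the responses. These are
# repository defaults (the source study does not state its bounds) and
# every one of them can be overridden through fit_model(bounds = ...).
.scale_hi <- function(response) max(10 * max(abs(response)), 1)

.MODEL_REGISTRY <- list(
  logan = list(
    key = "logan", label = "Logan",
    par_names = c("psi", "rho", "t_max", "delta_t"),
    kind = "development_rate",
    fn = function(t, p) logan_rate(t, p[["psi"]], p[["rho"]],
                                   p[["t_max"]], p[["delta_t"]]),
    bounds = function(temperature, response) list(
      lower = c(psi = 1e-6, rho = 0.005, t_max = max(temperature) - 2,
                delta_t = 0.1),
      upper = c(psi = .scale_hi(response), rho = 0.5, t_max = 60,
                delta_t = 20))
  ),
  briere = list(
    key = "briere", label = "Briere",
    par_names = c("a", "m", "t_low", "t_max"),
    kind = "development_rate",
    fn = function(t, p) briere_rate(t, p[["a"]], p[["m"]],
                                    p[["t_low"]], p[["t_max"]]),
    bounds = function(temperature, response) list(
      lower = c(a = 1e-8, m = 0.5, t_low = -10, t_max = max(temperature) - 2),
      upper = c(a = 0.1, m = 10, t_low = min(temperature) + 2, t_max = 60))
  ),
  sharpe_demichele = list(
    key = "sharpe_demichele", label = "Sharpe-De Michele",
    par_names = c("a_", "b_", "c_", "d_", "e_", "f_"),
    kind = "development_rate",
    fn = function(t, p) sharpe_demichele_rate(t, p[["a_"]], p[["b_"]],
                                              p[["c_"]], p[["d_"]],
                                              p[["e_"]], p[["f_"]]),
    bounds = function(temperature, response) list(
      lower = c(a_ = -10, b_ = -500, c_ = -50, d_ = -1000,
                e_ = -50, f_ = -500),
      upper = c(a_ = 20, b_ = 500, c_ = 50, d_ = 1000,
                e_ = 50, f_ = 500))
  ),
  lactin1 = list(
    key = "lactin1", label = "Lactin-1",
    par_names = c("a", "t_max", "delta_t"),
    kind = "development_rate",
    fn = function(t, p) lactin_rate(t, p[["a"]], p[["t_max"]],
                                    p[["delta_t"]], lam = 0),
    bounds = function(temperature, response) list(
      lower = c(a = 0.005, t_max = max(temperature) - 2, delta_t = 0.1),
      upper = c(a = 0.5, t_max = 60, delta_t = 20))
  ),
  lactin2 = list(
    key = "lactin2", label = "Lactin-2",
    par_names = c("a", "t_max", "delta_t", "lam"),
    kind = "development_rate",
    fn = function(t, p) lactin_rate(t, p[["a"]], p[["t_max"]],
                                    p[["delta_t"]], p[["lam"]]),
    bounds = function(temperature, response) list(
      lower = c(a = 0.005, t_max = max(temperature) - 2, delta_t = 0.1,
                lam = -2),
      upper = c(a = 0.5, t_max = 60, delta_t = 20, lam = 2))
  ),
  bathtub = list(
    key = "bathtub", label = "bathtub (quartic)",
    par_names = c("am", "bm", "cm", "dm", "em"),
    kind = "mortality_proportion",
    fn = function(t, p) bathtub_mortality(t, p[["am"]], p[["bm"]],
                                          p[["cm"]], p[["dm"]], p[["em"]]),
    bounds = function(temperature, response) list(
      lower = c(am = -1e-2, bm = -1, cm = -10, dm = -100, em = -1000),
      upper = c(am = 1e-2, bm = 1, cm = 10, dm = 100, em = 1000))
  ),
  kimlee = list(
    key = "kimlee", label = "Kim-Lee",
    par_names = c("k", "rho_t", "t_opt_survival"),
    kind = "mortality_proportion",
    fn = function(t, p) kimlee_mortality(t, p[["k"]], p[["rho_t"]],
                                         p[["t_opt_survival"]]),
    bounds = function(temperature, response) list(
      lower = c(k = 1e-4, rho_t = 0.5, t_opt_survival = 0),
      upper = c(k = 1, rho_t = 30, t_opt_survival = 40))
  ),
  fertility_gaussianlike = list(
    key = "fertility_gaussianlike", label = "Gaussian-like fertility",
    par_names = c("alpha", "gamma_", "lam", "tau", "delta"),
    kind = "total_eggs",
    fn = function(t, p) fertility_curve(t, p[["alpha"]], p[["gamma_"]],
                                        p[["lam"]], p[["tau"]], p[["delta"]]),
    bounds = function(temperature, response) list(
      lower = c(alpha = 1, gamma_ = 0.5, lam = 0.5, tau = 10, delta = 0),
      upper = c(alpha = 1e7, gamma_ = 60, lam = 60, tau = 35, delta = 40))
  )
)

#' Serialize / deserialize a parameter set
#'
#' Parameter sets are plain named numeric vectors; these helpers move
#' them to and from the flat key-value (JSON-compatible) representation
#' used in config files and report headers.
#'
#' @param pars Named numeric vector.
#' @param key Registry key the set belongs to.
#' @return `params_to_list()`: a named list of scalars with a `model`
#'   element; `params_from_list()`: the named numeric vector, checked
#'   against the family's parameter names.
#' @export
params_to_list <- function(pars, key) {
  c(list(model = key), as.list(pars))
}

#' @rdname params_to_list
#' @param x Flat named list as produced by `params_to_list()`.
#' @export
params_from_list <- function(x) {
  key <- x$model
  fam <- rate_model(key)
  pars <- unlist(x[fam$par_names])
  if (length(pars) != length(fam$par_names) || anyNA(pars))
    stop("parameter list incomplete for model ", key, call. = FALSE)
  pars
}
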