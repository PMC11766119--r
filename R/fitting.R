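#' Fit a temperature-response model by multi-start nonlinear least squares
#'
#' Minimizes the ordinary (unweighted) sum of squared residuals of a
#' registry family against a [rate_dataset()]. Because every family is
#' nonconvex with threshold-type parameters, the optimisation is
#' restarted from `n_starts` Latin-hypercube points spread over the
#' family's box bounds (log-spaced along dimensions whose bounds span
#' more than three decades), each polished with the
#' Levenberg-Marquardt algorithm ([minpack.lm::nls.lm()]) under the same
#' bounds; the best converged start wins. The start layout is drawn
#' under `seed`, so a fit is bit-reproducible.
#'
#' Standard errors come from the residual-variance-scaled inverse
#' Gauss-Newton curvature at the optimum, `sigma^2 (J'J)^{-1}`. When the
#' curvature matrix is numerically singular — endemic to the strongly
#' correlated Sharpe-De Michele coefficients — the SEs are reported
#' missing rather than as meaningless numbers.
#'
#' @param ds A [rate_dataset()].
#' @param model_key Registry key (see [rate_model()]).
#' @param n_starts Number of Latin-hypercube starts.
#' @param seed Integer seed for the start layout.
#' @param bounds Optional `list(lower =, upper =)` named vectors
#'   overriding the family defaults.
#' @param max_iter Maximum Levenberg-Marquardt iterations per start.
#' @return A `fit_result`: list with `model_key`, `estimates` (named
#'   vector), `std_errors` (named vector, possibly all `NA`),
#'   `r_squared`, `rmse`, `chi_squared`, `chi_squared_excluded`, `ndf`,
#'   `converged`, `n_starts_used`, `fitted`, `data`, `seed`.
#' @examples
#' ds <- rate_dataset(seq(10, 32, 2),
#'                    logan_rate(seq(10, 32, 2), 0.08, 0.093, 32.6, 1.5))
#' fit <- fit_model(ds, "logan", n_starts = 16)
#' fit$estimates
#' @export
fit_model <- function(ds, model_key, n_starts = 64, seed = 1,
                      bounds = NULL, max_iter = 200) {
  stopifnot(inherits(ds, "rate_dataset"))
  fam <- rate_model(model_key)
  p <- length(fam$par_names)
  n <- nrow(ds)
  if (n <= p)
    stop("refusing to fit: ", n, " points for ", p,
         " parameters leaves no degrees of freedom", call. = FALSE)
  if (is.null(bounds)) bounds <- fam$bounds(ds$temperature, ds$response)
  lower <- bounds$lower[fam$par_names]
  upper <- bounds$upper[fam$par_names]
  if (anyNA(lower) || anyNA(upper) || any(lower >= upper))
    stop("invalid bounds for model ", model_key, call. = FALSE)

  resid_fn <- function(par) {
    names(par) <- fam$par_names
    r <- ds$response - fam$fn(ds$temperature, par)
    r[!is.finite(r)] <- 1e6  # keep LM away from overflow regions
    r
  }

  starts <- .lhs_starts(lower, upper, n_starts, seed)
  best <- NULL
  best_ss <- Inf
  used <- 0L
  for (i in seq_len(nrow(starts))) {
    f <- tryCatch(
      minpack.lm::nls.lm(par = starts[i, ], lower = lower, upper = upper,
                         fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = max_iter, ftol = 1e-15, ptol = 1e-15)),
      error = function(e) NULL)
    if (is.null(f) || !is.finite(f$deviance)) next
    used <- used + 1L
    if (f$deviance < best_ss) {
      best_ss <- f$deviance
      best <- f
    }
  }
  if (is.null(best)) {
    return(structure(list(model_key = model_key, estimates = NULL,
                          std_errors = NULL, r_squared = NA_real_,
                          rmse = NA_real_, chi_squared = NA_real_,
                          chi_squared_excluded = NA_integer_,
                          ndf = n - p, converged = FALSE,
                          n_starts_used = used, fitted = NULL, data = ds,
                          seed = seed),
                     class = "fit_result"))
  }

  est <- stats::setNames(as.numeric(best$par), fam$par_names)
  pred <- fam$fn(ds$temperature, est)
  gof <- goodness_of_fit(ds$response, pred, p)
  se <- .curvature_se(best, n, p)
  structure(list(model_key = model_key,
                 estimates = est,
                 std_errors = stats::setNames(se, fam$par_names),
                 r_squared = gof$r_squared, rmse = gof$rmse,
                 chi_squared = gof$chi_squared,
                 chi_squared_excluded = gof$n_excluded,
                 ndf = gof$ndf, converged = TRUE, n_starts_used = used,
                 fitted = pred, data = ds, seed = seed),
            class = "fit_result")
}

# Latin-hypercube start layout inside the box; dimensions whose positive
# bounds span > 3 decades are sampled on the log scale.
.lhs_starts <- function(lower, upper, n_starts, seed) {
  p <- length(lower)
  set.seed(seed)
  h <- lhs::randomLHS(n_starts, p)
  starts <- matrix(NA_real_, n_starts, p)
  for (j in seq_len(p)) {
    lo <- lower[j]; hi <- upper[j]
    logscale <- lo > 0 && hi / lo > 1e3
    starts[, j] <- if (logscale)
      exp(log(lo) + h[, j] * (log(hi) - log(lo)))
    else lo + h[, j] * (hi - lo)
  }
  colnames(starts) <- names(lower)
  starts
}

.curvature_se <- function(fit, n, p) {
  h <- fit$hessian  # J'J at the optimum (Gauss-Newton curvature)
  if (is.null(h) || anyNA(h) || any(diag(h) <= 0)) return(rep(NA_real_, p))
  # condition is judged on the diagonally normalized matrix so that
  # parameter-scale disparity is not mistaken for collinearity
  d <- sqrt(diag(h))
  hn <- h / tcrossprod(d)
  if (!is.finite(rcond(hn)) || rcond(hn) < 1e-10) return(rep(NA_real_, p))
  sigma2 <- fit$deviance / (n - p)
  cv <- tryCatch(sigma2 * solve(h), error = function(e) NULL)
  if (is.null(cv)) return(rep(NA_real_, p))
  dg <- diag(cv)
  ifelse(dg >= 0, sqrt(dg), NA_real_)
}

#' Goodness-of-fit battery
#'
#' The metrics used to compare the response families: coefficient of
#' determination `R^2 = 1 - SSres/SStot` (missing when the observations
#' are constant, and deliberately not clamped — a fit worse than the
#' mean goes negative); `RMSE = sqrt(SSres/n)`; a Pearson-type
#' `chi^2 = sum (obs - pred)^2 / |pred|` over points whose predicted
#' magnitude exceeds `eps` (the excluded count is reported alongside);
#' and the degrees of freedom `n - p`.
#'
#' @param observed,predicted Numeric vectors of equal length.
#' @param n_par Number of fitted parameters.
#' @param eps Predicted-magnitude floor below which a point is excluded
#'   from the chi-squared sum.
#' @return List `r_squared`, `rmse`, `chi_squared`, `ndf`, `n_excluded`.
#' @export
goodness_of_fit <- function(observed, predicted, n_par, eps = 1e-9) {
  stopifnot(length(observed) == length(predicted))
  n <- length(observed)
  ss_res <- sum((observed - predicted)^2)
  ss_tot <- sum((observed - mean(observed))^2)
  keep <- abs(predicted) > eps
  list(r_squared = if (ss_tot > 0) 1 - ss_res / ss_tot else NA_real_,
       rmse = sqrt(ss_res / n),
       chi_squared = sum((observed[keep] - predicted[keep])^2 /
                           abs(predicted[keep])),
       ndf = n - n_par,
       n_excluded = sum(!keep))
}

#' Rank fits of competing families on the same dataset
#'
#' Orders fit results by RMSE ascending, breaking ties by R-squared
#' descending; all metrics are carried so users can re-rank by another
#' criterion. Results must come from the same dataset (same
#' temperatures and responses) or the comparison refuses.
#'
#' @param results List of `fit_result` objects from [fit_model()].
#' @return A `model_comparison` data frame: `rank`, `model_key`,
#'   `r_squared`, `rmse`, `chi_squared`, `ndf`, `converged`.
#' @export
compare_models <- function(results) {
  if (length(results) < 2)
    stop("need at least two fit results to compare", call. = FALSE)
  ref <- results[[1]]$data
  same <- vapply(results, function(r)
    isTRUE(all.equal(r$data$temperature, ref$temperature)) &&
      isTRUE(all.equal(r$data$response, ref$response)), logical(1))
  if (!all(same))
    stop("fit results come from different datasets; refusing to rank",
         call. = FALSE)
  tab <- do.call(rbind, lapply(results, function(r)
    data.frame(model_key = r$model_key, r_squared = r$r_squared,
               rmse = r$rmse, chi_squared = r$chi_squared, ndf = r$ndf,
               converged = r$converged)))
  ord <- order(tab$rmse, -tab$r_squared, na.last = TRUE)
  tab <- tab[ord, , drop = FALSE]
  tab <- cbind(rank = seq_len(nrow(tab)), tab)
  rownames(tab) <- NULL
  class(tab) <- c("model_comparison", "data.frame")
  tab
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", rate_model(x$model_key)$label, "on",
      attr(x$data, "response_kind"), "data",
      sprintf("(stage %s, n = %d)\n", attr(x$data, "stage"), nrow(x$data)))
  if (!x$converged) {
    cat("  no start converged (", x$n_starts_used, "starts attempted )\n")
    return(invisible(x))
  }
  est <- format(signif(x$estimates, 4))
  se <- ifelse(is.na(x$std_errors), "--", format(signif(x$std_errors, 2)))
  cat(paste0("  ", names(x$estimates), " = ", est, " +/- ", se,
             collapse = "\n"), "\n")
  cat(sprintf("  R2 = %s  RMSE = %.4g  chi2 = %.4g  NDF = %d\n",
              ifelse(is.na(x$r_squared), "--",
                     sprintf("%.3f", x$r_squared)),
              x$rmse, x$chi_squared, x$ndf))
  invisible(x)
}

#' Predict from a fit result
#' @param object A `fit_result`.
#' @param newdata Optional numeric vector of temperatures; defaults to
#'   the fitted temperatures.
#' @param ... Unused.
#' @return Predicted responses.
#' @export
predict.fit_result <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("fit did not converge", call. = FALSE)
  t <- if (is.null(newdata)) object$data$temperature else newdata
  rate_model(object$model_key)$fn(t, object$estimates)
}
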