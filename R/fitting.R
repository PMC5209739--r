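# Multistart ordinary least-squares fitting of registry models to a
# treatment, via Levenberg-Marquardt (minpack.lm) with box bounds.

#' Fitting configuration
#'
#' @param maxiter Maximum Levenberg-Marquardt iterations per start.
#' @param ic_param_count Convention for the parameter count K used in AICc /
#'   BIC: `"plus_sigma"` (default) counts the residual variance, K = p + 1;
#'   `"regression_only"` uses K = p.
#' @param penalty Residual value substituted for non-finite or
#'   constraint-violating model evaluations during optimisation.
#' @return A list of class `tpc_config`.
#' @export
fit_config <- function(maxiter = 200L,
                       ic_param_count = c("plus_sigma", "regression_only"),
                       penalty = 1e4) {
  structure(list(maxiter = as.integer(maxiter),
                 ic_param_count = match.arg(ic_param_count),
                 penalty = penalty),
            class = "tpc_config")
}

# Box bounds for the optimiser.  P_max in (0, 10 x max rate]; t_opt within
# the observed range +- 5 degC; finite t_max allowed up to 60 degC beyond the
# warmest observation; shape parameters per registry.  Joint constraints
# (t_opt < t_max etc.) are enforced by penalisation, not the box.
.fit_bounds <- function(m, tr) {
  d <- tr$data
  lo <- c(p_max = 1e-8, t_opt = min(d$temperature) - 5)
  hi <- c(p_max = 10 * max(d$rate), t_opt = max(d$temperature) + 5)
  if ("t_max" %in% m$param_names) {
    lo["t_max"] <- min(d$temperature)
    hi["t_max"] <- max(d$temperature) + 60
  }
  if ("t_min" %in% m$param_names) {
    lo["t_min"] <- -80
    hi["t_min"] <- max(d$temperature)
  }
  lo <- c(lo, m$shape_lower)
  hi <- c(hi, m$shape_upper)
  list(lower = lo[m$param_names], upper = hi[m$param_names])
}

#' Deterministic multistart initial values
#'
#' Builds the grid of starting parameter vectors used by [fit_tpc()]:
#' `p_max` at the maximum observed rate and 1.2 x that; `t_opt` at the
#' temperature of the maximum observed rate and +-3 deg C; for models with a
#' finite `t_max` parameter, `t_max` at 1, 5 and 15 deg C above the warmest
#' observation (clamped below the model's validity limit where one exists);
#' shape parameters at their registry defaults.  Starts violating a model's
#' parameter constraints are dropped.
#'
#' @param treatment A [treatment()] object.
#' @param model Model name or descriptor.
#' @return A list of named numeric starting vectors (all valid, all with
#'   `t_opt < t_max` where applicable).
#' @export
multistart_initials <- function(treatment, model) {
  m <- tpc_model(model)
  tr <- .as_treatment(treatment)
  d <- tr$data
  rmax <- max(d$rate)
  if (rmax <= 0) rmax <- 1
  t_at_max <- d$temperature[which.max(d$rate)]
  p0 <- c(rmax, 1.2 * rmax)
  to0 <- t_at_max + c(0, -3, 3)
  tm0 <- if ("t_max" %in% m$param_names) max(d$temperature) + c(1, 5, 15) else NA
  starts <- list()
  for (pv in p0) for (tov in to0) for (tmv in tm0) {
    th <- c(p_max = pv, t_opt = max(tov, 0.5))
    if (!is.na(tmv)) {
      # keep Briere-style reparameterisations inside their validity region
      cap <- Inf
      if (m$name == "Briere1") cap <- 1.5 * th[["t_opt"]] - 0.2
      if (m$name == "Briere2") cap <- (1 + 1 / m$shape_start[["m"]]) * th[["t_opt"]] - 0.2
      th["t_max"] <- min(tmv, cap)
    }
    if ("t_min" %in% m$param_names)
      th["t_min"] <- min(d$temperature) - 10
    th <- c(th, m$shape_start)
    th <- th[m$param_names]
    if (.params_ok(m, as.list(th))) starts[[length(starts) + 1L]] <- th
  }
  unique(starts)
}

# Residual function factory; invalid or non-finite evaluations are penalised
# rather than raised so the multistart stays robust.
.residual_fun <- function(m, d, penalty) {
  force(m); force(d); force(penalty)
  function(par) {
    th <- as.list(par)
    names(th) <- m$param_names
    if (!.params_ok(m, th)) return(rep(penalty, nrow(d)))
    pred <- m$fun(d$temperature, th)
    r <- d$rate - pred
    r[!is.finite(r)] <- penalty
    r
  }
}

#' Fit one model to one treatment
#'
#' Minimises the sum of squared residuals between observed gross
#' photosynthesis rates and the model curve, over all replicate-level
#' observations (no weighting), using Levenberg-Marquardt from every start
#' in [multistart_initials()].  The best converged run is returned.
#' Degenerate data (fewer than 4 distinct temperatures, constant rates, or
#' too few observations) yields a flagged non-converged result rather than
#' an error.
#'
#' @param treatment A [treatment()] object (or data.frame with
#'   `temperature` and `rate` columns).
#' @param model Model name or descriptor.
#' @param config A [fit_config()].
#' @return A `tpc_fit` object: model name, `estimates`, `se` (per-parameter
#'   standard errors from the Jacobian at the optimum), `sse`, `n`, `p`,
#'   `converged`, `cardinals` (see [critical_temperatures()]),
#'   `predictions` at the observed temperatures, and fitting diagnostics.
#' @examples
#' tr <- simulate_treatment(simulation_config(seed = 1))
#' fit <- fit_tpc(tr, "YanHunt")
#' fit$estimates
#' @export
fit_tpc <- function(treatment, model, config = fit_config()) {
  m <- tpc_model(model)
  tr <- .as_treatment(treatment)
  d <- tr$data
  diag_msg <- .treatment_diagnostic(tr, m$p)
  if (!is.null(diag_msg)) {
    return(.tpc_fit(m, tr, estimates = NULL, se = NULL, sse = NA_real_,
                    converged = FALSE, diagnostics = list(reason = diag_msg,
                                                          starts_tried = 0L)))
  }
  starts <- multistart_initials(tr, m)
  bounds <- .fit_bounds(m, tr)
  rf <- .residual_fun(m, d, config$penalty)
  best <- NULL
  n_ok <- 0L
  for (st in starts) {
    res <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = bounds$lower, upper = bounds$upper,
                         fn = rf,
                         control = minpack.lm::nls.lm.control(
                           maxiter = config$maxiter)),
      error = function(e) NULL)
    if (is.null(res)) next
    est <- res$par
    names(est) <- m$param_names
    if (!.params_ok(m, as.list(est))) next
    sse <- res$deviance
    conv <- res$info %in% 1:3
    if (conv) n_ok <- n_ok + 1L
    if (is.null(best) || sse < best$sse - 1e-12 ||
        (conv && !best$conv && sse < best$sse + 1e-12)) {
      best <- list(est = est, sse = sse, conv = conv, info = res$info)
    }
  }
  if (is.null(best)) {
    return(.tpc_fit(m, tr, estimates = NULL, se = NULL, sse = NA_real_,
                    converged = FALSE,
                    diagnostics = list(reason = "no start converged",
                                       starts_tried = length(starts))))
  }
  fit <- .tpc_fit(m, tr, estimates = best$est, se = NULL, sse = best$sse,
                  converged = best$conv,
                  diagnostics = list(starts_tried = length(starts),
                                     starts_converged = n_ok,
                                     lm_info = best$info))
  fit$se <- parameter_se(fit, tr)
  fit
}

.tpc_fit <- function(m, tr, estimates, se, sse, converged, diagnostics) {
  preds <- if (!is.null(estimates)) m$fun(tr$data$temperature, as.list(estimates))
           else rep(NA_real_, nrow(tr$data))
  cards <- if (!is.null(estimates)) critical_temperatures(m, estimates) else NULL
  structure(list(
    model = m$name, treatment = tr$label,
    estimates = estimates, se = se, sse = sse,
    n = nrow(tr$data), p = m$p, converged = converged,
    cardinals = cards, predictions = preds, observed = tr$data$rate,
    diagnostics = diagnostics
  ), class = "tpc_fit")
}

#' @export
print.tpc_fit <- function(x, ...) {
  cat(sprintf("<tpc_fit> %s on %s: ", x$model, x$treatment))
  if (is.null(x$estimates)) {
    cat("not fitted (", x$diagnostics$reason, ")\n", sep = "")
    return(invisible(x))
  }
  cat(sprintf("sse = %.4g, converged = %s\n", x$sse, x$converged))
  est <- x$estimates
  se <- x$se
  for (i in seq_along(est)) {
    cat(sprintf("  %-10s %8.4g", names(est)[i], est[i]))
    if (!is.null(se) && is.finite(se[i])) cat(sprintf(" +- %.3g", se[i]))
    cat("\n")
  }
  invisible(x)
}

#' Predict from a fitted curve
#'
#' @param object A `tpc_fit`.
#' @param temp Temperatures (deg C); defaults to the fitted data's.
#' @param ... Unused.
#' @export
predict.tpc_fit <- function(object, temp = NULL, ...) {
  if (is.null(object$estimates)) stop("fit did not converge; no curve available")
  if (is.null(temp)) return(object$predictions)
  tpc_evaluate(object$model, object$estimates, temp)
}

#' Per-parameter standard errors
#'
#' Computes standard errors from the curvature of the least-squares surface
#' at the optimum: `SE = sqrt(diag(sigma2 * (J'J)^-1))`, with
#' `sigma2 = sse / (n - p)` and `J` the (finite-difference) Jacobian of the
#' model predictions with respect to the parameters.  When `J'J` is singular
#' the SEs are returned as `NA` and flagged.
#'
#' @param fit A converged `tpc_fit`.
#' @param treatment The treatment the model was fitted to.
#' @return Named numeric vector of standard errors (with attribute
#'   `singular = TRUE` when the information matrix could not be inverted).
#' @export
parameter_se <- function(fit, treatment) {
  tr <- .as_treatment(treatment)
  m <- tpc_model(fit$model)
  if (is.null(fit$estimates)) stop("fit did not converge; no standard errors")
  est <- fit$estimates
  f <- function(par) {
    th <- as.list(par)
    names(th) <- m$param_names
    m$fun(tr$data$temperature, th)
  }
  J <- pracma::jacobian(f, unname(est))
  n <- nrow(tr$data)
  sigma2 <- fit$sse / (n - m$p)
  jtj <- crossprod(J)
  vc <- tryCatch(solve(jtj) * sigma2, error = function(e) NULL)
  if (is.null(vc) || any(!is.finite(diag(vc)))) {
    out <- setNames(rep(NA_real_, m$p), m$param_names)
    attr(out, "singular") <- TRUE
    return(out)
  }
  setNames(sqrt(pmax(diag(vc), 0)), m$param_names)
}

#' Fit every registry model to a treatment
#'
#' @param treatment A [treatment()].
#' @param models Character vector of model names (default: all twelve).
#' @param config A [fit_config()].
#' @return Named list of `tpc_fit` objects.
#' @export
fit_all_models <- function(treatment, models = names(tpc_registry()),
                           config = fit_config()) {
  tr <- .as_treatment(treatment)
  fits <- lapply(models, function(mn) fit_tpc(tr, mn, config))
  names(fits) <- models
  fits
}
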