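# Exponential Q10 sub-fit below the thermal optimum:
# P(T) = P_0 * Q10 ^ ((T - T_ref) / 10), fitted to observations with
# T strictly less than T_opt.

#' Fit the exponential Q10 function below the optimum
#'
#' Fits `P(T) = P_0 * Q10^((T - t_ref)/10)` by nonlinear least squares to
#' the subset of observations with temperature strictly below `t_opt`.
#' `Q10` is the factor increase in rate per 10 deg C rise; `P_0` is the rate
#' at the reference temperature (20 deg C by convention).  Because `t_opt`
#' is model-dependent, Q10 is computed per (model, treatment) pair: pass the
#' `t_opt` from the model fit of interest.
#'
#' Starting values come from a log-linear regression (exact when the data
#' are noiseless and positive); the reported estimates minimise the
#' untransformed least-squares loss.
#'
#' @param treatment A [treatment()] object.
#' @param t_opt Thermal optimum (deg C) defining the subset `T < t_opt`.
#' @param t_ref Reference temperature (deg C), default 20.
#' @return A `tpc_q10` object: `p0`, `q10`, their standard errors, `t_ref`,
#'   `n_used`, `sse`.
#' @examples
#' tr <- simulate_treatment(simulation_config(seed = 1))
#' fit_q10(tr, t_opt = 34.9)
#' @export
fit_q10 <- function(treatment, t_opt, t_ref = 20) {
  tr <- .as_treatment(treatment)
  d <- tr$data[tr$data$temperature < t_opt, , drop = FALSE]
  if (nrow(d) < 3L || length(unique(d$temperature)) < 2L)
    stop("treatment '", tr$label, "': need >= 3 observations at >= 2 distinct ",
         "temperatures below t_opt = ", t_opt)
  # log-linear start (slope = log(Q10)/10)
  pos <- d$rate > 0
  if (sum(pos) >= 2L && length(unique(d$temperature[pos])) >= 2L) {
    lf <- stats::lm(log(rate) ~ I((temperature - t_ref) / 10), data = d[pos, ])
    start <- c(p0 = exp(unname(coef(lf)[1L])),
               q10 = exp(unname(coef(lf)[2L])))
  } else {
    start <- c(p0 = max(mean(d$rate), 1e-3), q10 = 2)
  }
  start["q10"] <- min(max(start[["q10"]], 0.05), 20)
  rf <- function(par) {
    pred <- par[1L] * par[2L]^((d$temperature - t_ref) / 10)
    r <- d$rate - pred
    r[!is.finite(r)] <- 1e4
    r
  }
  res <- minpack.lm::nls.lm(par = start, lower = c(1e-10, 1e-3),
                            upper = c(Inf, 100), fn = rf,
                            control = minpack.lm::nls.lm.control(maxiter = 200))
  est <- setNames(res$par, c("p0", "q10"))
  sse <- res$deviance
  J <- pracma::jacobian(function(par)
    par[1L] * par[2L]^((d$temperature - t_ref) / 10), unname(est))
  dof <- nrow(d) - 2L
  se <- rep(NA_real_, 2L)
  if (dof > 0) {
    vc <- tryCatch(solve(crossprod(J)) * sse / dof, error = function(e) NULL)
    if (!is.null(vc)) se <- sqrt(pmax(diag(vc), 0))
  }
  structure(list(p0 = est[["p0"]], q10 = est[["q10"]],
                 se_p0 = se[1L], se_q10 = se[2L],
                 t_ref = t_ref, n_used = nrow(d), sse = sse,
                 treatment = tr$label),
            class = "tpc_q10")
}

#' @export
print.tpc_q10 <- function(x, ...) {
  cat(sprintf("<tpc_q10> %s: P0 = %.3g", x$treatment, x$p0))
  if (is.finite(x$se_p0)) cat(sprintf(" +- %.2g", x$se_p0))
  cat(sprintf(" (at %g degC), Q10 = %.3g", x$t_ref, x$q10))
  if (is.finite(x$se_q10)) cat(sprintf(" +- %.2g", x$se_q10))
  cat(sprintf(" [n = %d below t_opt]\n", x$n_used))
  invisible(x)
}
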