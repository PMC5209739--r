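# Goodness-of-fit statistics and information-criterion weights.

#' Adjusted R-squared
#'
#' `1 - (1 - R^2) (n - 1) / (n - p - 1)` with `R^2 = 1 - sse/sst`, `sst`
#' taken about the observed mean.
#'
#' @param observed,predicted Equal-length numeric vectors.
#' @param p Number of regression parameters.
#' @return Adjusted R-squared (at most 1; can be negative).
#' @export
adjusted_r2 <- function(observed, predicted, p) {
  stopifnot(length(observed) == length(predicted))
  n <- length(observed)
  if (n <= p + 1) stop("need n > p + 1 observations")
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0) stop("observed rates have zero variance; R-squared undefined")
  sse <- sum((observed - predicted)^2)
  r2 <- 1 - sse / sst
  1 - (1 - r2) * (n - 1) / (n - p - 1)
}

#' Refined index of agreement
#'
#' The bounded absolute-error agreement index d_r (Willmott-type, scaling
#' constant `c = 2`): with `A = sum(|pred - obs|)` and
#' `B = sum(|obs - mean(obs)|)`, `d_r = 1 - A/(c B)` when `A <= c B`, and
#' `c B / A - 1` otherwise.  Values lie in `[-1, 1]`; 1 is a perfect fit and
#' a mean-only predictor scores 0.5.
#'
#' @inheritParams adjusted_r2
#' @param c Scaling constant (default 2).
#' @return d_r in `[-1, 1]`.
#' @export
refined_index_of_agreement <- function(observed, predicted, c = 2) {
  stopifnot(length(observed) == length(predicted))
  A <- sum(abs(predicted - observed))
  B <- sum(abs(observed - mean(observed)))
  if (B == 0) stop("observed rates have zero absolute deviation; d_r undefined")
  if (A <= c * B) 1 - A / (c * B) else c * B / A - 1
}

#' Small-sample Akaike and Schwarz information criteria from least squares
#'
#' Gaussian likelihood with profiled variance gives the `n log(sse/n)` core;
#' `aic_c` adds the small-sample correction `2K(K+1)/(n-K-1)`, appropriate
#' when `K > n/40`.  A perfect fit (`sse = 0`) returns `-Inf`, a sentinel
#' that dominates the ensuing weights.
#'
#' @param sse Sum of squared residuals.
#' @param n Number of observations.
#' @param K Parameter count entering the criterion (see [fit_config()] for
#'   the `p` vs `p + 1` convention).
#' @return The criterion value.
#' @export
aic_c <- function(sse, n, K) {
  if (n <= K + 1) stop("need n > K + 1 for the AICc correction")
  if (sse < 0) stop("sse must be nonnegative")
  if (sse == 0) return(-Inf)
  n * log(sse / n) + 2 * K + 2 * K * (K + 1) / (n - K - 1)
}

#' @rdname aic_c
#' @export
bic <- function(sse, n, K) {
  if (sse < 0) stop("sse must be nonnegative")
  if (sse == 0) return(-Inf)
  n * log(sse / n) + K * log(n)
}

#' Information-criterion weights
#'
#' `w_i = exp(-Delta_i/2) / sum_j exp(-Delta_j/2)` with
#' `Delta_i = IC_i - min(IC)`.  `-Inf` sentinel values (perfect fits) take
#' weight 1, split equally on ties; non-finite (`NA`/`Inf`) entries get
#' weight 0.
#'
#' @param values Numeric vector of criterion values (one per model).
#' @return Weights summing to 1, same names as `values`.
#' @export
information_weights <- function(values) {
  if (!length(values)) stop("empty criterion vector")
  w <- rep(0, length(values))
  names(w) <- names(values)
  sentinel <- is.infinite(values) & values < 0
  if (any(sentinel)) {
    w[sentinel] <- 1 / sum(sentinel)
    return(w)
  }
  finite <- is.finite(values)
  if (!any(finite)) stop("no finite criterion values")
  delta <- values[finite] - min(values[finite])
  ew <- exp(-delta / 2)
  w[finite] <- ew / sum(ew)
  w
}

#' All four comparison metrics for a fit
#'
#' @param fit A converged `tpc_fit`.
#' @param config A [fit_config()] (controls the K convention).
#' @return A list with `adj_r2`, `d_r`, `aicc`, `bic`.
#' @export
fit_metrics <- function(fit, config = fit_config()) {
  if (is.null(fit$estimates)) stop("fit did not converge; metrics undefined")
  K <- fit$p + if (config$ic_param_count == "plus_sigma") 1L else 0L
  list(adj_r2 = adjusted_r2(fit$observed, fit$predictions, fit$p),
       d_r = refined_index_of_agreement(fit$observed, fit$predictions),
       aicc = aic_c(fit$sse, fit$n, K),
       bic = bic(fit$sse, fit$n, K))
}
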