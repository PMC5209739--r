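# Dual-criterion model selection: information-criterion weights across
# treatments, top-6 goodness sets, the biologically-meaningful set, and
# their intersection.

#' Construct a weight matrix from given weight tables
#'
#' Builds the treatments x models weight container from two numeric tables
#' (rows = treatments, columns = models), e.g. published weight tables.
#' Each row should sum to 1; rounded published values are accepted within
#' `tol`.
#'
#' @param w_akaike,w_schwarz Matrices or data.frames of Akaike and Schwarz
#'   weights with identical dimnames.
#' @param tol Row-sum tolerance (default 0.01, accommodating 4-dp rounding).
#' @return A `tpc_weights` object.
#' @export
weight_matrix <- function(w_akaike, w_schwarz, tol = 0.01) {
  wa <- as.matrix(w_akaike)
  wb <- as.matrix(w_schwarz)
  if (!identical(dimnames(wa), dimnames(wb)))
    stop("the two weight tables must have identical treatments and models")
  for (nm in list(rowSums(wa), rowSums(wb))) {
    if (any(abs(nm - 1) > tol))
      stop("weight rows must sum to 1 (tolerance ", tol, ")")
  }
  structure(list(w_akaike = wa, w_schwarz = wb,
                 treatments = rownames(wa), models = colnames(wa)),
            class = "tpc_weights")
}

#' Build the weight matrix from fitted models
#'
#' Computes per-treatment Akaike weights (from AICc) and Schwarz weights
#' (from BIC) across the fitted models.
#'
#' @param fits A named list (one element per treatment) of named lists of
#'   `tpc_fit` objects (one per model), as produced by [fit_all_models()].
#' @param config A [fit_config()] (controls the K convention).
#' @return A `tpc_weights` object; every row of each weight table sums to 1.
#' @export
build_weight_matrix <- function(fits, config = fit_config()) {
  if (!length(fits)) stop("no fits supplied")
  models <- Reduce(union, lapply(fits, names))
  gaps <- character()
  for (tn in names(fits)) {
    missing_models <- setdiff(models, names(fits[[tn]]))
    bad <- vapply(fits[[tn]], function(f) is.null(f$estimates), NA)
    if (length(missing_models) || any(bad))
      gaps <- c(gaps, paste0(tn, ": ",
                             paste(c(missing_models, names(bad)[bad]), collapse = ", ")))
  }
  if (length(gaps))
    stop("missing or unconverged model fits:\n  ", paste(gaps, collapse = "\n  "))
  K <- function(f) f$p + if (config$ic_param_count == "plus_sigma") 1L else 0L
  wa <- t(vapply(fits, function(row) {
    information_weights(vapply(row, function(f) aic_c(f$sse, f$n, K(f)), 0))
  }, numeric(length(models))))
  wb <- t(vapply(fits, function(row) {
    information_weights(vapply(row, function(f) bic(f$sse, f$n, K(f)), 0))
  }, numeric(length(models))))
  dimnames(wa) <- dimnames(wb) <- list(names(fits), models)
  weight_matrix(wa, wb, tol = 1e-9)
}

#' @export
print.tpc_weights <- function(x, ...) {
  cat(sprintf("<tpc_weights> %d treatments x %d models\n",
              length(x$treatments), length(x$models)))
  cat("Mean Akaike weights:\n")
  print(round(colMeans(x$w_akaike), 4))
  invisible(x)
}

#' Mean weights per model
#'
#' Arithmetic mean of each model's weights over the included treatments.
#'
#' @param wm A `tpc_weights` object.
#' @param exclude Character vector of treatment labels to leave out.
#' @return List with named numeric vectors `w_akaike` and `w_schwarz`.
#' @export
mean_weights <- function(wm, exclude = NULL) {
  stopifnot(inherits(wm, "tpc_weights"))
  if (length(exclude)) {
    unknown <- setdiff(exclude, wm$treatments)
    if (length(unknown))
      stop("unknown treatment(s) in 'exclude': ", paste(unknown, collapse = ", "))
  }
  keep <- setdiff(wm$treatments, exclude)
  if (!length(keep)) stop("all treatments excluded")
  list(w_akaike = colMeans(wm$w_akaike[keep, , drop = FALSE]),
       w_schwarz = colMeans(wm$w_schwarz[keep, , drop = FALSE]))
}

#' Top-k models by mean weight
#'
#' @param means Named numeric vector of per-model mean weights.
#' @param k Number of models to return (default 6).
#' @return Character vector of model names, best first; ties broken
#'   alphabetically.
#' @export
top_k_models <- function(means, k = 6) {
  if (k > length(means)) stop("k exceeds the number of models")
  ord <- order(-means, names(means))
  names(means)[ord][seq_len(k)]
}

#' Models with easily obtained biologically-meaningful parameters
#'
#' The models for which P_max, T_opt and a finite T_max are parameters or
#' simple algebraic functions of parameters
#' (`closed_form_meaningful = TRUE` and `tmax_kind = "finite"`).
#'
#' @param registry A registry as from [tpc_registry()].
#' @return Character vector of model names.
#' @export
meaningful_set <- function(registry = tpc_registry()) {
  keep <- vapply(registry, function(m)
    isTRUE(m$closed_form_meaningful) && m$tmax_kind == "finite", NA)
  names(registry)[keep]
}

#' Dual-criterion model selection
#'
#' Implements the two-criterion selection procedure: (1) goodness of fit —
#' the union of the top-`k` models by mean Akaike weight and by mean Schwarz
#' weight, computed both over all treatments and with outlier treatments
#' excluded; (2) ease of obtaining biologically-meaningful parameters — the
#' [meaningful_set()].  The best model is the member of the intersection
#' with the highest mean weight under every computed criterion (ties broken
#' by fewer parameters, then alphabetically).
#'
#' Outlier treatments are those where a single model's Akaike or Schwarz
#' weight exceeds `outlier_threshold` (such a treatment dominates the means);
#' they are excluded in a sensitivity recomputation, and a full
#' leave-one-treatment-out sweep is reported.
#'
#' @param wm A `tpc_weights` object.
#' @param registry A model registry.
#' @param exclude `"auto"` (default: apply the threshold rule), `NULL`
#'   (no exclusion), or explicit treatment labels.
#' @param outlier_threshold Weight above which a treatment is flagged
#'   (default 0.8).
#' @param k Size of each top list (default 6).
#' @param sensitivity Run the leave-one-out sweep (default TRUE).
#' @return A `tpc_selection` report; see Details.
#' @export
dual_criterion_select <- function(wm, registry = tpc_registry(),
                                  exclude = "auto", outlier_threshold = 0.8,
                                  k = 6, sensitivity = TRUE) {
  stopifnot(inherits(wm, "tpc_weights"))
  if (identical(exclude, "auto")) {
    flagged <- wm$treatments[apply(wm$w_akaike, 1, max) > outlier_threshold |
                             apply(wm$w_schwarz, 1, max) > outlier_threshold]
  } else {
    flagged <- exclude %||% character()
  }
  m_all <- mean_weights(wm)
  tops <- list(wA = top_k_models(m_all$w_akaike, k),
               wB = top_k_models(m_all$w_schwarz, k))
  m_excl <- NULL
  if (length(flagged) && length(flagged) < length(wm$treatments)) {
    m_excl <- mean_weights(wm, exclude = flagged)
    tops$wA_excl <- top_k_models(m_excl$w_akaike, k)
    tops$wB_excl <- top_k_models(m_excl$w_schwarz, k)
  }
  goodness <- Reduce(union, tops)
  meaningful <- meaningful_set(registry)
  inter <- intersect(names(registry), intersect(goodness, meaningful))
  crit_vectors <- c(list(m_all$w_akaike, m_all$w_schwarz),
                    if (!is.null(m_excl)) list(m_excl$w_akaike, m_excl$w_schwarz))
  best <- NA_character_
  dominant <- NA
  if (length(inter)) {
    score <- vapply(inter, function(mod)
      mean(vapply(crit_vectors, function(v) rank(-v)[[mod]], 0)), 0)
    is_dom <- vapply(inter, function(mod)
      all(vapply(crit_vectors, function(v) v[[mod]] == max(v[inter]), NA)), NA)
    p_of <- vapply(inter, function(mod) registry[[mod]]$p, 0L)
    ord <- order(score, p_of, inter)
    best <- inter[ord][1L]
    dominant <- isTRUE(is_dom[[best]])
  }
  sens <- NULL
  if (sensitivity && length(wm$treatments) > 1L) {
    sens <- do.call(rbind, lapply(wm$treatments, function(tn) {
      mw <- mean_weights(wm, exclude = tn)
      g <- union(top_k_models(mw$w_akaike, k), top_k_models(mw$w_schwarz, k))
      i <- intersect(g, meaningful)
      b <- if (length(i)) {
        sc <- vapply(i, function(mod)
          mean(c(rank(-mw$w_akaike)[[mod]], rank(-mw$w_schwarz)[[mod]])), 0)
        i[order(sc, vapply(i, function(mod) registry[[mod]]$p, 0L), i)][1L]
      } else NA_character_
      data.frame(excluded = tn, best = b,
                 goodness_set = paste(sort(g), collapse = ";"))
    }))
  }
  structure(list(
    mean_wA = m_all$w_akaike, mean_wB = m_all$w_schwarz,
    mean_wA_excl = m_excl$w_akaike, mean_wB_excl = m_excl$w_schwarz,
    excluded = flagged, top6 = tops,
    goodness_set = goodness, meaningful_set = meaningful,
    intersection = inter, best = best, best_dominates = dominant,
    sensitivity = sens,
    diagnostic = if (!length(inter))
      "no model satisfies both criteria; intersection empty" else NULL
  ), class = "tpc_selection")
}

#' @export
print.tpc_selection <- function(x, ...) {
  cat("<tpc_selection>\n")
  cat("  top-6 by mean Akaike weight: ", paste(x$top6$wA, collapse = ", "), "\n")
  cat("  top-6 by mean Schwarz weight:", paste(x$top6$wB, collapse = ", "), "\n")
  if (length(x$excluded))
    cat("  excluded treatment(s):       ", paste(x$excluded, collapse = ", "), "\n")
  cat("  goodness-of-fit set:         ", paste(sort(x$goodness_set), collapse = ", "), "\n")
  cat("  meaningful-parameter set:    ", paste(x$meaningful_set, collapse = ", "), "\n")
  cat("  intersection:                ", paste(x$intersection, collapse = ", "), "\n")
  cat("  best model:                  ", x$best,
      if (isTRUE(x$best_dominates)) " (dominates on every criterion)" else "", "\n",
      sep = "")
  if (!is.null(x$diagnostic)) cat("  note: ", x$diagnostic, "\n")
  invisible(x)
}

#' Fit, weight and select in one call
#'
#' Convenience wrapper: fits all models to every treatment, builds the
#' weight matrix, and runs [dual_criterion_select()].
#'
#' @param treatments List of [treatment()] objects.
#' @param config A [fit_config()].
#' @param ... Passed to [dual_criterion_select()].
#' @return List with `fits`, `weights` and `selection`.
#' @export
run_selection_study <- function(treatments, config = fit_config(), ...) {
  labels <- vapply(treatments, function(tr) .as_treatment(tr)$label, "")
  if (anyDuplicated(labels)) stop("duplicate treatment labels")
  fits <- lapply(treatments, fit_all_models, config = config)
  names(fits) <- labels
  wm <- build_weight_matrix(fits, config)
  list(fits = fits, weights = wm,
       selection = dual_criterion_select(wm, ...))
}
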