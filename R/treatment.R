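# Treatment container: one species x season x location set of gross
# photosynthesis observations over temperature, with replicates.

#' Construct a treatment
#'
#' A treatment bundles the gross photosynthesis observations for one
#' species/season/location combination: one row per replicate measurement,
#' with temperature in deg C and rate in mg C g-1 DW h-1.
#'
#' @param species,season,location Character labels.  `season` must be
#'   `"summer"` or `"winter"`.
#' @param temperature Numeric vector, deg C.
#' @param rate Numeric vector of gross photosynthesis rates
#'   (mg C g-1 DW h-1), same length as `temperature`.
#' @param replicate Replicate identifiers (defaults to within-temperature
#'   running numbers).
#' @return A `tpc_treatment` object: a list with `species`, `season`,
#'   `location`, `label`, and `data` (a data.frame with columns
#'   `temperature`, `rate`, `replicate`).
#' @export
treatment <- function(species, season, location, temperature, rate,
                      replicate = NULL) {
  season <- match.arg(tolower(season), c("summer", "winter"))
  if (length(temperature) != length(rate))
    stop("'temperature' and 'rate' must have equal length")
  if (any(!is.finite(temperature)))
    stop("temperatures must be finite")
  if (is.null(replicate))
    replicate <- stats::ave(seq_along(temperature), temperature, FUN = seq_along)
  structure(list(
    species = as.character(species), season = season,
    location = as.character(location),
    label = paste(species, season, location, sep = " / "),
    data = data.frame(temperature = as.numeric(temperature),
                      rate = as.numeric(rate),
                      replicate = replicate)
  ), class = "tpc_treatment")
}

#' @export
print.tpc_treatment <- function(x, ...) {
  cat(sprintf("<tpc_treatment> %s: n = %d (%d temperatures, %.1f-%.1f degC)\n",
              x$label, nrow(x$data), length(unique(x$data$temperature)),
              min(x$data$temperature), max(x$data$temperature)))
  invisible(x)
}

# Returns NULL or a character diagnostic; a treatment must support fitting a
# model with p free parameters (n >= p + 2, >= 4 distinct temperatures, and
# non-degenerate rates).
.treatment_diagnostic <- function(tr, p) {
  d <- tr$data
  if (nrow(d) < p + 2)
    return(sprintf("needs at least %d observations for a %d-parameter model, has %d",
                   p + 2, p, nrow(d)))
  if (length(unique(d$temperature)) < 4L)
    return("fewer than 4 distinct temperatures; unimodal curve not identifiable")
  if (stats::sd(d$rate) == 0)
    return("all rates identical; no temperature response to fit")
  NULL
}

.as_treatment <- function(x) {
  if (inherits(x, "tpc_treatment")) return(x)
  if (is.data.frame(x) && all(c("temperature", "rate") %in% names(x))) {
    return(treatment(species = x$species[1] %||% "unknown",
                     season = x$season[1] %||% "summer",
                     location = x$location[1] %||% "unknown",
                     temperature = x$temperature, rate = x$rate,
                     replicate = x$replicate))
  }
  stop("cannot interpret input as a treatment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
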