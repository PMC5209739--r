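# Measurement preprocessing arithmetic, dataset I/O and reporting.

.molar_mass_c <- 12.011
.molar_mass_o2 <- 31.998

#' Gross photosynthesis from net photosynthesis and dark respiration
#'
#' Gross rate = net rate minus dark respiration, with respiration recorded
#' as a negative (oxygen-consuming) rate, so gross = net + |respiration|.
#'
#' @param net,dark_respiration Numeric rates in the same unit.
#' @param unit_net,unit_dark Optional unit strings; if both given they must
#'   match.
#' @return Gross photosynthesis rates.
#' @export
gross_photosynthesis <- function(net, dark_respiration,
                                 unit_net = NULL, unit_dark = NULL) {
  if (!is.null(unit_net) && !is.null(unit_dark) &&
      !identical(unit_net, unit_dark))
    stop("unit mismatch: net in '", unit_net, "', dark respiration in '",
         unit_dark, "'")
  net - dark_respiration
}

#' Oxygen-to-carbon rate conversion
#'
#' Mole-for-mole conversion (1 mol O2 evolved = 1 mol C fixed):
#' `rate_C = rate_O2 * 12.011 / 31.998`.
#'
#' @param rate_o2 Rate on a g (or mg) O2 mass basis.
#' @return The rate on the corresponding carbon mass basis.
#' @export
o2_to_carbon <- function(rate_o2) rate_o2 * .molar_mass_c / .molar_mass_o2

#' @rdname o2_to_carbon
#' @param rate_c Rate on a carbon mass basis.
#' @export
carbon_to_o2 <- function(rate_c) rate_c * .molar_mass_o2 / .molar_mass_c

# supported units: mass prefix (mg|g) C per g DW per (h|d)
.unit_table <- list(
  "mgC_gDW_h" = c(mass = 1, time = 1),
  "gC_gDW_h"  = c(mass = 1000, time = 1),
  "mgC_gDW_d" = c(mass = 1, time = 1 / 24),
  "gC_gDW_d"  = c(mass = 1000, time = 1 / 24)
)

#' Convert between supported rate units
#'
#' Canonical internal unit is `"mgC_gDW_h"` (mg C g-1 DW h-1).  Supported
#' units: `"mgC_gDW_h"`, `"gC_gDW_h"`, `"mgC_gDW_d"`, `"gC_gDW_d"`
#' (g to mg multiplies by 1000; per day to per hour divides by 24).
#'
#' @param rate Numeric rates.
#' @param from,to Unit strings.
#' @return Converted rates.
#' @examples
#' convert_rate_units(1, "gC_gDW_d", "mgC_gDW_h")  # 41.6667
#' @export
convert_rate_units <- function(rate, from, to = "mgC_gDW_h") {
  for (u in c(from, to)) {
    if (!u %in% names(.unit_table))
      stop("unsupported unit '", u, "'; supported: ",
           paste(names(.unit_table), collapse = ", "))
  }
  f <- .unit_table[[from]]
  t <- .unit_table[[to]]
  rate * (f[["mass"]] * f[["time"]]) / (t[["mass"]] * t[["time"]])
}

#' Read observations from CSV
#'
#' Expects a header with columns `species`, `season`, `location`,
#' `temperature_C`, `replicate`, and either `rate` (gross photosynthesis)
#' or the pair `net`, `dark` (dark respiration recorded negative), plus an
#' optional `unit` column (default `"mgC_gDW_h"`).  Rates are converted to
#' the canonical unit and gross photosynthesis computed where needed.
#'
#' @param path CSV file path.
#' @return Named list of [treatment()] objects, one per distinct
#'   species/season/location combination.
#' @export
read_observations <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  required <- c("species", "season", "location", "temperature_C", "replicate")
  missing_cols <- setdiff(required, names(d))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ", paste(missing_cols, collapse = ", "))
  has_rate <- "rate" %in% names(d)
  has_pair <- all(c("net", "dark") %in% names(d))
  if (!has_rate && !has_pair)
    stop("need either a 'rate' column or the pair 'net' + 'dark' in ", path)
  num <- function(col) {
    v <- suppressWarnings(as.numeric(d[[col]]))
    bad <- which(is.na(v) & !is.na(d[[col]]) & d[[col]] != "")
    if (length(bad))
      stop("unparsable numeric value(s) in column '", col, "' at row(s) ",
           paste(utils::head(bad, 5L), collapse = ", "))
    if (anyNA(v))
      stop("missing value(s) in column '", col, "' at row(s) ",
           paste(utils::head(which(is.na(v)), 5L), collapse = ", "))
    v
  }
  tempc <- num("temperature_C")
  rate <- if (has_rate) num("rate")
          else gross_photosynthesis(num("net"), num("dark"))
  if ("unit" %in% names(d)) {
    rate <- unlist(lapply(seq_along(rate), function(i)
      convert_rate_units(rate[i], d$unit[i])))
  }
  key <- paste(d$species, d$season, d$location, sep = " / ")
  out <- lapply(split(seq_len(nrow(d)), key), function(idx) {
    treatment(d$species[idx[1L]], d$season[idx[1L]], d$location[idx[1L]],
              temperature = tempc[idx], rate = rate[idx],
              replicate = d$replicate[idx])
  })
  out[unique(key)]
}

#' Write observations to CSV
#'
#' Inverse of [read_observations()] (canonical units).
#'
#' @param treatments List of [treatment()] objects.
#' @param path Output CSV path.
#' @export
write_observations <- function(treatments, path) {
  rows <- do.call(rbind, lapply(treatments, function(tr) {
    tr <- .as_treatment(tr)
    data.frame(species = tr$species, season = tr$season,
               location = tr$location,
               temperature_C = tr$data$temperature,
               replicate = tr$data$replicate,
               rate = tr$data$rate, unit = "mgC_gDW_h")
  }))
  utils::write.csv(rows, path, row.names = FALSE)
  invisible(path)
}

#' Per-treatment parameter report for one model
#'
#' Fits `model` to every treatment and tabulates the biologically-meaningful
#' parameters with standard errors, the Q10 sub-fit, and adjusted
#' R-squared — one row per treatment (the layout of a curve-parameter
#' summary table).
#'
#' @param treatments List of [treatment()]s.
#' @param model Model to report (default `"YanHunt"`).
#' @param config A [fit_config()].
#' @return A data.frame.
#' @export
study_report <- function(treatments, model = "YanHunt", config = fit_config()) {
  rows <- lapply(treatments, function(tr) {
    tr <- .as_treatment(tr)
    fit <- fit_tpc(tr, model, config)
    if (is.null(fit$estimates)) {
      return(data.frame(species = tr$species, season = tr$season,
                        location = tr$location, model = model,
                        p_max = NA, p_max_se = NA, t_opt = NA, t_opt_se = NA,
                        t_max = NA, t_max_se = NA, p0 = NA, p0_se = NA,
                        q10 = NA, q10_se = NA, adj_r2 = NA,
                        note = fit$diagnostics$reason))
    }
    cards <- fit$cardinals
    se_of <- function(nm) if (nm %in% names(fit$se)) fit$se[[nm]] else NA_real_
    q <- tryCatch(fit_q10(tr, cards$t_opt), error = function(e) NULL)
    data.frame(
      species = tr$species, season = tr$season, location = tr$location,
      model = model,
      p_max = fit$estimates[["p_max"]], p_max_se = se_of("p_max"),
      t_opt = cards$t_opt, t_opt_se = se_of("t_opt"),
      t_max = cards$t_max, t_max_se = se_of("t_max"),
      p0 = if (is.null(q)) NA_real_ else q$p0,
      p0_se = if (is.null(q)) NA_real_ else q$se_p0,
      q10 = if (is.null(q)) NA_real_ else q$q10,
      q10_se = if (is.null(q)) NA_real_ else q$se_q10,
      adj_r2 = adjusted_r2(fit$observed, fit$predictions, fit$p),
      note = "")
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write a report to CSV or JSON
#'
#' Writes a [study_report()] data.frame, a `tpc_weights` object (as the two
#' weight tables), or a `tpc_selection` report.  Format follows the file
#' extension (`.csv` or `.json`).
#'
#' @param x Object to write.
#' @param path Output path.
#' @export
write_report <- function(x, path) {
  json <- grepl("\\.json$", path, ignore.case = TRUE)
  if (inherits(x, "tpc_selection")) {
    if (!json) stop("selection reports are written as JSON")
    out <- x[c("mean_wA", "mean_wB", "mean_wA_excl", "mean_wB_excl",
               "excluded", "top6", "goodness_set", "meaningful_set",
               "intersection", "best", "best_dominates")]
    out <- out[!vapply(out, is.null, NA)]
    jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  } else if (inherits(x, "tpc_weights")) {
    if (json) {
      jsonlite::write_json(list(w_akaike = as.data.frame(x$w_akaike),
                                w_schwarz = as.data.frame(x$w_schwarz)),
                           path, digits = NA, dataframe = "rows")
    } else {
      tab <- data.frame(treatment = rep(x$treatments, 2L),
                        weight = rep(c("akaike", "schwarz"),
                                     each = length(x$treatments)),
                        rbind(x$w_akaike, x$w_schwarz), check.names = FALSE)
      utils::write.csv(tab, path, row.names = FALSE)
    }
  } else if (is.data.frame(x)) {
    if (json) jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
    else utils::write.csv(x, path, row.names = FALSE)
  } else {
    stop("don't know how to write an object of class ", class(x)[1L])
  }
  invisible(path)
}
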