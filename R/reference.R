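# Published reference values shipped with the package (fitted parameter
# estimates and model weights from a tropical seagrass photosynthesis-
# temperature study of seven treatments).  These are fitted values, not raw
# measurements; they serve as selection inputs and as default truth values
# for the synthetic-data generator.

.extdata <- function(file) {
  path <- system.file("extdata", file, package = "tpcselect")
  if (path == "") stop("reference file not found: ", file)
  path
}

#' Published Yan and Hunt parameter estimates for seven seagrass treatments
#'
#' Fitted values (mean and SE) of `P_max`, `T_opt`, `T_max`, `P_0`, `Q10`
#' and adjusted R-squared for seven species/season/location treatments of
#' tropical seagrass.  Units: rates in mg C g-1 DW h-1, temperatures in
#' deg C.
#'
#' @return A data.frame with one row per treatment.
#' @export
reference_parameters <- function() {
  utils::read.csv(.extdata("seagrass_yanhunt_parameters.csv"),
                  check.names = FALSE)
}

#' Published Akaike and Schwarz weight tables
#'
#' The per-treatment Akaike (AICc-based) and Schwarz (BIC-based) weights of
#' all twelve models for the seven seagrass treatments, as a
#' `tpc_weights` object (rows sum to 1 up to 4-dp rounding of the published
#' cells).
#'
#' @return A `tpc_weights` object.
#' @export
reference_weights <- function() {
  rd <- function(f) {
    d <- utils::read.csv(.extdata(f), check.names = FALSE)
    lab <- paste(d$species, d$season, d$location, sep = " / ")
    m <- as.matrix(d[, setdiff(names(d), c("species", "season", "location"))])
    rownames(m) <- lab
    m
  }
  weight_matrix(rd("seagrass_akaike_weights.csv"),
                rd("seagrass_schwarz_weights.csv"))
}
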