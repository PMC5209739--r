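# Registry of the twelve temperature-response models, each reparameterised so
# that P_max (maximum rate) and T_opt (thermal optimum, deg C) are parameters
# and P(T_opt) = P_max holds by construction.  Rates are in mg C g-1 DW h-1,
# temperatures in deg C throughout.

.kB <- 8.617333262e-5   # Boltzmann constant, eV / K
.abs_zero_c <- -273.15

#' Model descriptor registry
#'
#' Returns the twelve empirical thermal-performance-curve models supported by
#' the package.  Every model predicts a unimodal, asymmetric rise-and-fall of
#' rate with temperature, has at most 4 free parameters, and is written in
#' terms of `p_max` and `t_opt`.  Capability flags record which cardinal
#' temperatures each model can predict and whether the biologically-meaningful
#' parameters (P_max, T_opt, T_max) are parameters or simple algebraic
#' functions of parameters (`closed_form_meaningful`).
#'
#' @return A named list of `tpc_model` descriptors, in stable alphabetical
#'   order: Briere1, Briere2, Deutsch, Johnson, Lactin, ONeill, Ratkowsky,
#'   Room, Spain, Thebault, VanDerHeide, YanHunt.
#' @examples
#' reg <- tpc_registry()
#' names(reg)
#' reg$YanHunt$param_names
#' @export
tpc_registry <- function() .tpc_registry

#' Fetch a single model descriptor
#'
#' @param model A model name (see [tpc_registry()]) or a `tpc_model` object.
#' @return A `tpc_model` descriptor.
#' @export
tpc_model <- function(model) {
  if (inherits(model, "tpc_model")) return(model)
  if (!is.character(model) || length(model) != 1L)
    stop("'model' must be a single model name or a 'tpc_model' object")
  m <- .tpc_registry[[model]]
  if (is.null(m))
    stop("unknown model name '", model, "'; see tpc_registry() for choices")
  m
}

#' @export
print.tpc_model <- function(x, ...) {
  cat(sprintf("<tpc_model> %s (p = %d: %s)\n", x$name, x$p,
              paste(x$param_names, collapse = ", ")))
  cat(sprintf("  T_min: %s | T_max: %s | closed-form meaningful: %s\n",
              x$tmin_kind, x$tmax_kind, x$closed_form_meaningful))
  invisible(x)
}

#' Export the registry as a table
#'
#' Machine-readable summary of the model registry (one row per model), with
#' the capability flags for the cardinal temperatures.
#'
#' @param path Optional file path; if supplied the table is written as CSV
#'   (extension `.csv`) or JSON (extension `.json`).
#' @return A `data.frame`, invisibly when `path` is given.
#' @export
registry_table <- function(path = NULL) {
  reg <- tpc_registry()
  tab <- data.frame(
    model = vapply(reg, `[[`, "", "name"),
    n_parameters = vapply(reg, `[[`, 0L, "p"),
    parameters = vapply(reg, function(m) paste(m$param_names, collapse = ";"), ""),
    tmin_kind = vapply(reg, `[[`, "", "tmin_kind"),
    tmax_kind = vapply(reg, `[[`, "", "tmax_kind"),
    closed_form_meaningful = vapply(reg, `[[`, NA, "closed_form_meaningful"),
    interdependent_cardinals = vapply(reg, `[[`, NA, "interdependent_cardinals"),
    row.names = NULL
  )
  if (!is.null(path)) {
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::write_json(tab, path, auto_unbox = TRUE, digits = NA)
    } else {
      utils::write.csv(tab, path, row.names = FALSE)
    }
    return(invisible(tab))
  }
  tab
}

# ---- parameter validation ----------------------------------------------------

# Returns NULL when valid, otherwise a character message naming the violated
# constraint.  Used both by tpc_evaluate (as an error) and by the optimiser
# (as a penalty).
.check_params <- function(m, th) {
  need <- setdiff(m$param_names, names(th))
  if (length(need))
    return(paste0("missing parameter(s): ", paste(need, collapse = ", ")))
  th <- th[m$param_names]
  if (any(!is.finite(unlist(th)))) return("non-finite parameter value")
  if (th[["p_max"]] <= 0) return("p_max must be > 0")
  extra <- m$validate(th)
  if (!is.null(extra)) return(extra)
  NULL
}

.params_ok <- function(m, th) is.null(.check_params(m, th))

#' Evaluate a model curve
#'
#' Computes the predicted gross photosynthesis rate at temperature(s) `temp`
#' for a given model and parameter vector.  Outside a model's thermal support
#' (e.g. beyond `t_max` for the Yan and Hunt model, or below 0 deg C where the
#' model fixes the rate at zero) the returned rate is 0; negative raw values
#' inside the support are clamped to 0.
#'
#' @param model Model name or `tpc_model` descriptor.
#' @param params Named numeric vector (or list) with the model's parameters;
#'   see `tpc_model(model)$param_names`.  `p_max` in mg C g-1 DW h-1,
#'   temperatures in deg C.
#' @param temp Numeric vector of temperatures (deg C).
#' @return Numeric vector of rates (mg C g-1 DW h-1).
#' @examples
#' tpc_evaluate("YanHunt", c(p_max = 3.9, t_opt = 34.9, t_max = 43.7), 34.9)
#' @export
tpc_evaluate <- function(model, params, temp) {
  m <- tpc_model(model)
  th <- as.list(params)
  msg <- .check_params(m, th)
  if (!is.null(msg)) stop("invalid parameters for ", m$name, ": ", msg)
  if (any(!is.finite(temp))) stop("'temp' must be finite")
  m$fun(temp, th)
}

# Unclamped / signed curve used for root bracketing (defaults to fun).
.tpc_raw <- function(m, th, temp) {
  if (is.null(m$raw)) m$fun(temp, th) else m$raw(temp, th)
}

# ---- cardinal temperatures ---------------------------------------------------

# Bracketed root search for the upper (or lower) zero crossing of the signed
# curve.  Window and tolerance follow the package defaults documented in the
# methods vignette: (t_opt, t_opt + 60] for T_max, [t_opt - 150, t_opt) for a
# possible finite T_min, tolerance 1e-6 deg C.
.find_zero <- function(m, th, t_opt, upper = TRUE, window = 60, tol = 1e-6) {
  grid <- if (upper) seq(t_opt, t_opt + window, length.out = 601L)
          else       seq(t_opt - 150, t_opt, length.out = 1501L)
  v <- .tpc_raw(m, th, grid)
  s <- sign(v)
  idx <- which(s[-1L] * s[-length(s)] < 0)
  if (!length(idx)) {
    exact <- which(v == 0)
    if (length(exact)) return(grid[if (upper) exact[1L] else exact[length(exact)]])
    return(NA_real_)
  }
  i <- if (upper) idx[1L] else idx[length(idx)]
  stats::uniroot(function(x) .tpc_raw(m, th, x),
                 lower = grid[i], upper = grid[i + 1L], tol = tol)$root
}

#' Cardinal temperatures of a fitted or specified curve
#'
#' Derives `t_min`, `t_opt` and `t_max` (deg C) for a model and parameter
#' vector.  For models whose cardinal temperatures are parameters or simple
#' algebraic functions of parameters they are returned directly; for the
#' Lactin, Ratkowsky and Spain forms the upper thermal limit requires solving
#' a transcendental equation and is obtained by bracketed root finding within
#' `(t_opt, t_opt + 60]`.  Limits that the model fixes at plus/minus infinity
#' (e.g. the Johnson model's `t_max`) are returned as infinities.  A root
#' that cannot be bracketed yields `status = "unsatisfactory"` with an `NA`
#' temperature rather than an error.
#'
#' @inheritParams tpc_evaluate
#' @return A list with elements `t_min`, `t_opt`, `t_max`, `p_max`, and
#'   `status` (`"ok"` or `"unsatisfactory"`).  `t_min` is `NA` for the Lactin
#'   form when its low-temperature zero crossing does not exist.
#' @export
critical_temperatures <- function(model, params) {
  m <- tpc_model(model)
  th <- as.list(params)
  msg <- .check_params(m, th)
  if (!is.null(msg)) stop("invalid parameters for ", m$name, ": ", msg)
  out <- m$cardinals(th)
  out$p_max <- th[["p_max"]]
  if (is.null(out$status))
    out$status <- if (is.na(out$t_max) && m$tmax_kind == "finite") "unsatisfactory" else "ok"
  out[c("t_min", "t_opt", "t_max", "p_max", "status")]
}

# ---- model definitions -------------------------------------------------------

.briere1_tmin <- function(to, tm) to * (4 * tm - 5 * to) / (2 * tm - 3 * to)
.briere2_tmin <- function(to, tm, m) {
  to * ((2 * m + 1) * to - 2 * m * tm) / ((m + 1) * to - m * tm)
}

.make_model <- function(name, param_names, tmin_kind, tmax_kind,
                        closed_form_meaningful, fun, cardinals,
                        validate = function(th) NULL, raw = NULL,
                        interdependent_cardinals = FALSE,
                        shape_start = numeric(), shape_lower = numeric(),
                        shape_upper = numeric()) {
  structure(list(
    name = name, param_names = param_names, p = length(param_names),
    tmin_kind = tmin_kind, tmax_kind = tmax_kind,
    closed_form_meaningful = closed_form_meaningful,
    interdependent_cardinals = interdependent_cardinals,
    fun = fun, raw = raw, cardinals = cardinals, validate = validate,
    shape_start = shape_start, shape_lower = shape_lower,
    shape_upper = shape_upper
  ), class = "tpc_model")
}

.req_topt_below_tmax <- function(th) {
  if (th[["t_opt"]] >= th[["t_max"]]) "t_opt must be strictly below t_max" else NULL
}

.tpc_registry <- list(

  # Briere-1: P = a T (T - T_min) sqrt(T_max - T).  Stationarity at T_opt
  # forces T_min = T_opt (4 T_max - 5 T_opt) / (2 T_max - 3 T_opt); validity
  # requires 0 < T_opt < T_max < 1.5 T_opt so that T_min < T_opt.
  Briere1 = .make_model(
    "Briere1", c("p_max", "t_opt", "t_max"),
    tmin_kind = "finite-parameter", tmax_kind = "finite",
    closed_form_meaningful = TRUE,
    validate = function(th) {
      if (th[["t_opt"]] <= 0) return("t_opt must be > 0 (deg C)")
      if (th[["t_opt"]] >= th[["t_max"]]) return("t_opt must be strictly below t_max")
      if (th[["t_max"]] >= 1.5 * th[["t_opt"]])
        return("t_max must be below 1.5 * t_opt for the Briere-1 reparameterisation")
      NULL
    },
    fun = function(temp, th) {
      pm <- th[["p_max"]]; to <- th[["t_opt"]]; tm <- th[["t_max"]]
      tn <- .briere1_tmin(to, tm)
      g <- function(x) x * (x - tn) * sqrt(pmax(tm - x, 0))
      out <- numeric(length(temp))
      ok <- temp >= tn & temp <= tm
      out[ok] <- pm * g(temp[ok]) / g(to)
      pmax(out, 0)
    },
    cardinals = function(th) list(t_min = .briere1_tmin(th[["t_opt"]], th[["t_max"]]),
                                  t_opt = th[["t_opt"]], t_max = th[["t_max"]])
  ),

  # Briere-2: generalises the square root to (T_max - T)^(1/m).
  Briere2 = .make_model(
    "Briere2", c("p_max", "t_opt", "t_max", "m"),
    tmin_kind = "finite-parameter", tmax_kind = "finite",
    closed_form_meaningful = TRUE,
    shape_start = c(m = 2), shape_lower = c(m = 1.05), shape_upper = c(m = 10),
    validate = function(th) {
      if (th[["t_opt"]] <= 0) return("t_opt must be > 0 (deg C)")
      if (th[["t_opt"]] >= th[["t_max"]]) return("t_opt must be strictly below t_max")
      if (th[["m"]] <= 1) return("shape exponent m must be > 1")
      if (th[["t_max"]] >= (1 + 1 / th[["m"]]) * th[["t_opt"]])
        return("t_max must be below (1 + 1/m) * t_opt for the Briere-2 reparameterisation")
      NULL
    },
    fun = function(temp, th) {
      pm <- th[["p_max"]]; to <- th[["t_opt"]]; tm <- th[["t_max"]]; mm <- th[["m"]]
      tn <- .briere2_tmin(to, tm, mm)
      g <- function(x) x * (x - tn) * pmax(tm - x, 0)^(1 / mm)
      out <- numeric(length(temp))
      ok <- temp >= tn & temp <= tm
      out[ok] <- pm * g(temp[ok]) / g(to)
      pmax(out, 0)
    },
    cardinals = function(th) list(
      t_min = .briere2_tmin(th[["t_opt"]], th[["t_max"]], th[["m"]]),
      t_opt = th[["t_opt"]], t_max = th[["t_max"]])
  ),

  # Deutsch: Gaussian rise below T_opt, inverted quadratic decline above,
  # reaching zero at T_max; shape parameter a is the Gaussian half-width.
  Deutsch = .make_model(
    "Deutsch", c("p_max", "t_opt", "t_max", "a"),
    tmin_kind = "negative-infinity", tmax_kind = "finite",
    closed_form_meaningful = TRUE,
    shape_start = c(a = 8), shape_lower = c(a = 0.5), shape_upper = c(a = 60),
    validate = function(th) {
      if (!is.null(v <- .req_topt_below_tmax(th))) return(v)
      if (th[["a"]] <= 0) return("Gaussian width a must be > 0")
      NULL
    },
    fun = function(temp, th) {
      pm <- th[["p_max"]]; to <- th[["t_opt"]]; tm <- th[["t_max"]]; a <- th[["a"]]
      below <- temp <= to
      out <- numeric(length(temp))
      out[below] <- pm * exp(-((temp[below] - to) / (2 * a))^2)
      out[!below] <- pm * (1 - ((temp[!below] - to) / (to - tm))^2)
      pmax(out, 0)
    },
    cardinals = function(th) list(t_min = -Inf, t_opt = th[["t_opt"]],
                                  t_max = th[["t_max"]])
  ),

  # Johnson (enzyme-kinetics / high-temperature-inactivation form, absolute
  # temperature scale): rate tends to 0 at 0 K and declines asymptotically
  # (never reaching zero) above the optimum, so T_max = +Inf.  e (activation
  # energy) and e_h (inactivation energy) in eV, e_h > e.
  Johnson = .make_model(
    "Johnson", c("p_max", "t_opt", "e", "e_h"),
    tmin_kind = "fixed-zero-kelvin", tmax_kind = "positive-infinity",
    closed_form_meaningful = FALSE,
    shape_start = c(e = 0.6, e_h = 3), shape_lower = c(e = 0.05, e_h = 0.3),
    shape_upper = c(e = 5, e_h = 40),
    validate = function(th) {
      if (th[["e"]] <= 0) return("activation energy e must be > 0")
      if (th[["e_h"]] <= th[["e"]]) return("inactivation energy e_h must exceed e")
      NULL
    },
    fun = function(temp, th) {
      pm <- th[["p_max"]]; to <- th[["t_opt"]]
      e <- th[["e"]]; eh <- th[["e_h"]]
      tk <- temp - .abs_zero_c; tok <- to - .abs_zero_c
      B <- e / (eh - e)
      out <- numeric(length(temp))
      pos <- tk > 0
      expo <- pmin(eh / .kB * (1 / tok - 1 / tk[pos]), 700)
      g <- exp(-e / (.kB * tk[pos])) / (1 + B * exp(expo))
      gopt <- exp(-e / (.kB * tok)) / (1 + B)
      out[pos] <- pm * g / gopt
      out
    },
    cardinals = function(th) list(t_min = .abs_zero_c, t_opt = th[["t_opt"]],
                                  t_max = Inf)
  ),

  # Lactin (lambda-augmented): P = exp(rho T) - exp(rho Tm - (Tm - T)/delta)
  # + lambda, with the intermediate Tm and offset lambda eliminated in favour
  # of T_opt and P_max.  Depending on the sign of lambda the curve may or may
  # not cross zero at low temperature, so T_min is undefined or finite; the
  # true T_max solves a transcendental equation (root-finding).
  Lactin = .make_model(
    "Lactin", c("p_max", "t_opt", "rho", "delta"),
    tmin_kind = "undefined-or-finite", tmax_kind = "finite",
    closed_form_meaningful = FALSE,
    shape_start = c(rho = 0.12, delta = 4), shape_lower = c(rho = 1e-3, delta = 0.1),
    shape_upper = c(rho = 1, delta = 500),
    validate = function(th) {
      if (th[["rho"]] <= 0) return("rho must be > 0")
      if (th[["delta"]] <= 0) return("delta must be > 0")
      if (th[["rho"]] * th[["delta"]] >= 1)
        return("rho * delta must be < 1 so that t_opt is a maximum")
      NULL
    },
    raw = function(temp, th) {
      pm <- th[["p_max"]]; to <- th[["t_opt"]]
      rho <- th[["rho"]]; dl <- th[["delta"]]
      s <- rho * dl
      tmi <- if (abs(s - 1) < 1e-10) to + 1 / rho else to + log(s) / (rho - 1 / dl)
      lam <- pm - exp(rho * to) * (1 - s)
      exp(rho * temp) - exp(rho * tmi - (tmi - temp) / dl) + lam
    },
    fun = function(temp, th) pmax(.tpc_registry$Lactin$raw(temp, th), 0),
    cardinals = function(th) {
      m <- .tpc_registry$Lactin
      list(t_min = .find_zero(m, th, th[["t_opt"]], upper = FALSE),
           t_opt = th[["t_opt"]],
           t_max = .find_zero(m, th, th[["t_opt"]], upper = TRUE))
    }
  ),

  # O'Neill: P = P_max ((T_max - T)/(T_max - T_opt))^x exp(x (T - T_opt) /
  # (T_max - T_opt)); asymptotically zero at low temperature.
  ONeill = .make_model(
    "ONeill", c("p_max", "t_opt", "t_max", "x"),
    tmin_kind = "negative-infinity", tmax_kind = "finite",
    closed_form_meaningful = FALSE,
    shape_start = c(x = 15), shape_lower = c(x = 0.5), shape_upper = c(x = 400),
    validate = function(th) {
      if (!is.null(v <- .req_topt_below_tmax(th))) return(v)
      if (th[["x"]] <= 0) return("shape exponent x must be > 0")
      NULL
    },
    fun = function(temp, th) {
      pm <- th[["p_max"]]; to <- th[["t_opt"]]; tm <- th[["t_max"]]; x <- th[["x"]]
      d <- tm - to
      out <- numeric(length(temp))
      ok <- temp <= tm
      out[ok] <- pm * ((tm - temp[ok]) / d)^x * exp(x * (temp[ok] - to) / d)
      out
    },
    cardinals = function(th) list(t_min = -Inf, t_opt = th[["t_opt"]],
                                  t_max = th[["t_max"]])
  ),

  # Ratkowsky (square-root-type full-range model, squared form):
  # P = [b (T - T_min) (1 - exp(c (T - Tm)))]^2 on [T_min, Tm].  Stationarity
  # at T_opt fixes Tm; because the squared form is nonnegative everywhere the
  # upper limit is recovered by root finding on the signed pre-square curve.
  Ratkowsky = .make_model(
    "Ratkowsky", c("p_max", "t_opt", "t_min", "c"),
    tmin_kind = "finite-parameter", tmax_kind = "finite",
    closed_form_meaningful = FALSE,
    shape_start = c(c = 0.2), shape_lower = c(c = 5e-3), shape_upper = c(c = 3),
    validate = function(th) {
      if (th[["t_min"]] >= th[["t_opt"]]) return("t_min must be strictly below t_opt")
      if (th[["c"]] <= 0) return("rate constant c must be > 0")
      NULL
    },
    raw = function(temp, th) {
      # signed square root of the rate, normalised so raw(t_opt) = sqrt(p_max)
      pm <- th[["p_max"]]; to <- th[["t_opt"]]; tn <- th[["t_min"]]; cc <- th[["c"]]
      tmi <- to + log1p(cc * (to - tn)) / cc
      s <- function(x) (x - tn) * (1 - exp(cc * (x - tmi)))
      sqrt(pm) * s(temp) / s(to)
    },
    fun = function(temp, th) {
      tn <- th[["t_min"]]; to <- th[["t_opt"]]; cc <- th[["c"]]
      tmi <- to + log1p(cc * (to - tn)) / cc
      r <- .tpc_registry$Ratkowsky$raw(temp, th)
      out <- r^2
      out[temp < tn | temp > tmi] <- 0
      out
    },
    cardinals = function(th) {
      m <- .tpc_registry$Ratkowsky
      list(t_min = th[["t_min"]], t_opt = th[["t_opt"]],
           t_max = .find_zero(m, th, th[["t_opt"]], upper = TRUE))
    }
  ),

  # Room: asymmetric split Gaussian with separate widths below and above the
  # optimum; rate approaches but never reaches zero on either side.
  Room = .make_model(
    "Room", c("p_max", "t_opt", "sigma_low", "sigma_high"),
    tmin_kind = "negative-infinity", tmax_kind = "positive-infinity",
    closed_form_meaningful = FALSE,
    shape_start = c(sigma_low = 9, sigma_high = 5),
    shape_lower = c(sigma_low = 0.5, sigma_high = 0.5),
    shape_upper = c(sigma_low = 80, sigma_high = 80),
    validate = function(th) {
      if (th[["sigma_low"]] <= 0 || th[["sigma_high"]] <= 0)
        return("Gaussian widths must be > 0")
      NULL
    },
    fun = function(temp, th) {
      pm <- th[["p_max"]]; to <- th[["t_opt"]]
      sig <- ifelse(temp <= to, th[["sigma_low"]], th[["sigma_high"]])
      pm * exp(-0.5 * ((temp - to) / sig)^2)
    },
    cardinals = function(th) list(t_min = -Inf, t_opt = th[["t_opt"]], t_max = Inf)
  ),

  # Spain: exponential rise multiplied by an exponential high-temperature
  # cutoff, P = A exp(rho T) (1 - exp(c (T - TL))); asymptotically zero at low
  # temperature, zero at TL (recovered by root finding).
  Spain = .make_model(
    "Spain", c("p_max", "t_opt", "rho", "c"),
    tmin_kind = "negative-infinity", tmax_kind = "finite",
    closed_form_meaningful = FALSE,
    shape_start = c(rho = 0.1, c = 0.5), shape_lower = c(rho = 1e-3, c = 1e-2),
    shape_upper = c(rho = 1, c = 10),
    validate = function(th) {
      if (th[["rho"]] <= 0) return("rho must be > 0")
      if (th[["c"]] <= 0) return("cutoff rate c must be > 0")
      NULL
    },
    raw = function(temp, th) {
      pm <- th[["p_max"]]; to <- th[["t_opt"]]
      rho <- th[["rho"]]; cc <- th[["c"]]
      tl <- to + log((rho + cc) / rho) / cc
      pm * exp(rho * (temp - to)) * (1 - exp(cc * (temp - tl))) / (cc / (rho + cc))
    },
    fun = function(temp, th) pmax(.tpc_registry$Spain$raw(temp, th), 0),
    cardinals = function(th) {
      m <- .tpc_registry$Spain
      list(t_min = -Inf, t_opt = th[["t_opt"]],
           t_max = .find_zero(m, th, th[["t_opt"]], upper = TRUE))
    }
  ),

  # Thebault: linear rise from a finite T_min multiplied by exponential
  # decay, P = P_max ((T - T_min)/(T_opt - T_min)) exp(-(T - T_opt)/(T_opt -
  # T_min)); declines asymptotically above the optimum (T_max = +Inf).
  Thebault = .make_model(
    "Thebault", c("p_max", "t_opt", "t_min"),
    tmin_kind = "finite-parameter", tmax_kind = "positive-infinity",
    closed_form_meaningful = FALSE,
    validate = function(th) {
      if (th[["t_min"]] >= th[["t_opt"]]) return("t_min must be strictly below t_opt")
      NULL
    },
    fun = function(temp, th) {
      pm <- th[["p_max"]]; to <- th[["t_opt"]]; tn <- th[["t_min"]]
      d <- to - tn
      out <- numeric(length(temp))
      ok <- temp >= tn
      out[ok] <- pm * ((temp[ok] - tn) / d) * exp(-(temp[ok] - to) / d)
      out
    },
    cardinals = function(th) list(t_min = th[["t_min"]], t_opt = th[["t_opt"]],
                                  t_max = Inf)
  ),

  # van der Heide: cubic with a repeated root at the lower limit,
  # P = A (T - T_min)^2 (T_max - T).  Stationarity forces
  # T_min = 3 T_opt - 2 T_max: the three cardinal temperatures are mutually
  # interdependent (two of them determine the third).
  VanDerHeide = .make_model(
    "VanDerHeide", c("p_max", "t_opt", "t_max"),
    tmin_kind = "finite-parameter", tmax_kind = "finite",
    closed_form_meaningful = TRUE, interdependent_cardinals = TRUE,
    validate = .req_topt_below_tmax,
    fun = function(temp, th) {
      pm <- th[["p_max"]]; to <- th[["t_opt"]]; tm <- th[["t_max"]]
      tn <- 3 * to - 2 * tm
      out <- numeric(length(temp))
      ok <- temp >= tn & temp <= tm
      out[ok] <- pm * ((temp[ok] - tn)^2 * (tm - temp[ok])) /
        ((to - tn)^2 * (tm - to))
      pmax(out, 0)
    },
    cardinals = function(th) list(t_min = 3 * th[["t_opt"]] - 2 * th[["t_max"]],
                                  t_opt = th[["t_opt"]], t_max = th[["t_max"]])
  ),

  # Yan and Hunt (3-parameter): P = P_max ((T_max - T)/(T_max - T_opt))
  # (T/T_opt)^(T_opt/(T_max - T_opt)) for 0 <= T <= T_max, 0 otherwise.
  # Assumes T_min = 0 deg C.
  YanHunt = .make_model(
    "YanHunt", c("p_max", "t_opt", "t_max"),
    tmin_kind = "fixed-zero-celsius", tmax_kind = "finite",
    closed_form_meaningful = TRUE,
    validate = function(th) {
      if (th[["t_opt"]] <= 0) return("t_opt must be > 0 (deg C)")
      .req_topt_below_tmax(th)
    },
    fun = function(temp, th) {
      pm <- th[["p_max"]]; to <- th[["t_opt"]]; tm <- th[["t_max"]]
      out <- numeric(length(temp))
      ok <- temp >= 0 & temp <= tm
      out[ok] <- pm * ((tm - temp[ok]) / (tm - to)) *
        (temp[ok] / to)^(to / (tm - to))
      pmax(out, 0)
    },
    cardinals = function(th) list(t_min = 0, t_opt = th[["t_opt"]],
                                  t_max = th[["t_max"]])
  )
)
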