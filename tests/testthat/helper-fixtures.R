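# Shared fixtures: one realistic seagrass-scale parameterisation per model
# (optimum near 35 degC, maximum rate near 3.9 mg C g-1 DW h-1).

fixture_params <- function() {
  list(
    Briere1     = c(p_max = 3.9, t_opt = 34.9, t_max = 43.7),
    Briere2     = c(p_max = 3.9, t_opt = 34.9, t_max = 43.7, m = 2.5),
    Deutsch     = c(p_max = 3.9, t_opt = 34.9, t_max = 43.7, a = 8),
    Johnson     = c(p_max = 3.9, t_opt = 34.9, e = 0.6, e_h = 3),
    Lactin      = c(p_max = 3.9, t_opt = 34.9, rho = 0.04, delta = 10),
    ONeill      = c(p_max = 3.9, t_opt = 34.9, t_max = 43.7, x = 15),
    Ratkowsky   = c(p_max = 3.9, t_opt = 34.9, t_min = 5, c = 0.2),
    Room        = c(p_max = 3.9, t_opt = 34.9, sigma_low = 9, sigma_high = 5),
    Spain       = c(p_max = 3.9, t_opt = 34.9, rho = 0.08, c = 0.25),
    Thebault    = c(p_max = 3.9, t_opt = 34.9, t_min = 5),
    VanDerHeide = c(p_max = 3.9, t_opt = 34.9, t_max = 43.7),
    YanHunt     = c(p_max = 3.9, t_opt = 34.9, t_max = 43.7)
  )
}

# noiseless treatment on the study design (7 temperatures x 6 replicates)
noiseless_treatment <- function(model, params, season = "summer",
                                n_replicates = 6L) {
  temps <- rep(design_temperatures(season), each = n_replicates)
  treatment("fixture", season, "lab", temps,
            tpc_evaluate(model, params, temps))
}

# reference treatment labels used in the published weight tables
label_winter_mb <- "C. serrulata / winter / Moreton Bay"

# absolute-tolerance comparison for values published rounded to 4 dp
expect_abs_equal <- function(object, expected, tol = 1e-4) {
  expect_lt(max(abs(object - expected)), tol)
}
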