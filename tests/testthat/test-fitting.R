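test_that("multistart grid is deterministic, valid and has at least six starts", {
  tr <- simulate_treatment(simulation_config(seed = 1))
  for (nm in c("YanHunt", "Johnson", "Briere1", "Ratkowsky")) {
    starts <- multistart_initials(tr, nm)
    expect_gte(length(starts), 6L)
    expect_identical(starts, multistart_initials(tr, nm))
    m <- tpc_model(nm)
    for (st in starts) {
      expect_named(st, m$param_names)
      if ("t_max" %in% m$param_names) expect_lt(st[["t_opt"]], st[["t_max"]])
      expect_silent(tpc_evaluate(nm, st, 25))  # all starts are valid parameters
    }
  }
})

test_that("multistart is at least as good as the naive first start", {
  tr <- simulate_treatment(simulation_config(seed = 5, noise_sd = 0.4))
  for (nm in c("YanHunt", "ONeill")) {
    m <- tpc_model(nm)
    st <- multistart_initials(tr, nm)[[1L]]
    rf <- function(par) {
      th <- setNames(as.list(par), m$param_names)
      pred <- tryCatch(tpc_evaluate(nm, th, tr$data$temperature),
                       error = function(e) rep(Inf, nrow(tr$data)))
      r <- tr$data$rate - pred
      r[!is.finite(r)] <- 1e4
      r
    }
    naive <- minpack.lm::nls.lm(par = st, fn = rf)
    fit <- fit_tpc(tr, nm)
    expect_lte(fit$sse, naive$deviance + 1e-10)
  }
})

test_that("each model refits its own noiseless curve to high relative accuracy", {
  fix <- fixture_params()
  for (nm in names(fix)) {
    th <- fix[[nm]]
    tr <- noiseless_treatment(nm, th)
    fit <- fit_tpc(tr, nm)
    expect_true(fit$converged, label = paste(nm, "converged"))
    expect_lte(fit$sse, 1e-12 * sum(tr$data$rate^2))
    rel <- max(abs(fit$estimates - th) / pmax(abs(th), 1e-8))
    expect_lt(rel, 1e-4, label = paste(nm, "parameter recovery"))
  }
})

test_that("degenerate data yields a flagged non-convergence, not an error", {
  flat <- treatment("x", "summer", "y", rep(c(17, 21, 26, 30, 35, 40, 43), 2),
                    rate = rep(2, 14))
  fit <- fit_tpc(flat, "YanHunt")
  expect_false(fit$converged)
  expect_match(fit$diagnostics$reason, "rates identical")

  few_temps <- treatment("x", "summer", "y", rep(c(20, 30, 40), each = 4),
                         rate = c(1, 1.1, 1, 1.2, 3, 3.1, 3, 3.2, 2, 2.1, 2, 1.9))
  fit2 <- fit_tpc(few_temps, "YanHunt")
  expect_false(fit2$converged)
  expect_match(fit2$diagnostics$reason, "distinct temperatures")

  tiny <- treatment("x", "summer", "y", c(20, 25, 30, 35), c(1, 2, 3, 2))
  fit3 <- fit_tpc(tiny, "Johnson")  # n = 4 < p + 2 = 6
  expect_false(fit3$converged)
  expect_match(fit3$diagnostics$reason, "observations")
})

test_that("fitting identical inputs is bit-for-bit deterministic", {
  tr <- simulate_treatment(simulation_config(seed = 3))
  f1 <- fit_tpc(tr, "Deutsch")
  f2 <- fit_tpc(tr, "Deutsch")
  expect_identical(f1$estimates, f2$estimates)
  expect_identical(f1$sse, f2$sse)
  expect_identical(f1$se, f2$se)
})

test_that("standard errors match the independent nls() implementation", {
  tr <- simulate_treatment(simulation_config(seed = 11, noise_sd = 0.3))
  fit <- fit_tpc(tr, "YanHunt")
  nf <- stats::nls(
    rate ~ p_max * ((t_max - temperature) / (t_max - t_opt)) *
      (temperature / t_opt)^(t_opt / (t_max - t_opt)),
    data = tr$data, start = as.list(fit$estimates))
  expect_equal(unname(fit$estimates), unname(coef(nf)[names(fit$estimates)]),
               tolerance = 1e-6)
  expect_equal(unname(fit$se),
               unname(summary(nf)$coefficients[names(fit$se), "Std. Error"]),
               tolerance = 1e-4)
})

test_that("standard errors vanish on noiseless data", {
  th <- fixture_params()$YanHunt
  fit <- fit_tpc(noiseless_treatment("YanHunt", th), "YanHunt")
  expect_true(all(fit$se < 1e-6))
})

test_that("reported t_opt SE is calibrated against Monte-Carlo spread", {
  n_rep <- 200L
  topts <- numeric(n_rep)
  ses <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    tr <- simulate_treatment(simulation_config(seed = 1000L + i, noise_sd = 0.2))
    fit <- fit_tpc(tr, "YanHunt")
    topts[i] <- fit$estimates[["t_opt"]]
    ses[i] <- fit$se[["t_opt"]]
  }
  expect_lt(abs(sd(topts) - mean(ses)) / mean(ses), 0.3)
})
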