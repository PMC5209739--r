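test_that("registry holds exactly the twelve models with their capability flags", {
  reg <- tpc_registry()
  expect_length(reg, 12L)
  expect_identical(names(reg), sort(names(reg)))  # stable alphabetical order
  expect_true(all(vapply(reg, `[[`, 0L, "p") <= 4L))
  expect_true(all(vapply(reg, `[[`, 0L, "p") >= 3L))
  # every model is written in terms of p_max and t_opt
  for (m in reg) expect_true(all(c("p_max", "t_opt") %in% m$param_names))

  expect_identical(reg$Johnson$tmin_kind, "fixed-zero-kelvin")
  expect_identical(reg$Johnson$tmax_kind, "positive-infinity")
  expect_identical(reg$YanHunt$tmin_kind, "fixed-zero-celsius")
  expect_identical(reg$YanHunt$tmax_kind, "finite")
  expect_identical(reg$Room$tmin_kind, "negative-infinity")
  expect_identical(reg$Room$tmax_kind, "positive-infinity")
  expect_identical(reg$Thebault$tmax_kind, "positive-infinity")
  expect_identical(reg$Lactin$tmin_kind, "undefined-or-finite")
  expect_identical(reg$Deutsch$tmin_kind, "negative-infinity")

  closed <- names(reg)[vapply(reg, `[[`, NA, "closed_form_meaningful")]
  expect_setequal(closed, c("Briere1", "Briere2", "Deutsch", "VanDerHeide",
                            "YanHunt"))
  interdep <- names(reg)[vapply(reg, `[[`, NA, "interdependent_cardinals")]
  expect_identical(interdep, "VanDerHeide")
  expect_identical(reg$YanHunt$p, 3L)

  tab <- registry_table()
  expect_identical(nrow(tab), 12L)
  tmp <- tempfile(fileext = ".csv")
  registry_table(tmp)
  expect_identical(read.csv(tmp)$model, tab$model)
})

test_that("Yan and Hunt curve reproduces its defining identities and oracle value", {
  th <- c(p_max = 3.9, t_opt = 34.9, t_max = 43.7)
  expect_equal(tpc_evaluate("YanHunt", th, 34.9), 3.9)
  expect_equal(tpc_evaluate("YanHunt", th, 43.7), 0)
  # frozen from an extended-precision transcription of the curve equation
  expect_equal(tpc_evaluate("YanHunt", th, 25), 2.20709559451749, tolerance = 1e-12)
  # fixed support: zero below 0 degC and above t_max
  expect_equal(tpc_evaluate("YanHunt", th, c(-5, 50)), c(0, 0))
})

test_that("invalid parameters and unknown models raise informative errors", {
  expect_error(tpc_evaluate("NotAModel", c(p_max = 1), 20), "unknown model")
  expect_error(tpc_evaluate("YanHunt", c(p_max = -1, t_opt = 30, t_max = 40), 20),
               "p_max")
  expect_error(tpc_evaluate("YanHunt", c(p_max = 1, t_opt = 45, t_max = 40), 20),
               "t_opt")
  expect_error(tpc_evaluate("Johnson", c(p_max = 1, t_opt = 30, e = 2, e_h = 1), 20),
               "e_h")
  expect_error(tpc_evaluate("YanHunt", c(p_max = 1, t_opt = 30), 20), "missing")
  expect_error(tpc_evaluate("YanHunt", c(p_max = 1, t_opt = 30, t_max = 40), NaN),
               "finite")
})

test_that("every model attains P_max exactly at t_opt and is zero at a finite t_max", {
  fix <- fixture_params()
  for (nm in names(fix)) {
    th <- fix[[nm]]
    pm <- th[["p_max"]]
    expect_lt(abs(tpc_evaluate(nm, th, th[["t_opt"]]) - pm), 1e-9 * pm)
    cards <- critical_temperatures(nm, th)
    if (is.finite(cards$t_max)) {
      # root-found limits are located to the root tolerance
      tol <- if (tpc_model(nm)$closed_form_meaningful ||
                 nm == "ONeill") 1e-9 * pm else 1e-4 * pm
      expect_lt(abs(tpc_evaluate(nm, th, cards$t_max)), tol)
    }
  }
})

test_that("every curve rises to the optimum and falls beyond it (unimodal shape)", {
  fix <- fixture_params()
  for (nm in names(fix)) {
    th <- fix[[nm]]
    to <- th[["t_opt"]]
    below <- tpc_evaluate(nm, th, seq(to - 6, to - 0.5, by = 0.5))
    above <- tpc_evaluate(nm, th, seq(to + 0.5, to + 4, by = 0.5))
    expect_true(all(diff(below) > 0), label = paste(nm, "increasing below t_opt"))
    expect_true(all(diff(above) < 0), label = paste(nm, "decreasing above t_opt"))
  }
})

test_that("every model is asymmetric about the optimum", {
  fix <- fixture_params()
  for (nm in names(fix)) {
    th <- fix[[nm]]
    to <- th[["t_opt"]]
    lo <- tpc_evaluate(nm, th, to - 5)
    hi <- tpc_evaluate(nm, th, to + 5)
    expect_gt(abs(lo - hi), 1e-6, label = paste(nm, "P(t_opt-5) != P(t_opt+5)"))
  }
})

test_that("cardinal temperatures agree with a brute-force grid oracle", {
  fix <- fixture_params()
  for (nm in names(fix)) {
    th <- fix[[nm]]
    cards <- critical_temperatures(nm, th)
    expect_identical(cards$status, "ok")
    grid <- seq(0.5, 60, by = 0.001)
    v <- tpc_evaluate(nm, th, grid)
    expect_lt(abs(grid[which.max(v)] - cards$t_opt), 0.01)
    if (is.finite(cards$t_max)) {
      # t_max is the support boundary: positive just below, zero just above
      expect_gt(tpc_evaluate(nm, th, cards$t_max - 1e-3), 0)
      expect_equal(tpc_evaluate(nm, th, cards$t_max + 1e-3), 0,
                   tolerance = 1e-12)
    }
  }
})

test_that("fixed and infinite limits are reported without computation", {
  expect_identical(critical_temperatures("Johnson", fixture_params()$Johnson)$t_max, Inf)
  expect_equal(critical_temperatures("Johnson", fixture_params()$Johnson)$t_min, -273.15)
  expect_identical(critical_temperatures("Room", fixture_params()$Room)$t_min, -Inf)
  expect_identical(critical_temperatures("Thebault", fixture_params()$Thebault)$t_max, Inf)
  expect_equal(critical_temperatures("YanHunt", fixture_params()$YanHunt)$t_min, 0)
  # van der Heide cardinals are interdependent: t_min = 3 t_opt - 2 t_max
  vdh <- critical_temperatures("VanDerHeide", c(p_max = 3.9, t_opt = 34.9, t_max = 43.7))
  expect_equal(vdh$t_min, 3 * 34.9 - 2 * 43.7)
})

test_that("an unbracketable upper root is flagged, not raised", {
  # Lactin with rho*delta near 1 pushes the zero crossing beyond the
  # t_opt + 60 search window
  th <- c(p_max = 3.9, t_opt = 34.9, rho = 0.01, delta = 99)
  cards <- critical_temperatures("Lactin", th)
  expect_identical(cards$status, "unsatisfactory")
  expect_true(is.na(cards$t_max))
})
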