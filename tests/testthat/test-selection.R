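ref_wm <- reference_weights()

test_that("published weight tables load as a valid weight matrix", {
  expect_s3_class(ref_wm, "tpc_weights")
  expect_length(ref_wm$treatments, 7L)
  expect_length(ref_wm$models, 12L)
  expect_true(all(abs(rowSums(ref_wm$w_akaike) - 1) < 0.01))
  expect_error(weight_matrix(ref_wm$w_akaike * 2, ref_wm$w_schwarz), "sum to 1")
})

test_that("mean weights reproduce the published per-model means to 4 dp", {
  m <- mean_weights(ref_wm)
  expect_abs_equal(m$w_akaike[["YanHunt"]], 0.0995)
  expect_abs_equal(m$w_akaike[["Johnson"]], 0.2088)
  m_ex <- mean_weights(ref_wm, exclude = label_winter_mb)
  expect_abs_equal(m_ex$w_schwarz[["YanHunt"]], 0.1733)
  expect_abs_equal(m_ex$w_akaike[["YanHunt"]], 0.1144)
  # single-row matrix: means equal that row
  one <- weight_matrix(ref_wm$w_akaike[1, , drop = FALSE],
                       ref_wm$w_schwarz[1, , drop = FALSE])
  expect_equal(mean_weights(one)$w_akaike, ref_wm$w_akaike[1, ])
  expect_error(mean_weights(ref_wm, exclude = "no such treatment"), "unknown")
  expect_error(mean_weights(one, exclude = rownames(ref_wm$w_akaike)[1]),
               "all treatments excluded")
})

test_that("top-k ranking reproduces the published orderings", {
  m <- mean_weights(ref_wm)
  expect_identical(top_k_models(m$w_akaike, 6),
                   c("Johnson", "Room", "ONeill", "YanHunt", "Ratkowsky",
                     "Deutsch"))
  expect_identical(top_k_models(m$w_schwarz, 6)[1L], "Johnson")
  expect_identical(top_k_models(m$w_schwarz, 6),
                   c("Johnson", "YanHunt", "Briere1", "Room", "ONeill",
                     "Ratkowsky"))
  expect_identical(top_k_models(c(a = 0.9, b = 0.1), 1), "a")
  expect_identical(top_k_models(c(b = 0.5, a = 0.5, c = 0.1), 2), c("a", "b"))
  expect_error(top_k_models(m$w_akaike, 13), "exceeds")
})

test_that("the meaningful set is driven by the registry flags", {
  expect_identical(meaningful_set(),
                   c("Briere1", "Briere2", "Deutsch", "VanDerHeide", "YanHunt"))
  expect_false("ONeill" %in% meaningful_set())
  reg2 <- tpc_registry()
  reg2$YanHunt$closed_form_meaningful <- FALSE
  expect_identical(meaningful_set(reg2),
                   c("Briere1", "Briere2", "Deutsch", "VanDerHeide"))
})

test_that("dual-criterion selection on the published weights picks Yan and Hunt", {
  sel <- dual_criterion_select(ref_wm)
  # the winter Moreton Bay treatment exceeds the 0.8 outlier threshold
  expect_identical(sel$excluded, label_winter_mb)
  # same six models with and without the exclusion, in a different order
  expect_setequal(sel$top6$wA, sel$top6$wA_excl)
  expect_setequal(sel$top6$wB, sel$top6$wB_excl)
  expect_setequal(sel$goodness_set,
                  c("Briere1", "Deutsch", "Johnson", "ONeill", "Ratkowsky",
                    "Room", "YanHunt"))
  expect_identical(sel$intersection, c("Briere1", "Deutsch", "YanHunt"))
  expect_identical(sel$best, "YanHunt")
  expect_true(sel$best_dominates)
  expect_identical(nrow(sel$sensitivity), 7L)
  # the choice is robust to the flagged exclusion and to most single
  # exclusions (a close runner-up can overtake when a treatment that favours
  # the winner is dropped)
  expect_identical(
    sel$sensitivity$best[sel$sensitivity$excluded == label_winter_mb],
    "YanHunt")
  expect_gte(mean(sel$sensitivity$best == "YanHunt"), 6 / 7)
})

test_that("weight matrix built from fits normalises and averages to 1/12", {
  trs <- simulate_study(seed = 21, noise_sd = 0.3)[1:2]
  fits <- lapply(trs, fit_all_models)
  wm <- build_weight_matrix(fits)
  expect_equal(unname(rowSums(wm$w_akaike)), rep(1, 2), tolerance = 1e-12)
  expect_equal(unname(rowSums(wm$w_schwarz)), rep(1, 2), tolerance = 1e-12)
  expect_equal(unname(rowMeans(wm$w_akaike)), rep(1 / 12, 2), tolerance = 1e-12)
  # missing cells are reported
  broken <- fits
  broken[[1]] <- broken[[1]][-3]
  expect_error(build_weight_matrix(broken), "missing")
})

test_that("noiseless generated treatments give the true model weight ~ 1", {
  th <- fixture_params()$YanHunt
  trs <- list(noiseless_treatment("YanHunt", th, "summer"),
              noiseless_treatment("YanHunt", c(p_max = 2.9, t_opt = 35.8,
                                               t_max = 44.7), "winter"))
  trs[[2]]$label <- "second / winter / lab"
  fits <- lapply(trs, fit_all_models)
  names(fits) <- vapply(trs, `[[`, "", "label")
  wm <- build_weight_matrix(fits)
  expect_true(all(wm$w_akaike[, "YanHunt"] > 0.999))
  sel <- dual_criterion_select(wm)
  expect_identical(sel$best, "YanHunt")
})

test_that("selection is invariant to a common shift of a treatment's criteria", {
  v <- c(m1 = 100, m2 = 102, m3 = 95)
  expect_equal(information_weights(v), information_weights(v - 95))
})

test_that("an empty intersection is reported with a diagnostic, not an error", {
  reg2 <- tpc_registry()
  for (nm in names(reg2)) reg2[[nm]]$closed_form_meaningful <- FALSE
  sel <- dual_criterion_select(ref_wm, registry = reg2)
  expect_true(is.na(sel$best))
  expect_match(sel$diagnostic, "intersection empty")
})
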