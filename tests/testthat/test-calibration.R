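test_that("calibration recovers targets generated by the model itself", {
  ## ground truth with known parameters -> targets -> refit -> the fitted
  ## statistics must reproduce the targets (parameters may be degenerate)
  truth <- radiation_quality("truth", 1, 500, 0.6, 0.25, 22)
  cfg <- simulation_config(n_clusters = 1e6, seed = 51)
  y <- tally_yields(generate_clusters(truth, cfg), cfg)
  ## convert simulated yields into a calibration target
  tgt_yields <- y$table$yield * 500 / sum(y$table$yield)
  names(tgt_yields) <- y$table$class
  tgt <- calibration_target(tgt_yields, tolerance = 0.05)
  fit <- damage_model(tgt, quality_name = "refit", n_final = 5e5, seed = 52)
  expect_true(fit$converged)
  expect_equal(fit$quality$cluster_rate_rho, 500)
  ## the recovered parameters should sit near the generating values
  expect_equal(coef(fit)[["multiplicity_nu"]], 0.6, tolerance = 0.15)
  expect_equal(coef(fit)[["p_strand_break"]], 0.25, tolerance = 0.1)
  expect_lt(abs(coef(fit)[["nseg"]] - 22), 3)
})

test_that("the default baseline calibration reproduces its reference yields", {
  m <- test_model()
  expect_true(m$converged)
  expect_lt(max(abs(m$residuals)), m$target$tolerance)
  ## total damage is exact by construction (one damage site per cluster)
  expect_equal(m$fitted_yields$totals["total_damage", "yield"],
               m$target$total, tolerance = 1e-12)
  ## multiplicity must be positive: DSB targets need multi-lesion clusters
  expect_gt(coef(m)[["multiplicity_nu"]], 0)
  expect_gt(coef(m)[["p_strand_break"]], 0)
})

test_that("model methods expose coefficients, predictions and simulations", {
  m <- test_model()
  co <- coef(m)
  expect_named(co, c("cluster_rate_rho", "multiplicity_nu",
                     "p_strand_break", "nseg"))
  pr <- predict(m, data.frame(dmso_M = c(0, 0.1), o2_percent = 21),
                n_clusters = 1e5, seed = 53)
  expect_true(all(c("survival", "class", "yield") %in% names(pr)))
  s0 <- unique(pr$survival[pr$dmso_M == 0])
  expect_equal(s0, 1)
  ## coupled prediction: yields shrink with survival
  t0 <- pr$yield[pr$dmso_M == 0 & pr$class == "total_damage"]
  t1 <- pr$yield[pr$dmso_M == 0.1 & pr$class == "total_damage"]
  expect_lt(t1, t0)
  y <- simulate(m, seed = 54, n_clusters = 2e4)
  expect_s3_class(y, "damage_yields")
  expect_output(print(m), "Calibrated")
  expect_output(print(summary(m)), "Relative residuals")
})

test_that("oxygen calibration recovers synthetic ground-truth parameters", {
  m <- test_model()
  truth <- oxygen_params(m_lesion = 1.6, k_o2 = 0.5)
  curve <- dsb_retention_curve(m, n_clusters = 5e5, seed = 55)
  ## generate the two targets from the ground truth through the same model
  s_hyp <- oxygen_survival_factor(0.001, truth)
  s_int <- oxygen_survival_factor(0.1, truth)
  oer_target <- 1 / curve$fun(s_hyp)
  dsb_int <- curve$fun(s_int) * m$fitted_yields$totals["total_DSB", "yield"]
  fit <- calibrate_oxygen(m, oer_target = oer_target,
                          intermediate = list(o2_percent = 0.1, total_DSB = dsb_int),
                          curve = curve)
  expect_equal(fit$m_lesion, 1.6, tolerance = 0.05)
  expect_equal(fit$k_o2, 0.5, tolerance = 0.15)
  ## endpoint-only mode fits m and keeps K
  fit_m <- calibrate_oxygen(m, oer_target = oer_target, intermediate = NULL,
                            curve = curve)
  expect_equal(fit_m$k_o2, m$quality$oxygen$k_o2)
  expect_lt(attr(fit_m, "fit")$residual, 1e-4)
})

test_that("retention curve is monotone and anchored at 1", {
  m <- test_model()
  curve <- dsb_retention_curve(m, s_grid = seq(0.4, 1, 0.1),
                               n_clusters = 2e5, seed = 56)
  expect_true(all(diff(curve$retention) >= 0))
  expect_equal(curve$retention[length(curve$retention)], 1)
  ## complex-damage nonlinearity: retention below s but above s^2 * 0.9
  mid <- curve$fun(0.7)
  expect_lt(mid, 0.7)
  expect_gt(mid, 0.7^2 * 0.9)
})

test_that("RBE anchoring scales a high-multiplicity quality to the requested ratio", {
  m <- test_model()
  he <- anchor_rbe_quality(m, rbe0 = 2.9, multiplicity_nu = 3,
                           n_clusters = 2e5, seed = 57)
  cfg <- simulation_config(n_clusters = 2e5, seed = 58)
  y_he <- tally_yields(generate_clusters(he, cfg), cfg)
  r <- rbe(y_he, yield_entry(m$fitted_yields, "total_DSB"))
  expect_equal(r[["value"]], 2.9, tolerance = 0.03)
  ## the complex-DSB share is markedly higher than the low-LET baseline's
  share <- function(y) sum(y$table$yield[y$table$class %in% c("DSB+", "DSB++")]) /
    y$totals["total_DSB", "yield"]
  expect_gt(share(y_he), 2 * share(m$fitted_yields))
})
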