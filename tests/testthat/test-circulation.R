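test_that("least-squares fit to the calibration pairs recovers the published parameters", {
  fit <- fit_flow_model()
  expect_equal(fit$F_o, 0.31)    # minimum measured flow
  expect_equal(fit$F_max, 1.22)  # flow at the highest temperature
  expect_equal(fit$a, -2.67, tolerance = 0.05 / 2.67)
  expect_equal(fit$b, 4.88, tolerance = 0.05 / 4.88)
  expect_lt(attr(fit, "fit")$sse, 0.05)

  # independent oracle: Levenberg-Marquardt via minpack.lm on the same SSE
  skip_if_not_installed("minpack.lm")
  d <- chiesa_flow_data()
  dT <- d$temperature_C - 34.9
  lm_fit <- minpack.lm::nlsLM(
    flow_L_min ~ 0.31 + (1.22 - 0.31) / (1 + exp(a * dT + b)),
    data = data.frame(flow_L_min = d$flow_L_min, dT = dT),
    start = list(a = -1, b = 1),
    control = minpack.lm::nls.lm.control(maxiter = 500))
  expect_equal(fit$a, unname(coef(lm_fit)["a"]), tolerance = 1e-4)
  expect_equal(fit$b, unname(coef(lm_fit)["b"]), tolerance = 1e-4)
})

test_that("fitted model reproduces the published flow predictions", {
  fit <- fit_flow_model()
  # elevations of the printed 1 cm and 2 cm tissue temperatures over core
  expect_equal(predict_flow(42.2 - 37, fit), 1.22, tolerance = 0.02 / 1.22)
  expect_equal(predict_flow(39.6 - 37, fit), 1.11, tolerance = 0.02 / 1.11)
  # resting elevation: F(0) sits just above the baseline flow
  expect_equal(predict_flow(0, fit), 0.317, tolerance = 0.01)
})

test_that("logistic form has the correct asymptotes, midpoint and bounds", {
  p <- flow_model_params(0.31, 1.22, -2.67, 4.88)
  expect_equal(predict_flow(-1e6, p), 0.31)
  expect_equal(predict_flow(1e6, p), 1.22)
  expect_equal(predict_flow(-p$b / p$a, p), (0.31 + 1.22) / 2)
  dT <- seq(-5, 10, by = 0.05)
  f <- predict_flow(dT, p)
  expect_true(all(f > 0.31 & f < 1.22))    # strictly inside (F_o, F_max)
  expect_true(all(diff(f) > 0))            # monotone for a < 0
})

test_that("noiseless synthetic data recover the generating parameters", {
  truth <- flow_model_params(0.31, 1.22, -2.67, 4.88)
  dT <- c(0, 0.8, 1.6, 2.4, 3.2, 4)
  synth <- data.frame(temperature_C = 34.9 + dT,
                      flow_L_min = predict_flow(dT, truth))
  fit <- fit_flow_model(synth, 34.9, F_o = 0.31, F_max = 1.22)
  expect_equal(fit$a, truth$a, tolerance = 1e-6)
  expect_equal(fit$b, truth$b, tolerance = 1e-6)
})

test_that("parameter recovery under measurement noise is accurate and unbiased", {
  set.seed(2024)
  truth <- flow_model_params(0.31, 1.22, -2.67, 4.88)
  dT <- chiesa_flow_data()$temperature_C - 34.9
  a_hat <- replicate(200, {
    noisy <- data.frame(
      temperature_C = 34.9 + dT,
      flow_L_min = pmax(predict_flow(dT, truth) + rnorm(length(dT), 0, 0.05),
                        0.01))
    fit_flow_model(noisy, 34.9, F_o = 0.31, F_max = 1.22)$a
  })
  expect_lt(median(abs(a_hat - truth$a)), 0.5)
})

test_that("degenerate calibration data are rejected", {
  expect_error(fit_flow_model(data.frame(temperature_C = c(35, 36),
                                         flow_L_min = c(0.3, 0.5))),
               "at least 3")
  expect_error(fit_flow_model(data.frame(temperature_C = 35:39,
                                         flow_L_min = rep(0.5, 5))),
               "degenerate")
  expect_error(fit_flow_model(data.frame(temperature_C = c(35, 35, 36),
                                         flow_L_min = c(0.3, 0.4, 0.5))),
               "distinct")
})

test_that("flow fields are monotone, bounded, and congruence-checked", {
  fit <- fit_flow_model()
  vol <- small_scene_volume()
  base <- baseline_field(vol)
  f65 <- pennes_steady(vol, small_scene_actuators(65))
  fl <- flow_field(f65, base, fit)
  expect_true(all(fl$values >= fit$F_o - 1e-9))
  expect_true(all(fl$values <= fit$F_max + 1e-9))
  expect_true(all(abs(fl$fold_change - fl$values / fit$F_o) < 1e-12))
  expect_lte(max(fl$fold_change), fit$F_max / fit$F_o + 1e-9)
  # baseline against itself: uniform flow at delta-T = 0
  fl0 <- flow_field(base, base, fit)
  expect_equal(max(abs(fl0$values - predict_flow(0, fit))), 0)
  # saturation under each actuator for a hot scene (union contact patch)
  sat <- fl$values[, , 1] >= 0.99 * fit$F_max
  expect_gt(sum(sat), 0)
  # pointwise monotone in temperature
  f45 <- pennes_steady(vol, small_scene_actuators(45))
  fl45 <- flow_field(f45, base, fit)
  expect_gte(min(fl$values - fl45$values), -1e-9)
  # grid mismatch errors
  volB <- small_scene_volume(spacing = 8)
  expect_error(flow_field(f65, baseline_field(volB), fit), "congruent")
})

test_that("form-resolution report justifies the logistic default", {
  rep <- form_resolution_oracle()
  ref <- attr(rep, "reference_exponential")
  # the printed unbounded form at (-2.67, 4.88) overshoots F_max beyond ~2 C
  expect_true(all(ref$flow[ref$delta_T >= 2.1] > 1.22))
  sse <- setNames(rep$sse, rep$form)
  expect_lt(sse[["logistic"]], 0.05)
  expect_gt(sse[["exponential"]], sse[["logistic"]])
  # logistic optimum close to the published values
  lg <- rep[rep$form == "logistic", ]
  expect_equal(lg$a, -2.67, tolerance = 0.05 / 2.67)
  expect_equal(lg$b, 4.88, tolerance = 0.05 / 4.88)
  # at the published parameters both the logistic and the printed
  # exponential form reproduce the resting flow near F_o
  expect_equal(predict_flow(0, flow_model_params(0.31, 1.22, -2.67, 4.88)),
               0.31, tolerance = 0.03 / 0.31)
  expect_equal(ref$flow[ref$delta_T == 0], 0.31, tolerance = 0.03 / 0.31)
  # the freely fitted clamped form beats the unbounded one
  expect_lt(sse[["clamped"]], sse[["exponential"]])
})

test_that("fitted parameters round-trip through JSON", {
  fit <- fit_flow_model()
  path <- withr::local_tempfile(fileext = ".json")
  write_flow_params_json(fit, path)
  back <- read_flow_params_json(path)
  expect_equal(back$a, fit$a)
  expect_equal(back$b, fit$b)
  expect_identical(back$form, fit$form)
  # refit from the exported curve reproduces the parameters
  dT <- seq(0, 4, by = 0.5)
  refit <- fit_flow_model(data.frame(temperature_C = 34.9 + dT,
                                     flow_L_min = predict_flow(dT, back)),
                          34.9, F_o = fit$F_o, F_max = fit$F_max)
  expect_equal(refit$a, fit$a, tolerance = 1e-5)
})
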