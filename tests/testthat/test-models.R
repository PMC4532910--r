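test_that("the factorial model space enumerates 24 distinct models", {
  models <- enumerate_models()
  expect_equal(nrow(models), 24)
  expect_equal(length(unique(models$model_id)), 24)
  expect_equal(sum(models$prior == "flat"), 8)
  expect_equal(sum(models$combination == "weighting" &
                     models$decay == "decay" &
                     models$prior == "double"), 1)
  expect_identical(models, enumerate_models())
})

test_that("parameter sets are validated against the model spec", {
  mod_sel <- model_spec("selection", "no_decay", "flat")
  expect_error(
    durbayes:::validate_params(
      observer_params(w_H = 0.5, c_H = 0.5), mod_sel),
    "not part of"
  )
  expect_error(
    durbayes:::validate_params(observer_params(), mod_sel),
    "requires parameter 'c_H'"
  )
  # w_H is irrelevant without HL stimuli and so not required
  expect_silent(
    durbayes:::validate_params(
      observer_params(),
      model_spec("weighting", "no_decay", "flat"), has_HL = FALSE)
  )
  expect_error(observer_params(sigma_H = -1))
  expect_error(observer_params(m = 0.5))
  expect_error(model_spec("averaging", "decay", "flat"))
})

test_that("optimal-integration SD follows the reliability-weighting rule", {
  expect_equal(predict_sd_optimal(0.3, 0.3), 0.3 / sqrt(2))
  # values used in the illustration of the combination rules
  expect_equal(predict_sd_optimal(0.2, 0.24),
               0.2 * 0.24 / sqrt(0.2^2 + 0.24^2), tolerance = 1e-12)
  expect_equal(predict_sd_optimal(0.2, 0.24), 0.15364, tolerance = 1e-4)
  # a vastly noisier partner contributes nothing
  expect_equal(predict_sd_optimal(0.2, 1e6), 0.2, tolerance = 1e-8)
  expect_error(predict_sd_optimal(0, 0.2))
  grid <- expand.grid(sH = c(0.1, 0.2, 0.35), sL = c(0.12, 0.24, 0.4))
  expect_true(all(predict_sd_optimal(grid$sH, grid$sL) <
                    pmin(grid$sH, grid$sL)))
})

test_that("selection-rule mixture moments match the closed form", {
  out <- predict_mean_sd_selection(1, 0.2, -0.1, 0.2, 0.24)
  expect_equal(out$mean_offset, 0.2)
  expect_equal(out$sd, 0.2)
  out2 <- predict_mean_sd_selection(0.5, 0.1, -0.1, 0.2, 0.24)
  expect_equal(out2$sd, sqrt(0.0588), tolerance = 1e-12)
  # identical components collapse to a single Gaussian
  out3 <- predict_mean_sd_selection(0.5, 0.1, 0.1, 0.3, 0.3)
  expect_equal(out3$sd, 0.3)

  # Monte-Carlo check of the two-component mixture moments
  set.seed(42)
  n <- 2e5
  pick <- runif(n) < 0.3
  x <- ifelse(pick, rnorm(n, 0.2, 0.2), rnorm(n, -0.2, 0.24))
  mc <- predict_mean_sd_selection(0.3, 0.2, -0.2, 0.2, 0.24)
  expect_equal(mean(x), mc$mean_offset, tolerance = 0.01)
  expect_equal(sd(x), mc$sd, tolerance = 0.01)
})

test_that("weighted combination matches its distributional moments", {
  expect_equal(combine_weighting(0.7, -0.3, 1), 0.7)
  expect_equal(combine_weighting(1.0, 0.8, 0.5), 0.9)
  set.seed(1)
  n <- 1e6
  x <- combine_weighting(rnorm(n, 0, 0.2), rnorm(n, 0, 0.24), 0.5)
  expect_equal(sd(x), sqrt(0.25 * 0.04 + 0.25 * 0.0576), tolerance = 0.005)
})

test_that("combination rules preserve the predicted SD ordering", {
  sH <- 0.2
  sL <- 0.24
  for (w in seq(0, 1, by = 0.1)) {
    sd_w <- sqrt(w^2 * sH^2 + (1 - w)^2 * sL^2)
    expect_lte(sd_w, max(sH, sL) + 1e-12)
    expect_lt(predict_sd_optimal(sH, sL), min(sH, sL))
    sd_sel <- predict_mean_sd_selection(w, 0.2, -0.2, sH, sL)$sd
    expect_gte(sd_sel, min(sH, sL) - 1e-12)
  }
})

test_that("measurement distributions reflect stimulus type and decay", {
  pars <- rep_params()
  mod <- model_spec("weighting", "decay", "double")
  m_second <- measurement_distribution("H", log(600), pars, "second", mod)
  expect_equal(m_second$sd, 0.2)
  expect_equal(m_second$mean, log(600) + 0.2)
  m_first <- measurement_distribution("H", log(600), pars, "first", mod)
  expect_equal(m_first$sd, 0.3)  # sigma_H * m
  m_hl <- measurement_distribution("HL", log(600), pars, "second", mod)
  expect_equal(nrow(m_hl), 2)
  # each element keeps the SD it has when displayed alone
  expect_equal(m_hl$sd, c(pars$sigma_H, pars$sigma_L))
  expect_equal(m_hl$sd,
               c(measurement_distribution("H", log(600), pars,
                                          "second", mod)$sd,
                 measurement_distribution("L", log(600), pars,
                                          "second", mod)$sd))
})
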