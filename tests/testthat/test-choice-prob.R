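test_that("flat-prior equal-variance choice probability is exact", {
  mod <- model_spec("weighting", "no_decay", "flat")
  for (delta in c(-0.4, -0.1, 0, 0.2, 0.5)) {
    for (sg in c(0.15, 0.25)) {
      tr <- one_trial("H", "H", comp_ms = 600 * exp(delta))
      p <- choice_probability(tr, mod,
                              observer_params(sigma_H = sg, lambda = 0))
      expect_equal(p$p_second_longer, pnorm(delta / (sg * sqrt(2))),
                   tolerance = 1e-10)
    }
  }
})

test_that("lapse bounds and symmetry hold for every prior structure", {
  s3 <- head(build_schedule_exp3(1), 200)
  for (m in list(model_spec("weighting", "decay", "flat"),
                 model_spec("weighting", "decay", "single"),
                 model_spec("weighting", "decay", "double"))) {
    pars <- rep_params(m)
    p <- choice_probability(s3, m, pars)$p_second_longer
    expect_true(all(p >= pars$lambda / 2 - 1e-12))
    expect_true(all(p <= 1 - pars$lambda / 2 + 1e-12))
  }
  # full symmetry: equal biases and SDs, same type both intervals
  tr <- one_trial("H", "H", comp_ms = 600)
  for (m in list(model_spec("weighting", "no_decay", "flat"),
                 model_spec("weighting", "no_decay", "double"))) {
    pars <- observer_params(
      b_H = 0.1, b_L = 0.1, sigma_H = 0.2, sigma_L = 0.2, w_H = 0.5,
      lambda = 0.1, kappa = if (m$prior != "flat") 0.3
    )
    priors <- build_priors(build_schedule_exp3(1), m$prior,
                           kappa = pars$kappa)
    p <- choice_probability(tr, m, pars, priors)$p_second_longer
    expect_equal(p, 0.5, tolerance = 1e-9)
  }
})

test_that("choice probability increases with the second duration", {
  curve <- one_trial("H", "L")[rep(1, 26), ]
  curve$comp_duration_ms <- duration_grid()
  mod <- model_spec("weighting", "no_decay", "flat")
  pars <- observer_params(b_H = 0.1, b_L = -0.1, lambda = 0.02)
  p <- choice_probability(curve, mod, pars)$p_second_longer
  expect_true(all(diff(p) > 0))

  modd <- model_spec("weighting", "decay", "double")
  parsd <- rep_params(modd)
  pd <- choice_probability(curve, modd, parsd,
                           build_priors(build_schedule_exp3(1), "double",
                                        kappa = 0.3))$p_second_longer
  expect_true(all(diff(pd) > 0))
})

test_that("optimal integration equals weighting at the optimal weight", {
  s3 <- build_schedule_exp3(1)
  cells <- dplyr::distinct(s3, condition, .keep_all = TRUE)
  grid <- expand.grid(sH = c(0.15, 0.25), sL = c(0.2, 0.3),
                      prior = c("flat", "double"),
                      stringsAsFactors = FALSE)
  for (i in seq_len(nrow(grid))) {
    sH <- grid$sH[i]
    sL <- grid$sL[i]
    hyp <- grid$prior[i]
    kap <- if (hyp == "flat") NULL else 0.3
    pr <- build_priors(s3, hyp, kappa = kap)
    w_star <- sL^2 / (sH^2 + sL^2)
    base <- list(b_H = 0.2, b_L = -0.15, sigma_H = sH, sigma_L = sL,
                 m = 1.4, lambda = 0.03, kappa = kap)
    p_w <- choice_probability(
      cells, model_spec("weighting", "decay", hyp),
      do.call(observer_params, c(base, list(w_H = w_star))), pr
    )$p_second_longer
    p_o <- choice_probability(
      cells, model_spec("optimal_integration", "decay", hyp),
      do.call(observer_params, base), pr
    )$p_second_longer
    expect_lt(max(abs(p_w - p_o)), 1e-8)
  }
})

test_that("selection on HL mixes the element-conditional probabilities", {
  s3 <- build_schedule_exp3(1)
  pr <- build_priors(s3, "double", kappa = 0.3)
  tr <- one_trial("HL", "HL", comp_ms = 740)
  c_H <- 0.65
  pars <- observer_params(b_H = 0.2, b_L = -0.2, sigma_H = 0.2,
                          sigma_L = 0.24, c_H = c_H, m = 1.5,
                          lambda = 0, kappa = 0.3)
  mod <- model_spec("selection", "decay", "double")
  p_mix <- choice_probability(tr, mod, pars, pr)$p_second_longer

  # manual enumeration of the four selected-element branches:
  # a selected H element behaves exactly like a single H stimulus
  single <- function(t1, t2) {
    trb <- one_trial(t1, t2, comp_ms = 740)
    choice_probability(trb, model_spec("weighting", "decay", "double"),
                       observer_params(b_H = 0.2, b_L = -0.2, sigma_H = 0.2,
                                       sigma_L = 0.24, w_H = 1, m = 1.5,
                                       lambda = 0, kappa = 0.3),
                       pr)$p_second_longer
  }
  p_HH <- single("H", "H")
  p_HL <- single("H", "L")
  p_LH <- single("L", "H")
  p_LL <- single("L", "L")
  manual <- c_H^2 * p_HH + c_H * (1 - c_H) * (p_HL + p_LH) +
    (1 - c_H)^2 * p_LL
  expect_equal(p_mix, manual, tolerance = 1e-8)
})

test_that("choice probabilities agree with generative simulation", {
  # spot check; the broad grid lives in the acceptance suite
  s3 <- build_schedule_exp3(1)
  mod <- model_spec("selection", "decay", "single")
  pars <- rep_params(mod)
  pr <- build_priors(s3, "single", kappa = 0.3)
  tr <- one_trial("HL", "H", order = "c-r", comp_ms = 500)
  p <- choice_probability(tr, mod, pars, pr)$p_second_longer
  nrep <- 20000
  sim <- simulate_responses(tr[rep(1, nrep), ], mod, pars, seed = 77,
                            priors = pr)
  phat <- mean(sim$response == "second_longer")
  se <- sqrt(p * (1 - p) / nrep)
  expect_lt(abs(p - phat), 3.5 * se)
})
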