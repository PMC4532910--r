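test_that("simulation is deterministic and preserves the schedule", {
  s <- build_schedule_exp2(1)
  mod <- model_spec("weighting", "no_decay", "flat")
  pars <- observer_params(b_H = 0.2, b_L = -0.2, sigma_H = 0.2,
                          sigma_L = 0.24, w_H = 0.6, lambda = 0.02)
  a <- simulate_responses(s, mod, pars, seed = 4)
  b <- simulate_responses(s, mod, pars, seed = 4)
  c <- simulate_responses(s, mod, pars, seed = 5)
  expect_identical(a, b)
  expect_false(identical(a$response, c$response))
  expect_identical(a[names(s)] |> dplyr::select(-response),
                   s |> dplyr::select(-response))
  expect_true(all(a$response %in% c("second_longer", "second_shorter")))
})

test_that("a pure-lapse observer responds at chance", {
  s <- build_schedule_exp3(1)
  mod <- model_spec("weighting", "no_decay", "flat")
  pars <- observer_params(b_H = 0.3, b_L = -0.3, w_H = 0.5, lambda = 1)
  sim <- simulate_responses(s, mod, pars, seed = 8)
  rate <- mean(sim$response == "second_longer")
  expect_lt(abs(rate - 0.5), 3 * sqrt(0.25 / nrow(s)))
})

test_that("a fully symmetric trial is judged at chance", {
  tr <- one_trial("H", "H", comp_ms = 600)[rep(1, 4000), ]
  mod <- model_spec("weighting", "no_decay", "flat")
  pars <- observer_params(b_H = 0.1, b_L = 0.1, sigma_H = 0.2,
                          sigma_L = 0.2, w_H = 0.5, lambda = 0)
  sim <- simulate_responses(tr, mod, pars, seed = 2)
  rate <- mean(sim$response == "second_longer")
  expect_lt(abs(rate - 0.5), 3 * sqrt(0.25 / nrow(tr)))
})

test_that("flat-prior equal-variance response rates match the closed form", {
  delta <- 0.2
  sg <- 0.2
  tr <- one_trial("H", "H", comp_ms = 600 * exp(delta))[rep(1, 20000), ]
  mod <- model_spec("weighting", "no_decay", "flat")
  pars <- observer_params(sigma_H = sg, lambda = 0)
  sim <- simulate_responses(tr, mod, pars, seed = 3)
  p_true <- pnorm(delta / (sg * sqrt(2)))
  rate <- mean(sim$response == "second_longer")
  expect_lt(abs(rate - p_true), 3 * sqrt(p_true * (1 - p_true) / nrow(tr)))
})

test_that("simulated rates converge to the quadrature choice probability", {
  s3 <- build_schedule_exp3(1)
  nrep <- 20000
  cases <- list(
    list(model_spec("weighting", "decay", "double"), "HL", "H", "r-c", 460),
    list(model_spec("optimal_integration", "decay", "single"),
         "L", "HL", "c-r", 700),
    list(model_spec("reliable_stimulus", "no_decay", "double"),
         "HL", "HL", "r-c", 860)
  )
  for (cs in cases) {
    mod <- cs[[1]]
    pars <- rep_params(mod)
    pr <- build_priors(s3, mod$prior, kappa = pars$kappa)
    tr <- one_trial(cs[[2]], cs[[3]], order = cs[[4]], comp_ms = cs[[5]])
    p <- choice_probability(tr, mod, pars, pr)$p_second_longer
    sim <- simulate_responses(tr[rep(1, nrep), ], mod, pars, seed = 11,
                              priors = pr)
    phat <- mean(sim$response == "second_longer")
    expect_lt(abs(p - phat), 3 * sqrt(p * (1 - p) / nrep))
  }
})

test_that("parameters inconsistent with the model are rejected", {
  s <- head(build_schedule_exp2(1), 20)
  expect_error(
    simulate_responses(s, model_spec("selection", "no_decay", "flat"),
                       observer_params(w_H = 0.5, c_H = 0.5), seed = 1),
    "not part of"
  )
  expect_error(
    simulate_responses(s, model_spec("weighting", "decay", "flat"),
                       observer_params(w_H = 0.5), seed = 1),
    "requires parameter 'm'"
  )
})
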