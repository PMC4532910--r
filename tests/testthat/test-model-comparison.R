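test_that("stratified folds are balanced within and across cells", {
  s3 <- build_schedule_exp3(1)
  folds <- make_folds(s3, 12, seed = 3)
  expect_equal(as.integer(table(folds)), rep(133L, 12))
  cell <- paste(s3$condition, s3$order)
  per_cell <- tapply(folds, cell, function(f) {
    diff(range(table(factor(f, levels = 1:12))))
  })
  expect_true(all(per_cell <= 1))
  # every fold sees every condition
  expect_true(all(table(s3$condition, folds) >= floor(228 / 12)))
  expect_identical(folds, make_folds(s3, 12, seed = 3))
  expect_false(identical(folds, make_folds(s3, 12, seed = 4)))
  expect_error(make_folds(head(s3, 5), 12), "more folds")
})

test_that("frozen-parameter cross-validation matches its analytic value", {
  # all parameters frozen at truth: CVLL estimates n * E[log p]
  s <- build_schedule_exp2(2)
  mod <- model_spec("weighting", "no_decay", "flat")
  pars <- observer_params(b_H = 0.25, b_L = -0.25, sigma_H = 0.2,
                          sigma_L = 0.24, w_H = 0.6, lambda = 0.04)
  sim <- simulate_responses(s, mod, pars, seed = 31)
  p <- choice_probability(s, mod, pars)$p_second_longer
  expected_ll <- sum(p * log(p) + (1 - p) * log(1 - p))
  sd_ll <- sqrt(sum(p * (1 - p) * (log(p / (1 - p)))^2))

  folds <- make_folds(sim, 12, seed = 1)
  total <- sum(vapply(1:12, function(f) {
    fit <- structure(list(model = mod, params = pars), class = "observer_fit")
    score_loglik(fit, sim[folds == f, ], schedule = sim)
  }, numeric(1)))
  expect_lt(abs(total - expected_ll), 4 * sd_ll)
  expect_true(total <= 0)
})

test_that("cross-validation partitions trials and is seed-stable", {
  s <- head(build_schedule_exp2(1), 444)
  mod <- model_spec("weighting", "no_decay", "flat")
  pars <- observer_params(b_H = 0.25, b_L = -0.25, sigma_H = 0.2,
                          sigma_L = 0.24, w_H = 0.6, lambda = 0.04)
  sim <- simulate_responses(s, mod, pars, seed = 13)
  cv <- do.call(cross_validate,
                c(list(sim, mod, n_folds = 6, seed = 2), fast_cv_opts))
  expect_s3_class(cv, "cv_result")
  expect_equal(length(cv$fold_loglik), 6)
  expect_true(all(cv$fold_loglik <= 0))
  expect_equal(cv$total_cvll, sum(cv$fold_loglik))
  expect_equal(sort(unique(cv$folds)), 1:6)

  cv2 <- do.call(cross_validate,
                 c(list(sim, mod, n_folds = 6, seed = 2), fast_cv_opts))
  expect_equal(cv$total_cvll, cv2$total_cvll)
  td <- tidy(cv)
  expect_equal(nrow(td), 6)
  expect_equal(sum(td$n_test), nrow(sim))
})

test_that("refitting from a returned optimum does not improve it", {
  s <- build_schedule_exp2(3)
  mod <- model_spec("weighting", "no_decay", "flat")
  pars <- observer_params(b_H = 0.2, b_L = -0.2, sigma_H = 0.2,
                          sigma_L = 0.24, w_H = 0.7, lambda = 0.05)
  sim <- simulate_responses(s, mod, pars, seed = 17)
  fit <- fit_model(sim, mod, restarts = 2, seed = 1)
  refit <- fit_model(sim, mod, restarts = 1, seed = 2, init = fit$theta)
  expect_lt(abs(refit$log_likelihood - fit$log_likelihood), 1e-4)
})

test_that("a coin-flip dataset drives the lapse rate to its bound", {
  s <- build_schedule_exp2(4)
  sim <- s
  set.seed(99)
  sim$response <- sample(c("second_longer", "second_shorter"), nrow(s),
                         replace = TRUE)
  mod <- model_spec("weighting", "no_decay", "flat")
  fit <- fit_model(sim, mod, restarts = 2, seed = 1)
  expect_gt(fit$params$lambda, 0.45)
  expect_lt(abs(fit$log_likelihood - nrow(s) * log(0.5)), 6)
})

test_that("model comparison tables rank models and guard fold mismatch", {
  s <- head(build_schedule_exp2(1), 444)
  mod1 <- model_spec("weighting", "no_decay", "flat")
  mod2 <- model_spec("selection", "no_decay", "flat")
  pars <- observer_params(b_H = 0.3, b_L = -0.3, sigma_H = 0.2,
                          sigma_L = 0.24, w_H = 0.7, lambda = 0.03)
  sim <- simulate_responses(s, mod1, pars, seed = 23)
  folds <- make_folds(sim, 4, seed = 1)
  cv1 <- do.call(cross_validate,
                 c(list(sim, mod1, folds = folds, seed = 1), fast_cv_opts))
  cv2 <- do.call(cross_validate,
                 c(list(sim, mod2, folds = folds, seed = 1), fast_cv_opts))
  cmp <- compare_models(list(cv1, cv2))
  expect_equal(nrow(cmp), 2)
  expect_equal(max(cmp$delta_cvll), 0)
  expect_equal(cmp$delta_cvll[1], 0)

  cv_bad <- cv2
  cv_bad$folds <- rev(cv_bad$folds)
  expect_error(compare_models(list(cv1, cv_bad)), "fold assignments")

  # group-level comparison over synthetic CVLL draws: Holm-adjusted paired
  # tests against the group-best model
  fake <- function(id, lls, folds) {
    purrr::map2(id, lls, function(i, ll) {
      structure(list(model_id = i, folds = folds, total_cvll = ll,
                     fold_loglik = rep(ll / 4, 4)),
                class = "cv_result")
    })
  }
  set.seed(7)
  group <- purrr::map(1:8, function(d) {
    fake(c("A", "B", "C"),
         c(-100 + rnorm(1), -103 + rnorm(1), -115 + rnorm(1)), folds)
  })
  gc <- compare_models(group)
  expect_equal(gc$model_id[1], "A")
  expect_true(gc$best[gc$model_id == "A"])
  expect_equal(gc$mean_delta_cvll[gc$model_id == "A"], 0)
  expect_true(gc$significant[gc$model_id == "C"])
  expect_true(all(diff(gc$mean_cvll) <= 0))
})
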