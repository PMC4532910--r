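# Shared fixtures: a representative observer anchored to the study's
# headline values (HL weight 0.70 against an optimal weight near 0.5,
# i.e. near-equal element SDs, with moderate decay and prior smoothing),
# plus reduced designs used by the heavier simulation studies.

rep_params <- function(model = model_spec("weighting", "decay", "double")) {
  keep <- list(
    b_H = 0.2, b_L = -0.2, sigma_H = 0.2, sigma_L = 0.21,
    w_H = if (model$combination == "weighting") 0.7,
    c_H = if (model$combination == "selection") 0.7,
    m = if (model$decay == "decay") 1.5,
    lambda = 0.05,
    kappa = if (model$prior != "flat") 0.3
  )
  do.call(observer_params, purrr::compact(keep))
}

# one-row trial table (off-grid durations allowed: choice probabilities do
# not enforce the schedule grid)
one_trial <- function(ref_type = "H", comp_type = "H", order = "r-c",
                      comp_ms = 600, condition = paste0(comp_type, "vs",
                                                        ref_type)) {
  tibble::tibble(
    experiment_id = "t", condition = condition, ref_type = ref_type,
    comp_type = comp_type, order = order, ref_duration_ms = 600,
    comp_duration_ms = comp_ms, response = NA_character_
  )
}

# Reduced two-order design for the model-recovery study: three conditions
# (H vs L and both single-vs-HL pairings), both display orders, 13 of the
# 26 duration levels with Gaussian-shaped incidence, 1680 trials
# (the full-experiment scale). Choice-probability cost scales with unique
# cells rather than trials, so trials per cell are multiplied up relative
# to the printed schedule to reach the full-experiment trial count at a
# fraction of the cost.
recovery_schedule <- function() {
  inc <- 4L * c(2L, 4L, 4L, 6L, 8L, 8L, 8L, 8L, 6L, 6L, 4L, 4L, 2L)
  durs <- duration_grid()[seq(1, 26, by = 2)]
  blk <- function(cond, rt, ct, ord) {
    tibble::tibble(
      experiment_id = "recovery", condition = cond, ref_type = rt,
      comp_type = ct, order = ord, ref_duration_ms = 600,
      comp_duration_ms = rep(durs, times = inc), response = NA_character_
    )
  }
  dplyr::bind_rows(
    blk("HvsL", "L", "H", "r-c"), blk("HvsL", "L", "H", "c-r"),
    blk("HvsHL", "HL", "H", "r-c"), blk("HvsHL", "HL", "H", "c-r"),
    blk("LvsHL", "HL", "L", "r-c"), blk("LvsHL", "HL", "L", "c-r")
  )
}

# Bernoulli responses drawn directly from the psychometric function
# (independent of the observer-model machinery).
simulate_psychometric <- function(schedule, b, sigma, lambda = 0, seed = 1) {
  set.seed(seed)
  p_comp_longer <- psychometric_prob(log(schedule$comp_duration_ms),
                                     b, sigma, lambda)
  comp_longer <- stats::runif(nrow(schedule)) < p_comp_longer
  second_longer <- ifelse(schedule$order == "r-c", comp_longer, !comp_longer)
  out <- schedule
  out$response <- ifelse(second_longer, "second_longer", "second_shorter")
  out
}

fast_cv_opts <- list(restarts = 1L, maxit = 60L, factr = 1e9,
                     fold_maxit = 10L, fold_factr = 1e10)
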