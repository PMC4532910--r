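#' Simulate observer responses for a schedule
#'
#' Draws sensory measurements from the generative model of each trial
#' (first-interval SDs inflated by `m` under the decay assumption), runs the
#' model's inference rule to a decision about which interval was longer,
#' and with probability `lambda` replaces the decision by a fair coin flip.
#' Deterministic given `seed`.
#'
#' @param schedule A schedule tibble (responses may be missing).
#' @param model [model_spec()].
#' @param params [observer_params()]; must carry exactly the parameters the
#'   model uses (e.g. `w_H` only for the weighting rule), otherwise the call
#'   is rejected.
#' @param seed Integer seed.
#' @param priors Optional [build_priors()] object; built from `schedule`
#'   when missing.
#' @return The schedule with `response` filled
#'   (`"second_longer"`/`"second_shorter"`).
#' @export
#' @examples
#' sched <- build_schedule_exp1(1)
#' pars <- observer_params(b_H = 0.2, b_L = -0.2, lambda = 0.02)
#' mod <- model_spec("weighting", "no_decay", "flat")
#' table(simulate_responses(sched, mod, pars, seed = 2)$response)
simulate_responses <- function(schedule, model, params, seed = 1L,
                               priors = NULL) {
  has_HL <- any(c(schedule$ref_type, schedule$comp_type) == "HL")
  validate_params(params, model, has_HL = has_HL)
  if (is.null(priors)) {
    priors <- build_priors(schedule, model$prior, kappa = params$kappa)
  }
  n <- nrow(schedule)
  first_type <- ifelse(schedule$order == "r-c", schedule$ref_type,
                       schedule$comp_type)
  second_type <- ifelse(schedule$order == "r-c", schedule$comp_type,
                        schedule$ref_type)
  t1 <- ifelse(schedule$order == "r-c", log_ms(REF_MS),
               log_ms(schedule$comp_duration_ms))
  t2 <- ifelse(schedule$order == "r-c", log_ms(schedule$comp_duration_ms),
               log_ms(REF_MS))

  with_seed(seed, {
    draw_interval <- function(types, t_true, position) {
      s <- decay_scale(model, params, position)
      x <- numeric(n)
      v <- numeric(n)
      for (ty in unique(types)) {
        idx <- which(types == ty)
        if (ty == "HL") {
          x_H <- rnorm(length(idx), t_true[idx] + params$b_H,
                       params$sigma_H * s)
          x_L <- rnorm(length(idx), t_true[idx] + params$b_L,
                       params$sigma_L * s)
          red <- switch(model$combination,
            weighting = {
              w <- params$w_H
              list(x = combine_weighting(x_H, x_L, w),
                   sd = sqrt(w^2 * params$sigma_H^2 +
                             (1 - w)^2 * params$sigma_L^2) * s)
            },
            optimal_integration = {
              w <- optimal_w_H(params$sigma_H, params$sigma_L)
              list(x = combine_weighting(x_H, x_L, w),
                   sd = predict_sd_optimal(params$sigma_H, params$sigma_L) * s)
            },
            selection = {
              pick_H <- runif(length(idx)) < params$c_H
              list(x = ifelse(pick_H, x_H, x_L),
                   sd = ifelse(pick_H, params$sigma_H, params$sigma_L) * s)
            },
            reliable_stimulus = {
              if (params$sigma_H <= params$sigma_L) {
                list(x = x_H, sd = rep(params$sigma_H * s, length(idx)))
              } else {
                list(x = x_L, sd = rep(params$sigma_L * s, length(idx)))
              }
            }
          )
          x[idx] <- red$x
          v[idx] <- red$sd^2
        } else {
          b <- if (ty == "H") params$b_H else params$b_L
          sd <- (if (ty == "H") params$sigma_H else params$sigma_L) * s
          x[idx] <- rnorm(length(idx), t_true[idx] + b, sd)
          v[idx] <- sd^2
        }
      }
      list(x = x, v = v)
    }

    i1 <- draw_interval(first_type, t1, "first")
    i2 <- draw_interval(second_type, t2, "second")
    dec <- posterior_decision_prob(i1$x, i2$x, i1$v, i2$v, priors)
    # ties in the decision posterior count as "second longer"
    second_longer <- dec$p_D1 >= dec$p_D0
    lapse <- runif(n) < params$lambda
    guess <- runif(n) < 0.5
    second_longer[lapse] <- guess[lapse]
    out <- schedule
    out$response <- ifelse(second_longer, "second_longer", "second_shorter")
    out
  })
}
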