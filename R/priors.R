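new_belief <- function(weight, mean, variance) {
  stopifnot(length(weight) == length(mean), length(mean) == length(variance),
            all(weight >= 0), all(variance > 0))
  tibble::tibble(weight = weight / sum(weight), mean = mean,
                 variance = variance)
}

#' Build the observer's prior beliefs from a schedule
#'
#' Constructs the duration priors an observer is assumed to have learned
#' over the course of the experiment, smoothed by a Gaussian kernel of SD
#' `kappa` on log duration. The reference prior `p_r` is the kernel centred
#' at log 600 ms; the comparison prior `p_c` is a mixture with one component
#' per comparison duration, weighted by its incidence in the schedule.
#'
#' * `"flat"`: an improper uniform on the log-duration line; posteriors
#'   equal likelihoods and no mixture is built.
#' * `"single"`: one pooled belief, the equal mixture of `p_r` and `p_c`,
#'   applied to both intervals.
#' * `"double"`: `p_r` and `p_c` kept separate; at decision time the
#'   observer marginalizes over the unknown display order.
#'
#' @param schedule A schedule tibble (see [build_schedule_exp1()]); only the
#'   comparison-duration incidence is used.
#' @param prior_hypothesis `"flat"`, `"single"` or `"double"`.
#' @param kappa Kernel SD in log-duration units (> 0; ignored for flat).
#' @return An object of class `duration_prior` with elements `hypothesis`,
#'   `kappa`, and (non-flat only) mixtures `p_r`, `p_c`, `pooled`, each a
#'   tibble with columns `weight`, `mean`, `variance`.
#' @export
#' @examples
#' pr <- build_priors(build_schedule_exp3(1), "double", kappa = 0.3)
#' nrow(pr$p_c)
build_priors <- function(schedule,
                         prior_hypothesis = c("flat", "single", "double"),
                         kappa = NULL) {
  prior_hypothesis <- match.arg(prior_hypothesis)
  if (prior_hypothesis == "flat") {
    return(structure(list(hypothesis = "flat", kappa = NULL),
                     class = "duration_prior"))
  }
  if (is.null(kappa) || kappa <= 0) {
    abort("non-flat priors need kappa > 0")
  }
  if (nrow(schedule) == 0) abort("empty schedule: cannot build priors")
  counts <- dplyr::count(schedule, .data$comp_duration_ms)
  p_c <- new_belief(counts$n, log_ms(counts$comp_duration_ms),
                    rep(kappa^2, nrow(counts)))
  p_r <- new_belief(1, log_ms(REF_MS), kappa^2)
  pooled <- new_belief(
    c(0.5 * p_r$weight, 0.5 * p_c$weight),
    c(p_r$mean, p_c$mean),
    c(p_r$variance, p_c$variance)
  )
  structure(
    list(hypothesis = prior_hypothesis, kappa = kappa,
         p_r = p_r, p_c = p_c, pooled = pooled),
    class = "duration_prior"
  )
}

#' @export
print.duration_prior <- function(x, ...) {
  cat("<duration_prior>", x$hypothesis,
      if (!is.null(x$kappa)) sprintf("(kappa = %.3g)", x$kappa), "\n")
  invisible(x)
}

belief_mean <- function(belief) sum(belief$weight * belief$mean)

#' Observer likelihood of duration given the sensory measurement(s)
#'
#' Returns the likelihood function over the (log) duration of one interval
#' implied by its measurement(s), as a single Gaussian component. The
#' measurement biases are not subtracted: they are assumed inaccessible to
#' the observer at the inference stage. For an HL stimulus the combination
#' rule of the model decides how the two element measurements collapse to
#' one Gaussian; under decay the likelihood SD of a first-interval stimulus
#' is inflated by `m`, mirroring the generative SD.
#'
#' @param stim_type `"H"`, `"L"` or `"HL"`.
#' @param measurements Named numeric: `x_H` and/or `x_L` as appropriate.
#' @param model [model_spec()].
#' @param params [observer_params()].
#' @param position `"first"` or `"second"`.
#' @param selected_element For the selection rule on HL stimuli, which
#'   element (`"H"` or `"L"`) the observer attended on this trial.
#' @return A one-row belief tibble (columns `weight`, `mean`, `variance`).
#' @export
likelihood_of_duration <- function(stim_type, measurements, model, params,
                                   position = c("second", "first"),
                                   selected_element = NULL) {
  position <- match.arg(position)
  stim_type <- match.arg(stim_type, c("H", "L", "HL"))
  s <- decay_scale(model, params, position)
  one <- function(mean, sd) new_belief(1, mean, (sd * s)^2)
  if (stim_type == "H") return(one(measurements[["x_H"]], params$sigma_H))
  if (stim_type == "L") return(one(measurements[["x_L"]], params$sigma_L))
  x_H <- measurements[["x_H"]]
  x_L <- measurements[["x_L"]]
  switch(model$combination,
    weighting = {
      w <- params$w_H
      one(combine_weighting(x_H, x_L, w),
          sqrt(w^2 * params$sigma_H^2 + (1 - w)^2 * params$sigma_L^2))
    },
    optimal_integration = {
      w <- optimal_w_H(params$sigma_H, params$sigma_L)
      one(combine_weighting(x_H, x_L, w),
          predict_sd_optimal(params$sigma_H, params$sigma_L))
    },
    selection = {
      if (is.null(selected_element)) {
        abort("selection rule on an HL stimulus needs `selected_element`")
      }
      if (selected_element == "H") one(x_H, params$sigma_H)
      else one(x_L, params$sigma_L)
    },
    reliable_stimulus = {
      # tie sigma_H == sigma_L resolves toward H for determinism
      if (params$sigma_H <= params$sigma_L) one(x_H, params$sigma_H)
      else one(x_L, params$sigma_L)
    }
  )
}

# Mixture-prior decision probability p(D = 1) = P(t2 > t1 | x1, x2) with
# priors P1 on t1 and P2 on t2. Vectorized over x1, x2, v1, v2. All prior
# components share variance kappa^2, so posterior component variances are
# constant within an interval.
pD1_assignment <- function(x1, v1, x2, v2, P1, P2) {
  post <- function(x, v, P) {
    K <- nrow(P)
    n <- length(x)
    lw <- matrix(0, n, K)
    mu <- matrix(0, n, K)
    V <- matrix(0, n, K)
    for (k in seq_len(K)) {
      denom_k <- P$variance[k] + v  # vector over trials
      lw[, k] <- log(P$weight[k]) - (x - P$mean[k])^2 / (2 * denom_k) -
        0.5 * log(denom_k)
      a <- P$variance[k] / denom_k
      mu[, k] <- a * x + (1 - a) * P$mean[k]
      V[, k] <- P$variance[k] * v / denom_k
    }
    m <- apply(lw, 1, max)
    w <- exp(lw - m)
    w <- w / rowSums(w)
    list(w = w, mu = mu, V = V)
  }
  p1 <- post(x1, v1, P1)
  p2 <- post(x2, v2, P2)
  out <- numeric(length(x1))
  for (k in seq_len(ncol(p1$w))) {
    for (l in seq_len(ncol(p2$w))) {
      sd_kl <- sqrt(p1$V[, k] + p2$V[, l])
      out <- out + p1$w[, k] * p2$w[, l] *
        pnorm((p2$mu[, l] - p1$mu[, k]) / sd_kl)
    }
  }
  out
}

#' Posterior probability of the decision variable
#'
#' Given the scalar measurement statistics of the two intervals and their
#' likelihood variances, returns the observer's posterior probability that
#' the first duration exceeded the second (`p_D0`) and its complement
#' (`p_D1`). Under a flat prior the posteriors equal the likelihoods; under
#' the single prior both intervals share the pooled mixture prior; under
#' double priors the order-conditional probabilities computed with the
#' (reference, comparison) and (comparison, reference) assignments are
#' averaged, the observer not knowing the display order.
#'
#' @param x1,x2 Measurement statistics of the first and second interval
#'   (log duration; vectorized).
#' @param v1,v2 Likelihood variances of the two intervals (recycled).
#' @param priors A [build_priors()] object.
#' @return A tibble with columns `p_D0` and `p_D1` (rows follow `x1`).
#' @export
posterior_decision_prob <- function(x1, x2, v1, v2, priors) {
  stopifnot(inherits(priors, "duration_prior"), all(v1 > 0), all(v2 > 0))
  n <- length(x1)
  v1 <- rep_len(v1, n)
  v2 <- rep_len(v2, n)
  p_D1 <- switch(priors$hypothesis,
    flat = pnorm((x2 - x1) / sqrt(v1 + v2)),
    single = pD1_assignment(x1, v1, x2, v2, priors$pooled, priors$pooled),
    double = 0.5 * (
      pD1_assignment(x1, v1, x2, v2, priors$p_c, priors$p_r) +
      pD1_assignment(x1, v1, x2, v2, priors$p_r, priors$p_c)
    )
  )
  tibble::tibble(p_D0 = 1 - p_D1, p_D1 = p_D1)
}
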