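COMBINATION_RULES <- c("weighting", "optimal_integration", "selection",
                       "reliable_stimulus")
DECAY_LEVELS <- c("decay", "no_decay")
PRIOR_LEVELS <- c("flat", "single", "double")

#' Specify one observer model
#'
#' An observer model is one cell of the 4 x 2 x 3 factorial space crossing
#' the cue-combination rule for HL stimuli, the memory-decay assumption for
#' the first interval, and the prior structure assumed over durations.
#'
#' @param combination One of `"weighting"`, `"optimal_integration"`,
#'   `"selection"`, `"reliable_stimulus"`.
#' @param decay `"decay"` (first-interval measurement and likelihood SDs
#'   scaled by `m`) or `"no_decay"`.
#' @param prior `"flat"` (improper uniform on log duration), `"single"`
#'   (one pooled learned mixture prior) or `"double"` (separate reference
#'   and comparison priors with marginalization over display order).
#' @return An object of class `model_spec`.
#' @export
#' @examples
#' model_spec("weighting", "decay", "double")
model_spec <- function(combination, decay, prior) {
  combination <- match.arg(combination, COMBINATION_RULES)
  decay <- match.arg(decay, DECAY_LEVELS)
  prior <- match.arg(prior, PRIOR_LEVELS)
  structure(
    list(combination = combination, decay = decay, prior = prior),
    class = "model_spec"
  )
}

#' @export
format.model_spec <- function(x, ...) {
  paste(x$combination, x$decay, x$prior, sep = "/")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", format(x), "\n")
  invisible(x)
}

#' Enumerate the factorial model space
#'
#' @return A tibble with 24 rows and columns `model_id`, `combination`,
#'   `decay`, `prior`, and a list-column `spec` of [model_spec()] objects,
#'   in a fixed deterministic order.
#' @export
#' @examples
#' enumerate_models()
enumerate_models <- function() {
  grid <- tidyr::expand_grid(
    combination = COMBINATION_RULES,
    decay = DECAY_LEVELS,
    prior = PRIOR_LEVELS
  )
  grid %>%
    dplyr::mutate(
      model_id = paste(.data$combination, .data$decay, .data$prior, sep = "/"),
      spec = purrr::pmap(
        list(.data$combination, .data$decay, .data$prior), model_spec
      )
    ) %>%
    dplyr::select("model_id", "combination", "decay", "prior", "spec")
}

#' Observer parameters
#'
#' The generative/inference parameter vector of an observer model.
#' All durations and SDs are on the natural-log duration scale.
#'
#' @param b_H,b_L Measurement biases of H and L stimuli (log units).
#' @param sigma_H,sigma_L Measurement SDs of H and L stimuli (> 0).
#' @param w_H Weight given to the H element under the weighting rule
#'   (in `[0, 1]`; only meaningful for `combination = "weighting"`).
#' @param c_H Probability of attending the H element under the selection
#'   rule (in `[0, 1]`; only meaningful for `combination = "selection"`).
#' @param m Memory-decay factor applied to the first interval's SD
#'   (>= 1; only meaningful for `decay = "decay"`).
#' @param lambda Lapse rate: probability of a random guess (in `[0, 0.5]`).
#' @param kappa SD of the Gaussian kernel smoothing the learned prior(s)
#'   (> 0; only meaningful for non-flat priors).
#' @return An object of class `observer_params` (a named list).
#' @export
#' @examples
#' observer_params(b_H = 0.2, b_L = -0.2, sigma_H = 0.2, sigma_L = 0.24,
#'                 w_H = 0.7, m = 1.5, lambda = 0.05, kappa = 0.3)
observer_params <- function(b_H = 0, b_L = 0, sigma_H = 0.2, sigma_L = 0.24,
                            w_H = NULL, c_H = NULL, m = NULL,
                            lambda = 0, kappa = NULL) {
  stopifnot(sigma_H > 0, sigma_L > 0, lambda >= 0, lambda <= 1)
  if (!is.null(w_H)) stopifnot(w_H >= 0, w_H <= 1)
  if (!is.null(c_H)) stopifnot(c_H >= 0, c_H <= 1)
  if (!is.null(m)) stopifnot(m >= 1)
  if (!is.null(kappa)) stopifnot(kappa > 0)
  structure(
    list(b_H = b_H, b_L = b_L, sigma_H = sigma_H, sigma_L = sigma_L,
         w_H = w_H, c_H = c_H, m = m, lambda = lambda, kappa = kappa),
    class = "observer_params"
  )
}

#' @export
print.observer_params <- function(x, ...) {
  vals <- purrr::imap(unclass(x), function(v, nm) {
    if (is.null(v)) NULL else sprintf("%s = %.4g", nm, v)
  })
  cat("<observer_params>", paste(unlist(vals), collapse = ", "), "\n")
  invisible(x)
}

# Check a parameter set against a model spec; irrelevant parameters must be
# absent (NULL) so that a mis-specified simulation fails loudly. w_H/c_H
# only matter when the data contain HL stimuli.
validate_params <- function(params, model, has_HL = TRUE) {
  stopifnot(inherits(params, "observer_params"), inherits(model, "model_spec"))
  allowed <- c(
    w_H = model$combination == "weighting",
    c_H = model$combination == "selection",
    m = model$decay == "decay",
    kappa = model$prior != "flat"
  )
  required <- allowed & c(w_H = has_HL, c_H = has_HL, m = TRUE, kappa = TRUE)
  for (nm in names(allowed)) {
    have <- !is.null(params[[nm]])
    if (required[[nm]] && !have) {
      abort(sprintf("model '%s' requires parameter '%s'", format(model), nm))
    }
    if (!allowed[[nm]] && have) {
      abort(sprintf(
        "parameter '%s' is not part of model '%s'; drop it or change the model",
        nm, format(model)
      ))
    }
  }
  invisible(params)
}

# Decay scale factor for a stimulus position.
decay_scale <- function(model, params, position) {
  if (model$decay == "decay" && position == "first") params$m else 1
}

#' Distribution of the sensory measurement(s) of one stimulus
#'
#' Returns the generative distribution of the noisy duration measurement(s)
#' produced by a stimulus of the given type: H and L stimuli yield one
#' Gaussian measurement on log duration, biased by the stimulus type; an HL
#' stimulus yields an independent pair, each element distributed exactly as
#' when shown alone. Under the decay assumption the first interval's SD is
#' inflated by `m`.
#'
#' @param stim_type `"H"`, `"L"` or `"HL"`.
#' @param t_log True log duration of the stimulus.
#' @param params [observer_params()].
#' @param position `"first"` or `"second"` interval of the trial.
#' @param model [model_spec()] supplying the decay assumption.
#' @return A tibble with one row per measurement channel and columns
#'   `element`, `mean`, `sd`.
#' @export
measurement_distribution <- function(stim_type, t_log, params,
                                     position = c("second", "first"),
                                     model = model_spec("weighting",
                                                        "no_decay", "flat")) {
  position <- match.arg(position)
  s <- decay_scale(model, params, position)
  stim_type <- match.arg(stim_type, c("H", "L", "HL"))
  rows <- switch(stim_type,
    H = tibble::tibble(element = "H", mean = t_log + params$b_H,
                       sd = params$sigma_H * s),
    L = tibble::tibble(element = "L", mean = t_log + params$b_L,
                       sd = params$sigma_L * s),
    HL = tibble::tibble(
      element = c("H", "L"),
      mean = t_log + c(params$b_H, params$b_L),
      sd = c(params$sigma_H, params$sigma_L) * s
    )
  )
  rows
}

#' Weighted combination of the two HL measurements
#'
#' The weighting rule forms a single duration estimate from the H- and
#' L-based measurements as `w_H * x_H + (1 - w_H) * x_L`.
#'
#' @param x_H,x_L Measurements based on the H and L elements (log duration).
#' @param w_H Weight of the H element, in `[0, 1]`.
#' @return The combined measurement (vectorized).
#' @export
combine_weighting <- function(x_H, x_L, w_H) {
  stopifnot(w_H >= 0, w_H <= 1)
  w_H * x_H + (1 - w_H) * x_L
}

#' SD of the optimally integrated duration estimate
#'
#' Under reliability-weighted (statistically optimal) integration the
#' combined estimate has SD `sigma_H * sigma_L / sqrt(sigma_H^2 + sigma_L^2)`,
#' strictly smaller than either element's SD.
#'
#' @param sigma_H,sigma_L Element SDs (> 0).
#' @return The integrated SD (vectorized).
#' @export
predict_sd_optimal <- function(sigma_H, sigma_L) {
  if (any(sigma_H <= 0) || any(sigma_L <= 0)) {
    abort("predict_sd_optimal() needs strictly positive SDs")
  }
  sigma_H * sigma_L / sqrt(sigma_H^2 + sigma_L^2)
}

# Optimal weight of the H element implied by the element SDs.
optimal_w_H <- function(sigma_H, sigma_L) {
  sigma_L^2 / (sigma_H^2 + sigma_L^2)
}

#' Across-trial mean and SD of the HL estimate under the selection rule
#'
#' With probability `c_H` the observer bases the HL duration estimate on the
#' H element, otherwise on the L element. Across trials the estimate is a
#' two-component mixture whose mean offset and SD are returned.
#'
#' @param c_H Probability of selecting the H element, in `[0, 1]`.
#' @param b_H,b_L Element biases (log units).
#' @param sigma_H,sigma_L Element SDs.
#' @return A tibble with columns `mean_offset` and `sd`.
#' @export
predict_mean_sd_selection <- function(c_H, b_H, b_L, sigma_H, sigma_L) {
  stopifnot(all(c_H >= 0), all(c_H <= 1))
  mu <- c_H * b_H + (1 - c_H) * b_L
  v <- c_H * sigma_H^2 + (1 - c_H) * sigma_L^2 +
    c_H * (1 - c_H) * (b_H - b_L)^2
  tibble::tibble(mean_offset = mu, sd = sqrt(v))
}
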