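# Free-parameter layout for one model: names, bounds, heuristic start.
param_layout <- function(model, lambda_max = 0.5) {
  nm <- c("b_H", "b_L", "sigma_H", "sigma_L")
  lo <- c(-1.5, -1.5, 0.05, 0.05)
  hi <- c(1.5, 1.5, 1.5, 1.5)
  st <- c(0.1, -0.1, 0.2, 0.25)
  if (model$combination == "weighting") {
    nm <- c(nm, "w_H"); lo <- c(lo, 0); hi <- c(hi, 1); st <- c(st, 0.5)
  }
  if (model$combination == "selection") {
    nm <- c(nm, "c_H"); lo <- c(lo, 0); hi <- c(hi, 1); st <- c(st, 0.5)
  }
  if (model$decay == "decay") {
    nm <- c(nm, "m"); lo <- c(lo, 1); hi <- c(hi, 3); st <- c(st, 1.3)
  }
  if (model$prior != "flat") {
    nm <- c(nm, "kappa"); lo <- c(lo, 0.05); hi <- c(hi, 2); st <- c(st, 0.4)
  }
  nm <- c(nm, "lambda"); lo <- c(lo, 0); hi <- c(hi, lambda_max)
  st <- c(st, 0.03)
  list(names = nm, lower = lo, upper = hi, start = st)
}

theta_to_params <- function(theta, layout, model) {
  v <- setNames(as.list(theta), layout$names)
  observer_params(
    b_H = v$b_H, b_L = v$b_L, sigma_H = v$sigma_H, sigma_L = v$sigma_L,
    w_H = v$w_H, c_H = v$c_H, m = v$m, lambda = v$lambda, kappa = v$kappa
  )
}

# Data-driven starting point: condition-wise psychometric fits give rough
# bias and noise estimates per stimulus type (method-of-moments flavour);
# remaining parameters start at neutral values. Falls back to NULL (the
# fixed heuristic start) if the quick psychometric fit fails.
init_from_data <- function(trials, model) {
  psych <- tryCatch(fit_psychometric(trials, restarts = 1L, seed = 1L),
                    error = function(e) NULL)
  if (is.null(psych)) return(NULL)
  tt <- tidy(psych)
  # per-condition bias ~ b_comp - b_ref; average the evidence for each type
  b_eq <- purrr::map(seq_len(nrow(tt)), function(i) {
    cond <- tt$condition[i]
    row <- trials[trials$condition == cond, ][1, ]
    c(comp = row$comp_type, ref = row$ref_type, b = tt$b[i],
      sigma = tt$sigma[i])
  })
  score <- c(H = 0, L = 0, HL = 0)
  nsc <- c(H = 0, L = 0, HL = 0)
  for (e in b_eq) {
    b <- as.numeric(e["b"])
    score[e["comp"]] <- score[e["comp"]] + b / 2
    nsc[e["comp"]] <- nsc[e["comp"]] + 0.5
    score[e["ref"]] <- score[e["ref"]] - b / 2
    nsc[e["ref"]] <- nsc[e["ref"]] + 0.5
  }
  bias <- ifelse(nsc > 0, score / pmax(nsc, 0.5), 0)
  sig <- stats::median(tt$sigma) / sqrt(2)
  out <- c(
    b_H = unname(bias["H"]), b_L = unname(bias["L"]),
    sigma_H = max(sig, 0.08), sigma_L = max(sig * 1.1, 0.08),
    w_H = 0.5, c_H = 0.5, m = 1.3, kappa = 0.4,
    lambda = min(max(psych$lambda, 0.01), 0.3)
  )
  out
}

# Collapse responded trials to unique cells with response counts.
response_cells <- function(trials) {
  trials %>%
    dplyr::filter(!is.na(.data$response)) %>%
    dplyr::count(.data$ref_type, .data$comp_type, .data$order,
                 .data$comp_duration_ms, .data$response) %>%
    tidyr::pivot_wider(names_from = "response", values_from = "n",
                       values_fill = 0L)
}

cells_loglik_ctx <- function(ctx, cells, model, params) {
  p_raw <- cp_context_eval(ctx, model, params)
  lam <- params$lambda
  p <- lam / 2 + (1 - lam) * p_raw
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  n_long <- if ("second_longer" %in% names(cells)) cells$second_longer else 0
  n_short <- if ("second_shorter" %in% names(cells)) {
    cells$second_shorter
  } else 0
  sum(n_long * log(p) + n_short * log(1 - p))
}

cells_loglik <- function(cells, model, params, schedule, gh_order = 7L) {
  ctx <- cp_context(cells, model, schedule, gh_order)
  cells_loglik_ctx(ctx, cells, model, params)
}

#' Fit one observer model by maximum likelihood
#'
#' Maximizes the summed log choice probability of the responded trials over
#' the model's free parameters (`b_H`, `b_L`, `sigma_H`, `sigma_L`,
#' `lambda`, plus `w_H`/`c_H` by combination rule, `m` under decay, `kappa`
#' under non-flat priors) by bounded quasi-Newton optimization with seeded
#' random restarts. Non-flat priors are rebuilt from the full schedule (the
#' observer's belief reflects the whole experiment), so they may be learned
#' even when `trials` is a training subset.
#'
#' @param trials Responded trials to fit.
#' @param model [model_spec()].
#' @param schedule Schedule defining the priors; defaults to `trials`.
#' @param restarts Number of optimizer starts (first is a fixed heuristic).
#' @param seed Seed for the restart draws.
#' @param init Optional named start vector (e.g. a previous fit's
#'   parameters) used instead of the heuristic first start.
#' @param gh_order Gauss-Hermite order for the choice probabilities.
#' @param maxit,factr `L-BFGS-B` control parameters.
#' @return An object of class `observer_fit` with elements `params`,
#'   `log_likelihood`, `model`, `convergence`, `theta`.
#' @export
fit_model <- function(trials, model, schedule = trials, restarts = 3L,
                      seed = 1L, init = NULL, gh_order = 7L,
                      maxit = 200L, factr = 1e8) {
  stopifnot(inherits(model, "model_spec"))
  cells <- response_cells(trials)
  if (nrow(cells) == 0) abort("no responded trials to fit")
  layout <- param_layout(model)
  ctx <- cp_context(cells, model, schedule, gh_order)

  n_long <- if ("second_longer" %in% names(cells)) cells$second_longer else 0
  n_short <- if ("second_shorter" %in% names(cells)) {
    cells$second_shorter
  } else 0
  lam_i <- length(layout$names)  # lambda is always last
  cache <- new.env(parent = emptyenv())
  nll <- function(theta) {
    params <- theta_to_params(theta, layout, model)
    key <- theta[-lam_i]
    # gradient steps on lambda alone reuse the cached choice probabilities
    if (!is.null(cache$key) && identical(cache$key, key)) {
      p_raw <- cache$p_raw
    } else {
      p_raw <- cp_context_eval(ctx, model, params)
      cache$key <- key
      cache$p_raw <- p_raw
    }
    p <- params$lambda / 2 + (1 - params$lambda) * p_raw
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(n_long * log(p) + n_short * log(1 - p))
  }

  start0 <- layout$start
  if (is.null(init)) {
    init <- init_from_data(trials, model)
  }
  if (!is.null(init)) {
    idx <- match(layout$names, names(init))
    start0[!is.na(idx)] <- unlist(init)[idx[!is.na(idx)]]
    start0 <- pmin(pmax(start0, layout$lower), layout$upper)
  }
  starts <- with_seed(seed, c(
    list(start0),
    purrr::map(seq_len(max(restarts - 1, 0)), function(i) {
      runif(length(layout$lower), layout$lower, layout$upper)
    })
  ))

  fits <- purrr::map(starts, function(s) {
    tryCatch(
      optim(s, nll, method = "L-BFGS-B",
            lower = layout$lower, upper = layout$upper,
            control = list(maxit = maxit, factr = factr)),
      error = function(e) NULL
    )
  })
  fits <- purrr::compact(fits)
  if (length(fits) == 0) abort("observer-model optimization failed")
  best <- fits[[which.min(purrr::map_dbl(fits, "value"))]]

  structure(
    list(
      model = model,
      params = theta_to_params(best$par, layout, model),
      theta = setNames(best$par, layout$names),
      log_likelihood = -best$value,
      convergence = best$convergence,
      n_trials = sum(!is.na(trials$response)),
      layout = layout
    ),
    class = "observer_fit"
  )
}

#' @export
print.observer_fit <- function(x, ...) {
  cat("<observer_fit>", format(x$model), " logLik =",
      signif(x$log_likelihood, 6), "on", x$n_trials, "trials\n")
  print(x$params)
  invisible(x)
}

#' Tidy an observer-model fit
#'
#' @param x An `observer_fit` object.
#' @param ... Unused.
#' @return A tibble with columns `term` and `estimate`.
#' @export
tidy.observer_fit <- function(x, ...) {
  tibble::tibble(term = names(x$theta), estimate = unname(x$theta))
}

#' One-row summary of an observer-model fit
#'
#' @param x An `observer_fit` object.
#' @param ... Unused.
#' @return A tibble with `model_id`, `log_likelihood`, `n_trials`,
#'   `n_params`, `convergence`.
#' @export
glance.observer_fit <- function(x, ...) {
  tibble::tibble(
    model_id = format(x$model),
    log_likelihood = x$log_likelihood,
    n_trials = x$n_trials,
    n_params = length(x$theta),
    convergence = x$convergence
  )
}

#' Held-out log-likelihood of fitted parameters
#'
#' Sum of log choice probabilities of `trials` under a fitted model,
#' without refitting.
#'
#' @param fit An `observer_fit`.
#' @param trials Responded trials to score.
#' @param schedule Schedule defining the priors.
#' @param gh_order Gauss-Hermite order.
#' @return A single number (nats, always <= 0 for 2AFC data).
#' @export
score_loglik <- function(fit, trials, schedule = trials, gh_order = 7L) {
  cells <- response_cells(trials)
  cells_loglik(cells, fit$model, fit$params, schedule, gh_order)
}
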