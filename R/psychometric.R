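T_REF_LOG <- log(600)

#' Lapse-augmented cumulative-Gaussian psychometric function
#'
#' Probability that the comparison interval is judged longer than the
#' reference, as a function of log comparison duration:
#' `(1 - lambda) * pnorm((t + b - t_ref)/sigma) + lambda/2`. The
#' complementary response has probability one minus this.
#'
#' @param t_comp_log Log comparison duration (vectorized).
#' @param b Bias: horizontal shift on log duration; `exp(b)` is the
#'   duration distortion ratio.
#' @param sigma JND: SD of the cumulative Gaussian on log duration (> 0).
#' @param lambda Lapse rate in `[0, 1]`.
#' @param t_ref_log Log reference duration (default `log(600)`).
#' @return Probability of "comparison judged longer".
#' @export
#' @examples
#' psychometric_prob(log(800), b = 0.2, sigma = 0.3, lambda = 0.02)
psychometric_prob <- function(t_comp_log, b, sigma, lambda = 0,
                              t_ref_log = T_REF_LOG) {
  if (any(sigma <= 0)) abort("sigma must be > 0")
  stopifnot(all(lambda >= 0), all(lambda <= 1))
  (1 - lambda) * pnorm((t_comp_log + b - t_ref_log) / sigma) + lambda / 2
}

# Aggregate trials to per-condition response-count cells. Display orders
# are pooled within condition.
psychometric_cells <- function(trials) {
  trials <- dplyr::filter(trials, !is.na(.data$response))
  if (nrow(trials) == 0) abort("no responded trials to fit")
  trials %>%
    dplyr::mutate(longer = .data$response == "second_longer") %>%
    dplyr::group_by(.data$condition, .data$comp_duration_ms) %>%
    dplyr::summarise(
      n_longer = sum(ifelse(.data$order == "r-c", .data$longer,
                            !.data$longer)),
      n = dplyr::n(), .groups = "drop"
    ) %>%
    dplyr::mutate(t_log = log_ms(.data$comp_duration_ms))
}

#' Fit psychometric functions to 2AFC trials
#'
#' Jointly fits, by maximum likelihood, one cumulative-Gaussian psychometric
#' function per condition (bias `b` and JND `sigma` on log duration) with a
#' single lapse rate shared across conditions. Trials of both display
#' orders are pooled within a condition; "comparison judged longer" is read
#' off the response taking the display order into account. Optimization is
#' bounded quasi-Newton (`L-BFGS-B`) with seeded random restarts.
#'
#' Conditions in which every response is identical are perfectly separated:
#' the bias estimate runs to its bound and the fit is flagged degenerate.
#'
#' @param trials Trial tibble with responses.
#' @param restarts Number of random restarts (the first start is a
#'   deterministic heuristic).
#' @param seed Seed for the restart draws.
#' @param b_bounds,sigma_bounds,lambda_max Box constraints of the optimizer.
#' @return An object of class `psychfit`; see [tidy.psychfit()],
#'   [glance.psychfit()], [ddr()].
#' @export
#' @examples
#' sched <- build_schedule_exp1(1)
#' pars <- observer_params(b_H = 0.2, b_L = -0.2, lambda = 0.02)
#' sim <- simulate_responses(sched, model_spec("weighting", "no_decay",
#'                                             "flat"), pars, seed = 2)
#' fit <- fit_psychometric(sim)
#' tidy(fit)
fit_psychometric <- function(trials, restarts = 10L, seed = 1L,
                             b_bounds = c(-1.5, 1.5),
                             sigma_bounds = c(0.01, 2),
                             lambda_max = 0.5) {
  cells <- psychometric_cells(trials)
  conds <- sort(unique(cells$condition))
  k <- length(conds)
  if (any(tapply(cells$comp_duration_ms, cells$condition, length) < 2)) {
    abort("each condition needs at least 2 distinct comparison durations")
  }

  nll <- function(theta) {
    b <- theta[seq_len(k)]
    sg <- theta[k + seq_len(k)]
    lam <- theta[2 * k + 1]
    j <- match(cells$condition, conds)
    p <- psychometric_prob(cells$t_log, b[j], sg[j], lam)
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(cells$n_longer * log(p) + (cells$n - cells$n_longer) * log(1 - p))
  }

  lower <- c(rep(b_bounds[1], k), rep(sigma_bounds[1], k), 0)
  upper <- c(rep(b_bounds[2], k), rep(sigma_bounds[2], k), lambda_max)

  # heuristic start: probit slope/intercept per condition
  start0 <- c(rep(0, k), rep(0.3, k), 0.02)
  starts <- with_seed(seed, c(
    list(start0),
    purrr::map(seq_len(max(restarts - 1, 0)), function(i) {
      runif(2 * k + 1, lower, upper)
    })
  ))

  fits <- purrr::map(starts, function(s) {
    tryCatch(
      optim(s, nll, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL
    )
  })
  fits <- purrr::compact(fits)
  if (length(fits) == 0) abort("psychometric optimization failed")
  best <- fits[[which.min(purrr::map_dbl(fits, "value"))]]

  b_hat <- setNames(best$par[seq_len(k)], conds)
  s_hat <- setNames(best$par[k + seq_len(k)], conds)
  degenerate <- cells %>%
    dplyr::group_by(.data$condition) %>%
    dplyr::summarise(sep = all(.data$n_longer == .data$n) ||
                       all(.data$n_longer == 0), .groups = "drop")
  deg_conds <- degenerate$condition[degenerate$sep]

  structure(
    list(
      conditions = conds,
      b = b_hat,
      sigma = s_hat,
      lambda = unname(best$par[2 * k + 1]),
      log_likelihood = -best$value,
      degenerate = deg_conds,
      cells = cells,
      convergence = best$convergence
    ),
    class = "psychfit"
  )
}

#' @export
print.psychfit <- function(x, ...) {
  cat("<psychfit>", length(x$conditions), "condition(s), lambda =",
      signif(x$lambda, 3), "\n")
  print(tidy(x))
  invisible(x)
}

#' Duration distortion ratio of a fitted condition
#'
#' The DDR is `exp(b)`: the multiplicative factor by which the comparison
#' stimulus type is perceived longer (DDR > 1) or shorter (DDR < 1) than
#' the reference stimulus type.
#'
#' @param fit A [fit_psychometric()] object.
#' @param condition Condition label present in the fit.
#' @return The DDR as a single number.
#' @export
ddr <- function(fit, condition) {
  stopifnot(inherits(fit, "psychfit"))
  if (!condition %in% fit$conditions) {
    abort(sprintf("condition '%s' not in fit (have: %s)", condition,
                  paste(fit$conditions, collapse = ", ")))
  }
  exp(unname(fit$b[condition]))
}

#' Tidy a psychometric fit
#'
#' @param x A `psychfit` object.
#' @param ... Unused.
#' @return A tibble with one row per condition: `condition`, `b`, `sigma`
#'   (JND), `ddr`, `lambda`, `degenerate`.
#' @export
tidy.psychfit <- function(x, ...) {
  tibble::tibble(
    condition = x$conditions,
    b = unname(x$b),
    sigma = unname(x$sigma),
    ddr = exp(unname(x$b)),
    lambda = x$lambda,
    degenerate = x$conditions %in% x$degenerate
  )
}

#' One-row summary of a psychometric fit
#'
#' @param x A `psychfit` object.
#' @param ... Unused.
#' @return A tibble with `log_likelihood`, `lambda`, `n_conditions`,
#'   `convergence`.
#' @export
glance.psychfit <- function(x, ...) {
  tibble::tibble(
    log_likelihood = x$log_likelihood,
    lambda = x$lambda,
    n_conditions = length(x$conditions),
    convergence = x$convergence
  )
}
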