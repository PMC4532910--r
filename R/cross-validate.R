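#' Stratified fold assignment for cross-validation
#'
#' Partitions trials into `n_folds` folds, stratified by condition and
#' display order: within each (condition x order) cell trials are shuffled
#' and dealt round-robin, the deal continuing across cells so that fold
#' sizes are globally balanced while differing by at most one within every
#' cell.
#'
#' @param trials Trial tibble.
#' @param n_folds Number of folds (default 12).
#' @param seed Seed for the within-cell shuffles.
#' @return Integer vector of fold labels (1..n_folds) aligned with rows of
#'   `trials`.
#' @export
#' @examples
#' table(make_folds(build_schedule_exp3(1), 12, seed = 1))
make_folds <- function(trials, n_folds = 12L, seed = 1L) {
  n <- nrow(trials)
  if (n_folds > n) abort("more folds than trials")
  cell <- paste(trials$condition, trials$order, sep = "\r")
  fold <- integer(n)
  with_seed(seed, {
    pointer <- 0L
    # cells sorted so both order-cells of a condition are dealt
    # consecutively: the continuing deal then balances folds at the
    # condition level as well as globally
    for (cl in sort(unique(cell), method = "radix")) {
      idx <- which(cell == cl)
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- ((pointer + seq_along(idx) - 1L) %% n_folds) + 1L
      pointer <- (pointer + length(idx)) %% n_folds
    }
  })
  fold
}

#' Cross-validate one observer model
#'
#' For each fold, fits the model on the remaining folds and evaluates the
#' summed log choice probability of the held-out trials at the trained
#' parameters; the total cross-validated log-likelihood (CVLL) is the sum
#' over folds. Priors are rebuilt from the full schedule, not the training
#' split. By default each fold's optimization is warm-started from a single
#' fit to the full dataset (plus the usual heuristic start), which makes
#' the per-fold optimum cheap to polish; set `warm_start = FALSE` for fully
#' independent fold fits.
#'
#' @param trials Responded trials.
#' @param model [model_spec()].
#' @param n_folds Number of folds (default 12).
#' @param seed Seed for fold assignment and optimizer restarts.
#' @param restarts Optimizer starts for the full-data (or per-fold) fit.
#' @param fold_restarts Optimizer starts per fold when warm-starting.
#' @param warm_start Warm-start fold fits from the full-data fit.
#' @param folds Optional externally supplied fold assignment (to share one
#'   assignment across models, as required for paired comparison).
#' @param gh_order,maxit,factr Passed to [fit_model()].
#' @param fold_maxit,fold_factr Optimizer budget for the warm-started
#'   per-fold fits (default: same as the full fit).
#' @return An object of class `cv_result`: per-fold test log-likelihoods,
#'   `total_cvll`, per-fold fitted parameters and the fold assignment.
#' @export
cross_validate <- function(trials, model, n_folds = 12L, seed = 1L,
                           restarts = 3L, fold_restarts = 1L,
                           warm_start = TRUE, folds = NULL,
                           gh_order = 7L, maxit = 200L, factr = 1e8,
                           fold_maxit = maxit, fold_factr = factr) {
  trials <- dplyr::filter(trials, !is.na(.data$response))
  if (is.null(folds)) folds <- make_folds(trials, n_folds, seed)
  stopifnot(length(folds) == nrow(trials))
  n_folds <- max(folds)

  init <- NULL
  if (warm_start) {
    full <- fit_model(trials, model, schedule = trials, restarts = restarts,
                      seed = seed, gh_order = gh_order, maxit = maxit,
                      factr = factr)
    init <- full$theta
  }

  fold_fits <- purrr::map(seq_len(n_folds), function(f) {
    train <- trials[folds != f, , drop = FALSE]
    fit <- tryCatch(
      fit_model(train, model, schedule = trials,
                restarts = if (warm_start) fold_restarts else restarts,
                seed = seed + f, init = init, gh_order = gh_order,
                maxit = fold_maxit, factr = fold_factr),
      error = function(e) {
        warn(sprintf("fold %d fit failed: %s", f, conditionMessage(e)))
        NULL
      }
    )
    fit
  })
  fold_ll <- purrr::map_dbl(seq_len(n_folds), function(f) {
    fit <- fold_fits[[f]]
    if (is.null(fit)) return(NA_real_)
    score_loglik(fit, trials[folds == f, , drop = FALSE], schedule = trials,
                 gh_order = gh_order)
  })

  structure(
    list(
      model = model,
      model_id = format(model),
      fold_loglik = fold_ll,
      total_cvll = sum(fold_ll),
      fits = fold_fits,
      folds = folds,
      n_trials = nrow(trials)
    ),
    class = "cv_result"
  )
}

#' @export
print.cv_result <- function(x, ...) {
  cat("<cv_result>", x$model_id, ":", length(x$fold_loglik),
      "folds, total CVLL =", signif(x$total_cvll, 6), "\n")
  invisible(x)
}

#' Tidy a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return A tibble with one row per fold: `fold`, `test_loglik`, `n_test`.
#' @export
tidy.cv_result <- function(x, ...) {
  tibble::tibble(
    model_id = x$model_id,
    fold = seq_along(x$fold_loglik),
    test_loglik = x$fold_loglik,
    n_test = as.integer(table(x$folds))
  )
}

#' One-row summary of a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return A tibble with `model_id`, `total_cvll`, `n_folds`, `n_trials`.
#' @export
glance.cv_result <- function(x, ...) {
  tibble::tibble(
    model_id = x$model_id,
    total_cvll = x$total_cvll,
    n_folds = length(x$fold_loglik),
    n_trials = x$n_trials
  )
}

#' Compare cross-validated models
#'
#' Within each dataset, computes the difference in total cross-validated
#' log-likelihood (delta CVLL) of every model from that dataset's best
#' model. When results for several datasets (e.g. simulated observers) are
#' supplied, also reports the group level: mean delta CVLL against the
#' model with the best mean CVLL, a paired two-sided t-test of each model
#' against that best model, and Holm-Bonferroni adjusted significance at
#' alpha = 0.05. All models of one dataset must share the same fold
#' assignment, otherwise the comparison is refused.
#'
#' @param cv_results A list of `cv_result` objects (one dataset), or a list
#'   of such lists (one per dataset) for a group comparison.
#' @return A tibble; for groups, columns include `mean_delta_cvll`,
#'   `p_value`, `p_holm`, `significant`.
#' @export
compare_models <- function(cv_results) {
  is_group <- !inherits(cv_results[[1]], "cv_result")
  datasets <- if (is_group) cv_results else list(cv_results)

  per_dataset <- purrr::imap(datasets, function(res, d) {
    stopifnot(all(purrr::map_lgl(res, inherits, "cv_result")))
    folds <- purrr::map(res, "folds")
    if (length(unique(purrr::map_chr(folds, paste, collapse = ","))) != 1) {
      abort("cv results within a dataset use different fold assignments")
    }
    tibble::tibble(
      dataset = d,
      model_id = purrr::map_chr(res, "model_id"),
      total_cvll = purrr::map_dbl(res, "total_cvll")
    ) %>%
      dplyr::mutate(delta_cvll = .data$total_cvll - max(.data$total_cvll))
  }) %>% dplyr::bind_rows()

  if (!is_group) {
    return(dplyr::arrange(per_dataset, dplyr::desc(.data$total_cvll)))
  }

  wide <- per_dataset %>%
    dplyr::group_by(.data$model_id) %>%
    dplyr::summarise(mean_cvll = mean(.data$total_cvll), .groups = "drop")
  best_id <- wide$model_id[which.max(wide$mean_cvll)]

  best_by_ds <- per_dataset %>%
    dplyr::filter(.data$model_id == best_id) %>%
    dplyr::select("dataset", best_cvll = "total_cvll")

  out <- per_dataset %>%
    dplyr::left_join(best_by_ds, by = "dataset") %>%
    dplyr::group_by(.data$model_id) %>%
    dplyr::summarise(
      mean_cvll = mean(.data$total_cvll),
      mean_delta_cvll = mean(.data$total_cvll - .data$best_cvll),
      sd_delta_cvll = stats::sd(.data$total_cvll - .data$best_cvll),
      p_value = if (.data$model_id[1] == best_id) NA_real_ else {
        t.test(.data$total_cvll, .data$best_cvll, paired = TRUE)$p.value
      },
      .groups = "drop"
    ) %>%
    dplyr::mutate(
      best = .data$model_id == best_id,
      p_holm = p.adjust(.data$p_value, method = "holm"),
      significant = !is.na(.data$p_holm) & .data$p_holm < 0.05
    ) %>%
    dplyr::arrange(dplyr::desc(.data$mean_cvll))
  out
}
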