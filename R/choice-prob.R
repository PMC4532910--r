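# Gauss-Hermite rule by Golub-Welsch: nodes/weights for
# integral f(x) exp(-x^2) dx.
gh_rule <- function(n) {
  if (n == 1) return(list(x = 0, w = sqrt(pi)))
  k <- seq_len(n - 1)
  J <- matrix(0, n, n)
  off <- sqrt(k / 2)
  J[cbind(k, k + 1)] <- off
  J[cbind(k + 1, k)] <- off
  e <- eigen(J, symmetric = TRUE)
  ord <- order(e$values)
  list(x = e$values[ord], w = sqrt(pi) * e$vectors[1, ord]^2)
}

# Scalar sufficient-statistic branches of one stimulus: although an HL
# stimulus yields two measurements, each combination rule's inference
# depends on a single scalar whose generative distribution is Gaussian.
# Returns one row per branch: prob, bias (generative mean offset from the
# true log duration), sd_g (generative SD incl. decay), v (observer
# likelihood variance; equals sd_g^2 for every rule here because the
# observer's assumed noise equals the true noise).
stimulus_branches <- function(stim_type, model, params, position) {
  s <- decay_scale(model, params, position)
  elem <- function(prob, bias, sd) {
    list(prob = prob, bias = bias, sd_g = sd * s, v = (sd * s)^2)
  }
  if (stim_type == "H") return(elem(1, params$b_H, params$sigma_H))
  if (stim_type == "L") return(elem(1, params$b_L, params$sigma_L))
  switch(model$combination,
    weighting = {
      w <- params$w_H
      elem(1, w * params$b_H + (1 - w) * params$b_L,
           sqrt(w^2 * params$sigma_H^2 + (1 - w)^2 * params$sigma_L^2))
    },
    optimal_integration = {
      w <- optimal_w_H(params$sigma_H, params$sigma_L)
      elem(1, w * params$b_H + (1 - w) * params$b_L,
           predict_sd_optimal(params$sigma_H, params$sigma_L))
    },
    selection = elem(c(params$c_H, 1 - params$c_H),
                     c(params$b_H, params$b_L),
                     c(params$sigma_H, params$sigma_L)),
    reliable_stimulus = {
      if (params$sigma_H <= params$sigma_L) {
        elem(1, params$b_H, params$sigma_H)
      } else {
        elem(1, params$b_L, params$sigma_L)
      }
    }
  )
}

prior_type_code <- function(priors) {
  switch(priors$hypothesis, flat = 0L, single = 1L, double = 2L)
}

# Branch lookup values for every (type, position) pair under the current
# parameters: a list keyed "type.position" of branch tibbles.
branch_values <- function(model, params, types1, types2) {
  vals <- list()
  for (ty in unique(types1)) {
    vals[[paste0(ty, ".first")]] <-
      stimulus_branches(ty, model, params, "first")
  }
  for (ty in unique(types2)) {
    vals[[paste0(ty, ".second")]] <-
      stimulus_branches(ty, model, params, "second")
  }
  vals
}

# Precompiled evaluation context for repeated choice-probability calls on a
# fixed cell set (the expensive pieces that do not depend on parameters:
# branch expansion, grouping order, prior component layout).
cp_context <- function(cells, model, schedule, gh_order = 7L) {
  gh <- gh_rule(gh_order)
  first_type <- ifelse(cells$order == "r-c", cells$ref_type, cells$comp_type)
  second_type <- ifelse(cells$order == "r-c", cells$comp_type, cells$ref_type)
  t1 <- ifelse(cells$order == "r-c", log_ms(REF_MS),
               log_ms(cells$comp_duration_ms))
  t2 <- ifelse(cells$order == "r-c", log_ms(cells$comp_duration_ms),
               log_ms(REF_MS))
  nb <- function(ty) {
    if (ty == "HL" && model$combination == "selection") 2L else 1L
  }
  n1 <- vapply(first_type, nb, integer(1))
  n2 <- vapply(second_type, nb, integer(1))
  # expand cells to branch combinations
  cell_id <- rep(seq_len(nrow(cells)), times = n1 * n2)
  b1 <- unlist(purrr::map2(n1, n2, function(a, b) rep(seq_len(a), each = b)))
  b2 <- unlist(purrr::map2(n1, n2, function(a, b) rep(seq_len(b), times = a)))
  key1 <- paste0(first_type[cell_id], ".first")
  key2 <- paste0(second_type[cell_id], ".second")
  # rows sharing (key1, b1, key2, b2) share (v1, v2); order within group by
  # the first interval's true duration so boundary solving is monotone
  ord <- order(key1, b1, key2, b2, t1[cell_id], method = "radix")
  counts <- dplyr::count(schedule, .data$comp_duration_ms)
  key1 <- key1[ord]
  key2 <- key2[ord]
  b1 <- b1[ord]
  b2 <- b2[ord]
  # precomputed row-index slots per (key, branch) for fast filling
  slots1 <- split(seq_along(key1), paste(key1, b1))
  slots2 <- split(seq_along(key2), paste(key2, b2))
  slot_info <- function(nm) {
    parts <- strsplit(nm, " ")
    list(key = vapply(parts, `[`, "", 1L),
         branch = as.integer(vapply(parts, `[`, "", 2L)))
  }
  list(
    gh = gh, n_cells = nrow(cells),
    cell_id = cell_id[ord],
    key1 = key1, b1 = b1, key2 = key2, b2 = b2,
    slots1 = slots1, info1 = slot_info(names(slots1)),
    slots2 = slots2, info2 = slot_info(names(slots2)),
    t1 = t1[cell_id][ord], t2 = t2[cell_id][ord],
    n_rows = length(key1),
    types1 = unique(sub("\\.first$", "", key1)),
    types2 = unique(sub("\\.second$", "", key2)),
    prior_hypothesis = model$prior,
    prior_counts = counts$n,
    prior_means = log_ms(counts$comp_duration_ms)
  )
}

# Fast prior construction from a precompiled context.
ctx_priors <- function(ctx, kappa) {
  if (ctx$prior_hypothesis == "flat") {
    return(structure(list(hypothesis = "flat", kappa = NULL),
                     class = "duration_prior"))
  }
  k2 <- kappa^2
  wc <- ctx$prior_counts / sum(ctx$prior_counts)
  p_c <- list(weight = wc, mean = ctx$prior_means,
              variance = rep(k2, length(wc)))
  p_r <- list(weight = 1, mean = log_ms(REF_MS), variance = k2)
  pooled <- list(weight = c(0.5, 0.5 * wc),
                 mean = c(log_ms(REF_MS), ctx$prior_means),
                 variance = rep(k2, length(wc) + 1))
  structure(list(hypothesis = ctx$prior_hypothesis, kappa = kappa,
                 p_r = p_r, p_c = p_c, pooled = pooled),
            class = "duration_prior")
}

# Choice probability (before lapse) per cell from a precompiled context.
cp_context_eval <- function(ctx, model, params, priors = NULL) {
  if (is.null(priors)) priors <- ctx_priors(ctx, params$kappa)
  vals <- branch_values(model, params, ctx$types1, ctx$types2)
  n <- ctx$n_rows
  fill <- function(slots, info) {
    prob <- numeric(n); bias <- numeric(n); sd_g <- numeric(n); v <- numeric(n)
    for (j in seq_along(slots)) {
      tab <- vals[[info$key[j]]]
      b <- info$branch[j]
      idx <- slots[[j]]
      prob[idx] <- tab$prob[b]
      bias[idx] <- tab$bias[b]
      sd_g[idx] <- tab$sd_g[b]
      v[idx] <- tab$v[b]
    }
    list(prob = prob, bias = bias, sd_g = sd_g, v = v)
  }
  f1 <- fill(ctx$slots1, ctx$info1)
  f2 <- fill(ctx$slots2, ctx$info2)

  pm <- prior_mixtures(priors)
  p_branch <- .cp_batch(ctx$t1 + f1$bias, f1$sd_g, f1$v,
                        ctx$t2 + f2$bias, f2$sd_g, f2$v,
                        prior_type_code(priors),
                        pm$pr_w, pm$pr_m, pm$pc_w, pm$pc_m, pm$pv,
                        ctx$gh$x, ctx$gh$w)
  as.numeric(rowsum(f1$prob * f2$prob * p_branch, ctx$cell_id,
                    reorder = TRUE))
}

prior_mixtures <- function(priors) {
  if (priors$hypothesis == "flat") {
    list(pr_w = numeric(0), pr_m = numeric(0), pc_w = numeric(0),
         pc_m = numeric(0), pv = 1)
  } else if (priors$hypothesis == "single") {
    list(pr_w = priors$pooled$weight, pr_m = priors$pooled$mean,
         pc_w = numeric(0), pc_m = numeric(0), pv = priors$kappa^2)
  } else {
    list(pr_w = priors$p_r$weight, pr_m = priors$p_r$mean,
         pc_w = priors$p_c$weight, pc_m = priors$p_c$mean,
         pv = priors$kappa^2)
  }
}

# Choice probability (before lapse) for unique trial cells.
# `cells`: tibble with ref_type, comp_type, order, comp_duration_ms.
# Returns the vector p(second reported longer) per cell row.
cp_cells <- function(cells, model, params, priors, gh_order = 7L) {
  ctx <- cp_context(cells, model, schedule = cells, gh_order = gh_order)
  cp_context_eval(ctx, model, params, priors)
}

#' Model-predicted choice probabilities for trials
#'
#' Computes, for each trial, the probability that the observer reports the
#' second interval as longer, under a given observer model and parameter
#' set. The double integral over the two measurements is evaluated as an
#' analytic Gaussian baseline plus a Gauss-Hermite quadrature (default
#' order 7) of the correction due to the prior-induced shift of the
#' decision boundary, which is located by a bracketed numerical search
#' (tolerance 1e-10). Ties in the decision posterior count as "second
#' longer". The lapse rate mixes in a fair guess: the returned probability
#' always lies in `[lambda/2, 1 - lambda/2]`.
#'
#' @param trials A trial tibble (see [build_schedule_exp1()]); responses are
#'   ignored.
#' @param model [model_spec()].
#' @param params [observer_params()], validated against `model`.
#' @param priors A [build_priors()] object matching `model$prior`; built
#'   from `trials` with `params$kappa` when not supplied.
#' @param gh_order Order of the Gauss-Hermite rule.
#' @return The input tibble with an added column `p_second_longer`.
#' @export
#' @examples
#' sched <- build_schedule_exp1(1)
#' pars <- observer_params(b_H = 0.2, b_L = -0.2, lambda = 0.02)
#' mod <- model_spec("weighting", "no_decay", "flat")
#' # flat model on single-element stimuli needs no w_H
#' head(choice_probability(sched, mod, pars)$p_second_longer)
choice_probability <- function(trials, model, params, priors = NULL,
                               gh_order = 7L) {
  stopifnot(inherits(model, "model_spec"), inherits(params, "observer_params"))
  needs_w <- model$combination == "weighting" &&
    any(c(trials$ref_type, trials$comp_type) == "HL")
  if (needs_w && is.null(params$w_H)) {
    abort("weighting model on HL trials requires w_H")
  }
  if (model$combination == "selection" &&
      any(c(trials$ref_type, trials$comp_type) == "HL") &&
      is.null(params$c_H)) {
    abort("selection model on HL trials requires c_H")
  }
  if (model$decay == "decay" && is.null(params$m)) {
    abort("decay model requires m")
  }
  if (is.null(priors)) {
    priors <- build_priors(trials, model$prior, kappa = params$kappa)
  }
  if (priors$hypothesis != model$prior) {
    abort("priors were built under a different prior hypothesis than `model`")
  }
  cells <- dplyr::distinct(
    trials, .data$ref_type, .data$comp_type, .data$order,
    .data$comp_duration_ms
  )
  cells$p_raw <- cp_cells(cells, model, params, priors, gh_order)
  lam <- params$lambda
  cells$p_second_longer <- lam / 2 + (1 - lam) * cells$p_raw
  dplyr::left_join(
    trials, dplyr::select(cells, -"p_raw"),
    by = c("ref_type", "comp_type", "order", "comp_duration_ms")
  )
}
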