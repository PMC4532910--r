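#' Comparison-duration grid
#'
#' The 26 comparison durations used in all three experiments: 100 to 1100 ms
#' in 40 ms steps. Over a session their incidence approximates a Gaussian
#' with mean 600 ms and SD 300 ms, truncated to this range.
#'
#' @return Integer vector of length 26 (milliseconds).
#' @export
#' @examples
#' duration_grid()
duration_grid <- function() {
  seq(100L, 1100L, by = 40L)
}

# Printed per-order incidence of each comparison duration, one count per
# grid level. Exp 2 used a single order, so its list is the per-condition
# total.
incidence_exp1 <- function() {
  c(1L, 2L, 2L, 2L, 3L, 3L, 4L, 4L, 4L, 5L, 5L, 5L, 5L, 5L, 5L, 5L, 5L,
    4L, 4L, 4L, 3L, 3L, 2L, 2L, 2L, 1L)
}

incidence_exp2 <- function() {
  c(2L, 2L, 4L, 4L, 4L, 6L, 6L, 6L, 8L, 8L, 8L, 8L, 8L, 8L, 8L, 8L, 8L,
    8L, 6L, 6L, 6L, 4L, 4L, 4L, 2L, 2L)
}

incidence_exp3 <- function() {
  c(rep(3L, 7L), rep(6L, 12L), rep(3L, 7L))
}

# One condition x order block: one row per trial, durations expanded by the
# incidence list.
schedule_block <- function(experiment_id, condition, ref_type, comp_type,
                           order, incidence) {
  stopifnot(length(incidence) == 26L)
  tibble::tibble(
    experiment_id = experiment_id,
    condition = condition,
    ref_type = ref_type,
    comp_type = comp_type,
    order = order,
    ref_duration_ms = REF_MS,
    comp_duration_ms = rep(duration_grid(), times = incidence),
    response = NA_character_
  )
}

# Evaluate `code` under a seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

finish_schedule <- function(trials, seed) {
  out <- with_seed(seed, trials[sample.int(nrow(trials)), , drop = FALSE])
  out$trial <- seq_len(nrow(out))
  dplyr::select(out, "trial", dplyr::everything())
}

#' Build the trial schedule of Experiment 1
#'
#' Two conditions (`LvsH`: reference H, comparison L; `HvsL`: reference L,
#' comparison H), 180 trials each, both display orders balanced, comparison
#' durations following the printed per-order incidence list. Responses are
#' left missing; fill them with [simulate_responses()].
#'
#' @param seed Integer seed controlling the trial interleaving only; the
#'   trial composition is fixed by design.
#' @return A tibble with one row per trial and columns `trial`,
#'   `experiment_id`, `condition`, `ref_type`, `comp_type`, `order`,
#'   `ref_duration_ms`, `comp_duration_ms`, `response`.
#' @export
#' @examples
#' sched <- build_schedule_exp1(seed = 1)
#' dplyr::count(sched, condition)
build_schedule_exp1 <- function(seed = 1L) {
  inc <- incidence_exp1()
  blocks <- list(
    schedule_block("exp1", "LvsH", "H", "L", "r-c", inc),
    schedule_block("exp1", "LvsH", "H", "L", "c-r", inc),
    schedule_block("exp1", "HvsL", "L", "H", "r-c", inc),
    schedule_block("exp1", "HvsL", "L", "H", "c-r", inc)
  )
  finish_schedule(dplyr::bind_rows(blocks), seed)
}

#' Build the trial schedule of Experiment 2
#'
#' Three conditions (`LvsHL`, `HvsHL`, `HLvsHL`), all with an HL reference
#' shown first (`order == "r-c"` on every trial), 148 trials per condition.
#'
#' @inheritParams build_schedule_exp1
#' @return A tibble of 444 trials; see [build_schedule_exp1()] for columns.
#' @export
build_schedule_exp2 <- function(seed = 1L) {
  inc <- incidence_exp2()
  blocks <- list(
    schedule_block("exp2", "LvsHL", "HL", "L", "r-c", inc),
    schedule_block("exp2", "HvsHL", "HL", "H", "r-c", inc),
    schedule_block("exp2", "HLvsHL", "HL", "HL", "r-c", inc)
  )
  finish_schedule(dplyr::bind_rows(blocks), seed)
}

#' Build the trial schedule of Experiment 3
#'
#' Seven conditions crossing reference type (H, L, HL) with comparison type
#' (H, L for every reference; HL only against the HL reference), 228 trials
#' per condition, both display orders balanced. The three experimental
#' sessions are flattened into one schedule; a `session` annotation is kept
#' but plays no role downstream.
#'
#' @inheritParams build_schedule_exp1
#' @return A tibble of 1596 trials; see [build_schedule_exp1()] for columns,
#'   plus `session`.
#' @export
build_schedule_exp3 <- function(seed = 1L) {
  inc <- incidence_exp3()
  pairs <- list(
    c("H", "H"), c("H", "L"),
    c("L", "H"), c("L", "L"),
    c("HL", "H"), c("HL", "L"), c("HL", "HL")
  )
  blocks <- purrr::map(pairs, function(p) {
    cond <- paste0(p[2], "vs", p[1])
    dplyr::bind_rows(
      schedule_block("exp3", cond, p[1], p[2], "r-c", inc),
      schedule_block("exp3", cond, p[1], p[2], "c-r", inc)
    )
  })
  trials <- dplyr::bind_rows(blocks)
  # incidence counts are multiples of 3, so sessions split evenly
  trials <- trials %>%
    dplyr::group_by(.data$condition, .data$order, .data$comp_duration_ms) %>%
    dplyr::mutate(session = rep_len(1:3, dplyr::n())) %>%
    dplyr::ungroup()
  finish_schedule(trials, seed)
}

#' Per-cell trial counts of a schedule
#'
#' Convenience tabulation of a schedule by condition, display order and
#' comparison duration, used by the schedule-exactness checks.
#'
#' @param schedule A schedule tibble.
#' @return A tibble with columns `condition`, `order`, `comp_duration_ms`, `n`.
#' @export
schedule_counts <- function(schedule) {
  dplyr::count(schedule, .data$condition, .data$order, .data$comp_duration_ms)
}
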