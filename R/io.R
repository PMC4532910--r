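TRIAL_COLUMNS <- c("experiment_id", "condition", "ref_type", "comp_type",
                   "order", "ref_duration_ms", "comp_duration_ms", "response")

#' Write a trial table to CSV
#'
#' Durations are stored in milliseconds; missing responses become empty
#' fields. The numeric response alias writes `1` for `"second_longer"` and
#' `0` for `"second_shorter"` when `numeric_response = TRUE`.
#'
#' @param trials Trial tibble.
#' @param path Output file.
#' @param numeric_response Write responses as 1/0 instead of labels.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path, numeric_response = FALSE) {
  out <- trials[, intersect(TRIAL_COLUMNS, names(trials))]
  if (numeric_response) {
    out$response <- dplyr::case_when(
      out$response == "second_longer" ~ "1",
      out$response == "second_shorter" ~ "0",
      TRUE ~ NA_character_
    )
  }
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a trial table from CSV
#'
#' Accepts the schema written by [write_trials()]; the response column may
#' use the `"second_longer"`/`"second_shorter"` labels or the documented
#' `1`/`0` alias, and empty fields become missing responses. With
#' `strict = TRUE` (default) comparison durations must lie on the 26-level
#' experimental grid and the reference must be 600 ms; offending rows are
#' reported.
#'
#' @param path CSV file.
#' @param strict Enforce the duration grid.
#' @return A trial tibble.
#' @export
read_trials <- function(path, strict = TRUE) {
  if (!file.exists(path)) abort(paste("no such file:", path))
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  missing_cols <- setdiff(TRIAL_COLUMNS, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste("trial file lacks columns:",
                paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::as_tibble(raw[TRIAL_COLUMNS])
  out$ref_duration_ms <- as.numeric(out$ref_duration_ms)
  out$comp_duration_ms <- as.numeric(out$comp_duration_ms)
  resp <- out$response
  resp[resp == ""] <- NA_character_
  resp[resp == "1"] <- "second_longer"
  resp[resp == "0"] <- "second_shorter"
  bad_resp <- !is.na(resp) &
    !resp %in% c("second_longer", "second_shorter")
  if (any(bad_resp)) {
    abort(paste("unrecognized responses in rows:",
                paste(head(which(bad_resp), 10), collapse = ", ")))
  }
  out$response <- resp
  if (strict) {
    bad <- !(out$comp_duration_ms %in% duration_grid()) |
      out$ref_duration_ms != REF_MS
    if (any(bad)) {
      abort(paste("durations off the experimental grid in rows:",
                  paste(head(which(bad), 10), collapse = ", ")))
    }
  }
  out
}

#' Read a run configuration
#'
#' Configurations are YAML or JSON mappings with fields `experiment_id`
#' (`"exp1"`, `"exp2"` or `"exp3"`), `schedule_seed`, `observer_seed`,
#' `model` (factor levels or `"all"`), `params` (generating parameter
#' values), and optional `folds`, `restarts`, `gh_order`, `out_dir`.
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A named list with class `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.json$", path)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  as_run_config(cfg)
}

as_run_config <- function(cfg) {
  needed <- c("experiment_id", "schedule_seed", "observer_seed", "gen_model",
              "model", "params")
  missing_fields <- setdiff(needed, names(cfg))
  if (length(missing_fields) > 0) {
    abort(paste("config lacks fields:",
                paste(missing_fields, collapse = ", ")))
  }
  defaults <- list(folds = 12L, restarts = 3L, gh_order = 7L,
                   out_dir = NULL)
  cfg <- utils::modifyList(defaults, cfg)
  structure(cfg, class = "run_config")
}

config_params <- function(cfg) {
  do.call(observer_params, cfg$params)
}

config_models <- function(cfg) {
  if (identical(cfg$model, "all")) {
    enumerate_models()$spec
  } else {
    list(model_spec(cfg$model$combination, cfg$model$decay, cfg$model$prior))
  }
}

#' Run the simulate / fit / cross-validate / compare pipeline
#'
#' Executes the full workflow described by a configuration: build the
#' experiment schedule, simulate responses from the generating model,
#' fit psychometric functions, cross-validate the requested observer
#' model(s) on one shared fold assignment, and compare them. When
#' `out_dir` is set, results and a manifest (seeds, versions, timings) are
#' written as JSON/CSV.
#'
#' @param config A `run_config` (see [read_run_config()]) or a named list
#'   with the same fields.
#' @return A list with `schedule`, `trials`, `psychometric`, `cv_results`,
#'   `comparison`, `manifest`.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "run_config")) config <- as_run_config(config)
  t0 <- Sys.time()
  build <- switch(config$experiment_id,
    exp1 = build_schedule_exp1, exp2 = build_schedule_exp2,
    exp3 = build_schedule_exp3,
    abort(paste("unknown experiment_id:", config$experiment_id))
  )
  schedule <- build(config$schedule_seed)

  gen_model <- model_spec(config$gen_model$combination,
                          config$gen_model$decay, config$gen_model$prior)
  gen_params <- config_params(config)
  trials <- simulate_responses(schedule, gen_model, gen_params,
                               seed = config$observer_seed)

  psych <- fit_psychometric(trials, seed = config$observer_seed)

  models <- config_models(config)
  folds <- make_folds(trials, config$folds, seed = config$observer_seed)
  cv_results <- purrr::map(models, function(mod) {
    cross_validate(trials, mod, folds = folds, seed = config$observer_seed,
                   restarts = config$restarts, gh_order = config$gh_order)
  })
  comparison <- compare_models(cv_results)

  manifest <- list(
    package_version = as.character(utils::packageVersion("durbayes")),
    r_version = R.version.string,
    experiment_id = config$experiment_id,
    schedule_seed = config$schedule_seed,
    observer_seed = config$observer_seed,
    folds = config$folds,
    restarts = config$restarts,
    gh_order = config$gh_order,
    gen_model = format(gen_model),
    n_trials = nrow(trials),
    models = purrr::map_chr(models, format),
    elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs"))
  )

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_trials(trials, file.path(config$out_dir, "trials.csv"))
    jsonlite::write_json(
      list(psychometric = tidy(psych),
           cv = purrr::map(cv_results, glance)),
      file.path(config$out_dir, "fits.json"),
      dataframe = "rows", auto_unbox = TRUE, digits = NA
    )
    utils::write.csv(comparison,
                     file.path(config$out_dir, "comparison.csv"),
                     row.names = FALSE)
    jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }

  list(schedule = schedule, trials = trials, psychometric = psych,
       cv_results = cv_results, comparison = comparison, manifest = manifest)
}
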