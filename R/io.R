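#' Read a trial-level choice log
#'
#' Expects a CSV with columns `trial`, `participant_id`, `block`, `offer`,
#' `choice` and optionally `rating` (empty allowed) and `rating_flag`.
#' Choices are parsed case-insensitively from `accept`/`reject` or the
#' keyboard codes `1` (accept) / `2` (reject). Trial indices are 1-based.
#'
#' @param path CSV file path.
#' @param endowment Token endowment used for offer-bound validation.
#' @return A validated tibble of trial records with `choice` normalized to
#'   `"accept"`/`"reject"`.
#' @export
read_trial_log <- function(path, endowment = 20) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           choice = readr::col_character(),
                           participant_id = readr::col_character(),
                           block = readr::col_character(),
                           .default = readr::col_guess()
                         ))
  required <- c("trial", "participant_id", "block", "offer", "choice")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  bad_offer <- which(raw$offer < 0 | raw$offer > endowment)
  if (length(bad_offer) > 0) {
    abort(paste0("Offer out of [0, ", endowment, "] at row(s): ",
                 paste(head(bad_offer, 5), collapse = ", ")))
  }
  if (any(raw$trial < 1)) abort("Trial indices must be 1-based.")
  dup <- duplicated(raw[c("participant_id", "trial")])
  if (any(dup)) {
    abort(paste0("Duplicate (participant, trial) at row(s): ",
                 paste(head(which(dup), 5), collapse = ", ")))
  }
  ch <- tolower(raw$choice)
  bad_choice <- which(!ch %in% c("accept", "reject", "1", "2"))
  if (length(bad_choice) > 0) {
    abort(paste0("Unknown choice code at row(s): ",
                 paste(head(bad_choice, 5), collapse = ", ")))
  }
  raw$choice <- ifelse(ch %in% c("accept", "1"), "accept", "reject")
  if (!"rating" %in% names(raw)) raw$rating <- NA_integer_
  if (!"rating_flag" %in% names(raw)) raw$rating_flag <- !is.na(raw$rating)
  tibble::as_tibble(raw)
}

#' Write a trial log as tidy CSV
#'
#' @param records Trial records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_trial_log <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}

#' Read a run configuration from JSON
#'
#' The JSON mirrors [run_config()]'s arguments; absent fields take the
#' defaults. Block designs may be given under `task$blocks` as a list of
#' `{block, n_trials, mean, sd}` objects.
#'
#' @param path JSON file path.
#' @return A `run_config` list.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  js <- jsonlite::read_json(path, simplifyVector = TRUE)
  task_args <- js$task %||% list()
  if (!is.null(task_args$blocks)) {
    task_args$blocks <- tibble::as_tibble(task_args$blocks)
  }
  task <- do.call(task_config, task_args)
  cohort_args <- js$cohort %||% list()
  cohort_args$task <- task
  if (!is.null(cohort_args$param_sampler)) {
    cohort_args$param_sampler <- tibble::as_tibble(cohort_args$param_sampler)
  }
  run_config(
    cohort = do.call(cohort_spec, cohort_args),
    models = js$models %||% MODEL_IDS,
    optimizer = do.call(optimizer_config, as.list(js$optimizer %||% list())),
    q = js$analysis$q %||% 0.05,
    window = js$analysis$window %||% 5L,
    seed = js$seed %||% 1L
  )
}

#' Assemble a full analysis run configuration
#'
#' @param cohort A [cohort_spec()].
#' @param models Model ids to fit.
#' @param optimizer An [optimizer_config()].
#' @param q FDR level for the per-offer-size contrasts.
#' @param window Sliding-window length in trials.
#' @param seed Master seed for the run.
#' @return A list of class `run_config` with a `fingerprint` hash of its
#'   settings for provenance.
#' @export
run_config <- function(cohort = cohort_spec(), models = MODEL_IDS,
                       optimizer = optimizer_config(), q = 0.05,
                       window = 5L, seed = 1L) {
  cfg <- list(cohort = cohort, models = models, optimizer = optimizer,
              q = q, window = window, seed = as.integer(seed))
  cfg$fingerprint <- config_fingerprint(cfg)
  structure(cfg, class = "run_config")
}

# compact deterministic hash of the serialized settings (provenance stamp)
config_fingerprint <- function(cfg) {
  cfg$fingerprint <- NULL
  ser <- jsonlite::toJSON(rapply(cfg, unclass, how = "replace"),
                          auto_unbox = TRUE, digits = NA, force = TRUE)
  sum_ <- sum(utf8ToInt(as.character(ser)) * (seq_along(utf8ToInt(as.character(ser))) %% 97 + 1))
  sprintf("%08x", sum_ %% .Machine$integer.max)
}

#' Run the full simulate-fit-compare-behavior pipeline
#'
#' Simulates a cohort under the configured generating model, fits all
#' configured models per participant, compares them by summed BIC/AIC, and
#' computes the model-free statistics (block contrast, per-offer-size
#' contrasts with FDR correction, sliding-window curve, offer-size
#' regression, rating contrast). Outputs are a pure function of the
#' configuration and seed.
#'
#' @param config A [run_config()].
#' @param out_dir Optional directory; when given, trial logs, truth, fits
#'   and a JSON report (stamped with the config fingerprint and seed) are
#'   written there.
#' @return A list: `trials`, `true_params`, `fits`, `comparison`,
#'   `behavior` (list of the statistics), `config`.
#' @export
run_pipeline <- function(config = run_config(), out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  cohort <- simulate_cohort(config$cohort, seed = config$seed)
  fits <- fit_cohort(cohort$trials, config$models, config = config$optimizer)
  comparison <- compare_models(fits)
  behavior <- list(
    block_contrast = block_contrast(cohort$trials),
    offer_size_contrasts = offer_size_contrasts(
      cohort$trials, q = config$q,
      min_n = min(5L, config$cohort$n_participants)),
    sliding = sliding_rejection(cohort$trials, window = config$window),
    offer_regression = tryCatch(
      suppressWarnings(offer_size_regression(
        cohort$trials, endowment = config$cohort$task$endowment)),
      error = function(e) NULL
    ),
    rating_contrast = suppressWarnings(rating_contrast(cohort$trials))
  )
  result <- list(trials = cohort$trials, true_params = cohort$params,
                 fits = fits, comparison = comparison, behavior = behavior,
                 config = config)
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- list(fingerprint = result$config$fingerprint,
                seed = result$config$seed,
                package_version = as.character(utils::packageVersion("normadapt")))
  readr::write_csv(result$trials, file.path(out_dir, "trials.csv"))
  readr::write_csv(result$true_params, file.path(out_dir, "true_params.csv"))
  readr::write_csv(result$fits, file.path(out_dir, "fits.csv"))
  beh <- result$behavior
  report <- list(
    provenance = stamp,
    comparison = list(table = result$comparison$table,
                      winner_bic = result$comparison$winner_bic,
                      winner_aic = result$comparison$winner_aic),
    block_contrast = unclass(beh$block_contrast),
    offer_size_tests = beh$offer_size_contrasts$tests,
    bh = as.data.frame(beh$offer_size_contrasts$bh),
    bh_cutoff_p = attr(beh$offer_size_contrasts$bh, "cutoff_p"),
    offer_regression = if (!is.null(beh$offer_regression)) {
      beh$offer_regression[c("coefficient", "odds_ratio", "ci", "z", "p",
                             "method")]
    },
    rating_contrast = unclass(beh$rating_contrast)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       force = TRUE)
  invisible(out_dir)
}
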