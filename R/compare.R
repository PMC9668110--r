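#' Compare models by summed BIC and AIC
#'
#' Sums each model's per-participant BIC and AIC over the (identical)
#' participant set and selects the winner as the argmin of each sum, exactly
#' as in summed-score model selection. When BIC and AIC disagree the
#' disagreement is flagged, not resolved; BIC is treated as primary. A
#' per-participant winner count (by BIC) is reported as supplementary
#' output.
#'
#' @param fits A `ug_fits` tibble from [fit_cohort()], covering every model
#'   for every participant.
#' @return A list of class `ug_comparison`: `table` (per model: `sum_bic`,
#'   `sum_aic`, `n_participants`, `n_best_bic`), `winner_bic`, `winner_aic`,
#'   `agreement` (logical).
#' @export
compare_models <- function(fits) {
  coverage <- dplyr::count(fits, .data$participant_id, .data$model_id)
  holes <- tidyr::complete(coverage, .data$participant_id, .data$model_id,
                           fill = list(n = 0L))
  missing <- dplyr::filter(holes, .data$n == 0L)
  if (nrow(missing) > 0) {
    abort(paste0(
      "Missing fits for: ",
      paste(missing$participant_id, missing$model_id,
            sep = "/", collapse = ", ")
    ))
  }
  per_part_best <- fits |>
    dplyr::slice_min(.data$bic, n = 1, by = "participant_id",
                     with_ties = FALSE) |>
    dplyr::count(.data$model_id, name = "n_best_bic")
  tab <- fits |>
    dplyr::summarise(
      sum_bic = sum(.data$bic),
      sum_aic = sum(.data$aic),
      n_participants = dplyr::n_distinct(.data$participant_id),
      .by = "model_id"
    ) |>
    dplyr::left_join(per_part_best, by = "model_id") |>
    dplyr::mutate(n_best_bic = dplyr::coalesce(.data$n_best_bic, 0L)) |>
    dplyr::arrange(.data$sum_bic)
  winner_bic <- tab$model_id[which.min(tab$sum_bic)]
  winner_aic <- tab$model_id[which.min(tab$sum_aic)]
  structure(
    list(table = tab, winner_bic = winner_bic, winner_aic = winner_aic,
         agreement = identical(winner_bic, winner_aic)),
    class = "ug_comparison"
  )
}

#' @export
print.ug_comparison <- function(x, ...) {
  cat("<ug_comparison> winner (BIC):", x$winner_bic)
  if (!x$agreement) {
    cat("  [AIC disagrees:", x$winner_aic, "]")
  }
  cat("\n")
  print(x$table)
  invisible(x)
}

#' Summarize true-versus-fitted parameter recovery
#'
#' For each free parameter of the generating model, computes the bias
#' (mean fitted minus true), RMSE, and Spearman rank correlation between
#' true and fitted values across participants.
#'
#' @param true_params Truth table from [simulate_cohort()] (`participant_id`,
#'   `model_id`, parameter columns).
#' @param fits Fits of the same model to the simulated data.
#' @return A tibble with columns `param`, `bias`, `rmse`, `rank_cor`, `n`.
#' @export
parameter_recovery <- function(true_params, fits) {
  model_id <- unique(true_params$model_id)
  fits <- dplyr::filter(fits, .data$model_id %in% !!model_id)
  if (nrow(fits) == 0 || !identical(sort(unique(fits$model_id)), sort(model_id))) {
    abort("`fits` must contain fits of the generating model.")
  }
  pnames <- free_param_names(model_id[1])
  joined <- dplyr::inner_join(
    dplyr::select(true_params, "participant_id", dplyr::all_of(pnames)),
    dplyr::select(fits, "participant_id", dplyr::all_of(pnames)),
    by = "participant_id", suffix = c("_true", "_fit")
  )
  if (nrow(joined) == 0) abort("No matching participant_ids between truth and fits.")
  purrr::list_rbind(purrr::map(pnames, function(p) {
    tr <- joined[[paste0(p, "_true")]]
    ft <- joined[[paste0(p, "_fit")]]
    tibble::tibble(
      param = p,
      bias = mean(ft - tr),
      rmse = sqrt(mean((ft - tr)^2)),
      rank_cor = suppressWarnings(cor(tr, ft, method = "spearman")),
      n = length(tr)
    )
  }))
}

#' Model-recovery confusion study
#'
#' For each generating model, simulates `n_replicates` cohorts, fits all
#' candidate models to each, and records how often each candidate wins the
#' summed-BIC comparison. Each confusion row sums to 1.
#'
#' @param generating_ids Models to generate from.
#' @param candidate_ids Models fitted to each cohort (default all six).
#' @param spec A [cohort_spec()]; its `model_id` is overridden per
#'   generating model.
#' @param n_replicates Cohorts per generating model.
#' @param seed Master seed.
#' @param config An [optimizer_config()].
#' @return A list of class `ug_recovery`: `confusion` (tibble
#'   `generating_model`, `winner`, `fraction`), `winners` (per-replicate
#'   detail).
#' @export
model_recovery <- function(generating_ids = MODEL_IDS,
                           candidate_ids = MODEL_IDS,
                           spec = cohort_spec(),
                           n_replicates = 10L,
                           seed = 1L,
                           config = optimizer_config()) {
  if (n_replicates < 1) abort("`n_replicates` must be >= 1.")
  seeds <- derive_seeds(seed, length(generating_ids) * n_replicates)
  grid <- tidyr::expand_grid(generating_model = generating_ids,
                             replicate = seq_len(n_replicates))
  grid$seed <- seeds
  winners <- purrr::pmap(grid, function(generating_model, replicate, seed) {
    gspec <- cohort_spec(
      model_id = generating_model,
      n_participants = spec$n_participants,
      task = spec$task,
      rating_slope = spec$rating_slope,
      rating_intercept = spec$rating_intercept,
      rating_noise_sd = spec$rating_noise_sd
    )
    if (identical(generating_model, spec$model_id)) {
      gspec$param_sampler <- spec$param_sampler
    }
    cohort <- simulate_cohort(gspec, seed = seed)
    fits <- fit_cohort(cohort$trials, candidate_ids, config = config)
    compare_models(fits)$winner_bic
  })
  grid$winner <- unlist(winners)
  confusion <- grid |>
    dplyr::count(.data$generating_model, .data$winner) |>
    dplyr::mutate(fraction = .data$n / sum(.data$n),
                  .by = "generating_model") |>
    dplyr::select(-"n")
  structure(list(confusion = confusion, winners = grid),
            class = "ug_recovery")
}

#' @export
print.ug_recovery <- function(x, ...) {
  cat("<ug_recovery> summed-BIC winner fractions by generating model\n")
  print(tidyr::pivot_wider(x$confusion, names_from = "winner",
                           values_from = "fraction", values_fill = 0))
  invisible(x)
}
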