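#' Tidy a table of model fits
#'
#' One row per (participant, model, parameter) with the fitted value.
#'
#' @param x A `ug_fits` tibble.
#' @param ... Unused.
#' @return A long tibble: `participant_id`, `model_id`, `param`, `estimate`.
#' @method tidy ug_fits
#' @export
tidy.ug_fits <- function(x, ...) {
  x |>
    tibble::as_tibble() |>
    tidyr::pivot_longer(
      dplyr::any_of(c("alpha", "beta", "gamma", "epsilon", "initial_norm")),
      names_to = "param", values_to = "estimate"
    ) |>
    dplyr::filter(!is.na(.data$estimate)) |>
    dplyr::filter(purrr::map2_lgl(.data$param, .data$model_id,
                                  ~ .x %in% free_param_names(.y))) |>
    dplyr::select("participant_id", "model_id", "param", "estimate")
}

#' Per-model fit summary
#'
#' @param x A `ug_fits` tibble.
#' @param ... Unused.
#' @return A tibble per model: `n_participants`, `sum_log_likelihood`,
#'   `sum_bic`, `sum_aic`, `n_free`, `prop_converged`.
#' @method glance ug_fits
#' @export
glance.ug_fits <- function(x, ...) {
  x |>
    tibble::as_tibble() |>
    dplyr::summarise(
      n_participants = dplyr::n_distinct(.data$participant_id),
      sum_log_likelihood = sum(.data$log_likelihood),
      sum_bic = sum(.data$bic),
      sum_aic = sum(.data$aic),
      n_free = .data$n_free[1],
      prop_converged = mean(.data$converged),
      .by = "model_id"
    )
}

#' Tidy a model comparison
#'
#' @param x A `ug_comparison`.
#' @param ... Unused.
#' @return The per-model table with a `winner_bic` flag.
#' @method tidy ug_comparison
#' @export
tidy.ug_comparison <- function(x, ...) {
  dplyr::mutate(x$table, winner_bic = .data$model_id == x$winner_bic)
}

#' One-row comparison summary
#'
#' @param x A `ug_comparison`.
#' @param ... Unused.
#' @return A one-row tibble: `winner_bic`, `winner_aic`, `agreement`,
#'   `n_models`, `n_participants`.
#' @method glance ug_comparison
#' @export
glance.ug_comparison <- function(x, ...) {
  tibble::tibble(
    winner_bic = x$winner_bic,
    winner_aic = x$winner_aic,
    agreement = x$agreement,
    n_models = nrow(x$table),
    n_participants = x$table$n_participants[1]
  )
}

#' Tidy a paired contrast
#'
#' @param x A `ug_paired`.
#' @param ... Unused.
#' @return A one-row tibble with the test statistics and effect size.
#' @method tidy ug_paired
#' @export
tidy.ug_paired <- function(x, ...) {
  tibble::tibble(
    t = x$t, df = x$df, p = x$p, mean_diff = x$mean_diff,
    sem_diff = x$sem_diff, cohens_d = x$cohens_d,
    ci_d_low = x$ci_d[1], ci_d_high = x$ci_d[2], n = x$n
  )
}

#' Tidy an offer-size regression
#'
#' @param x A `ug_offer_glm`.
#' @param ... Unused.
#' @return A one-row tibble: coefficient (log-odds of rejection per token
#'   decrease in offer), odds ratio and CI, z, p and fitting method.
#' @method tidy ug_offer_glm
#' @export
tidy.ug_offer_glm <- function(x, ...) {
  tibble::tibble(
    term = "offer_deficit",
    estimate = x$coefficient,
    odds_ratio = x$odds_ratio,
    conf_low = x$ci[1], conf_high = x$ci[2],
    z = x$z, p = x$p, method = x$method
  )
}
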