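# shared fixtures, built once per test run
fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(fixture_env[[name]])) fixture_env[[name]] <- builder()
  fixture_env[[name]]
}

tiny_cohort <- function() {
  fixture("tiny_cohort", function() {
    simulate_cohort(cohort_spec(n_participants = 4L), seed = 42L)
  })
}

tiny_fits <- function() {
  fixture("tiny_fits", function() {
    fit_cohort(tiny_cohort()$trials,
               config = optimizer_config(n_restarts = 5L, seed = 7L))
  })
}

monotone_cohort <- function() {
  fixture("monotone_cohort", function() {
    simulate_cohort(cohort_spec(
      n_participants = 12L,
      param_sampler = tibble::tibble(
        param = c("alpha", "beta", "gamma", "epsilon"),
        mean = c(3, 0, 2, 0.15), sd = c(0.5, 0, 0.5, 0.05)
      )
    ), seed = 77)
  })
}

# hand-built fits table with chosen scores, for aggregation tests
fake_fits <- function(bics, aics = bics, model_ids = names(bics)) {
  rows <- purrr::list_rbind(purrr::map(model_ids, function(m) {
    tibble::tibble(
      participant_id = sprintf("p%02d", seq_along(bics[[m]])),
      model_id = m,
      alpha = 1, beta = 0, gamma = 1, epsilon = NA_real_, initial_norm = 10,
      log_likelihood = -1,
      n_free = 3L, n_trials = 60L,
      bic = bics[[m]], aic = aics[[m]],
      n_restarts_used = 1L, converged = TRUE
    )
  }))
  class(rows) <- c("ug_fits", class(rows))
  rows
}

# a deterministic threshold responder: accept iff offer clears the cutoff
threshold_records <- function(schedule, cutoff = 8.5,
                              participant_id = "thr") {
  tibble::tibble(
    participant_id = participant_id,
    trial = schedule$trial,
    block = schedule$block,
    offer = schedule$offer,
    rating_flag = schedule$rating_flag,
    choice = ifelse(schedule$offer > cutoff, "accept", "reject"),
    rating = NA_integer_
  )
}
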