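#' Simulate one responder playing a schedule
#'
#' Each trial's acceptance probability is the softmax of the Fehr-Schmidt
#' utility at the current norm; the choice is a Bernoulli draw and the norm
#' then evolves per the model's update rule (from the offer alone).
#'
#' @param params An [agent_params()].
#' @param schedule A schedule tibble from [make_schedule()].
#' @param seed Integer seed; identical `(params, schedule, seed)` give
#'   identical records.
#' @param participant_id Identifier stored with the records.
#' @return A tibble of trial records: `participant_id`, `trial`, `block`,
#'   `offer`, `rating_flag`, `norm` (the pre-update norm used at that
#'   trial), `p_accept`, `choice` (`"accept"`/`"reject"`), `rating` (NA
#'   until [simulate_ratings()] fills flagged trials).
#' @export
#' @examples
#' sched <- make_schedule(task_config(), seed = 1)
#' params <- agent_params("RW_fixed", 2.58, 0.17, 1.78, epsilon = 0.16)
#' simulate_agent(params, sched, seed = 2)
simulate_agent <- function(params, schedule, seed = 1L,
                           participant_id = "p01") {
  stopifnot(inherits(params, "agent_params"))
  norms <- norm_trajectory(params, schedule)
  p <- p_accept(fs_utility(schedule$offer, norms, params$alpha, params$beta),
                params$gamma)
  accepted <- withr::with_seed(seed, runif(nrow(schedule)) < p)
  tibble::tibble(
    participant_id = participant_id,
    trial = schedule$trial,
    block = schedule$block,
    offer = schedule$offer,
    rating_flag = schedule$rating_flag,
    norm = norms,
    p_accept = p,
    choice = ifelse(accepted, "accept", "reject"),
    rating = NA_integer_
  )
}

#' Fill in synthetic emotion ratings
#'
#' A deliberately simple synthetic generator for the 1-9 happiness rating:
#' linear in offer size with Gaussian noise, rounded and clipped to the
#' scale. It exists to exercise the rating analyses; no generative model of
#' children's ratings is claimed.
#'
#' @param records Trial records with `rating_flag` and `offer` columns.
#' @param slope,intercept Rating = `intercept + slope * offer` (+ noise).
#' @param noise_sd Gaussian noise SD on the rating scale.
#' @param seed Integer seed.
#' @return `records` with `rating` filled on flagged trials (1-9 integers).
#' @export
simulate_ratings <- function(records, slope = 0.6, intercept = 1.0,
                             noise_sd = 1.0, seed = 1L) {
  flagged <- records$rating_flag
  n <- sum(flagged)
  noise <- withr::with_seed(seed, rnorm(n, 0, noise_sd))
  raw <- intercept + slope * records$offer[flagged] + noise
  records$rating <- NA_integer_
  records$rating[flagged] <-
    as.integer(pmin(pmax(round_half_away(raw), 1), 9))
  records
}

#' Specify a synthetic cohort
#'
#' Defaults emulate the study conditions: 30 responders, 60 trials in three
#' 20-trial blocks, and per-participant model parameters drawn from
#' independent truncated Gaussians centered on the fitted-sample moments
#' (envy 2.58 +/- 2.53, guilt 0.17 +/- 0.32, temperature 1.78 +/- 1.58,
#' learning rate 0.16 +/- 0.28), truncated to each parameter's bounds. Each
#' participant receives an independently sampled offer schedule.
#'
#' @param model_id Generating model (default `"RW_fixed"`, the winning
#'   model).
#' @param n_participants Cohort size (default 30).
#' @param task A [task_config()].
#' @param param_sampler A tibble with columns `param`, `mean`, `sd` giving
#'   the truncated-Gaussian sampler for each free parameter; defaults as
#'   above, with the initial norm (when free) centered at 10 +/- 3.
#' @param rating_slope,rating_intercept,rating_noise_sd Passed to
#'   [simulate_ratings()].
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(model_id = "RW_fixed",
                        n_participants = 30L,
                        task = task_config(),
                        param_sampler = NULL,
                        rating_slope = 0.6,
                        rating_intercept = 1.0,
                        rating_noise_sd = 1.0) {
  check_model_id(model_id)
  if (n_participants < 1) abort("`n_participants` must be >= 1.")
  defaults <- tibble::tibble(
    param = c("alpha", "beta", "gamma", "epsilon", "initial_norm"),
    mean = c(2.58, 0.17, 1.78, 0.16, 10),
    sd = c(2.53, 0.32, 1.58, 0.28, 3)
  )
  if (is.null(param_sampler)) {
    param_sampler <- defaults
  } else {
    param_sampler <- dplyr::rows_update(defaults,
                                        tibble::as_tibble(param_sampler),
                                        by = "param")
  }
  param_sampler <- dplyr::filter(param_sampler,
                                 .data$param %in% free_param_names(model_id))
  structure(
    list(model_id = model_id,
         n_participants = as.integer(n_participants),
         task = task,
         param_sampler = param_sampler,
         rating_slope = rating_slope,
         rating_intercept = rating_intercept,
         rating_noise_sd = rating_noise_sd),
    class = "cohort_spec"
  )
}

sample_cohort_params <- function(spec, seed) {
  bounds <- param_bounds(spec$model_id, endowment = spec$task$endowment)
  sampler <- dplyr::left_join(spec$param_sampler, bounds, by = "param")
  draws <- withr::with_seed(seed, {
    purrr::pmap(sampler, function(param, mean, sd, lower, upper) {
      rtrunc_norm(spec$n_participants, mean, sd, lower, upper)
    })
  })
  out <- tibble::as_tibble(setNames(draws, sampler$param))
  out$participant_id <- sprintf("p%02d", seq_len(spec$n_participants))
  out$model_id <- spec$model_id
  dplyr::select(out, "participant_id", "model_id", dplyr::everything())
}

row_to_params <- function(row) {
  agent_params(
    model_id = row$model_id,
    alpha = row$alpha, beta = row$beta, gamma = row$gamma,
    epsilon = row[["epsilon"]] %||% NULL,
    initial_norm = row[["initial_norm"]] %||% 10
  )
}

#' Simulate a full study-like cohort
#'
#' Samples per-participant parameters from the spec's truncated-Gaussian
#' sampler, draws an independent offer schedule per participant, simulates
#' choices under the generating model, and fills synthetic ratings on
#' flagged trials.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer master seed; all schedule, choice, parameter and
#'   rating randomness derives from it.
#' @return A list with `trials` (tidy trial records, one row per trial) and
#'   `params` (true generating parameters keyed by `participant_id`).
#' @export
#' @examples
#' cohort <- simulate_cohort(cohort_spec(n_participants = 3), seed = 1)
#' dplyr::count(cohort$trials, participant_id)
simulate_cohort <- function(spec = cohort_spec(), seed = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  seeds <- derive_seeds(seed, 3L * spec$n_participants + 1L)
  truth <- sample_cohort_params(spec, seeds[1])
  idx <- seq_len(spec$n_participants)
  trials <- purrr::list_rbind(purrr::map(idx, function(i) {
    sched <- make_schedule(spec$task, seed = seeds[1 + i])
    rec <- simulate_agent(row_to_params(truth[i, ]), sched,
                          seed = seeds[1 + spec$n_participants + i],
                          participant_id = truth$participant_id[i])
    simulate_ratings(rec,
                     slope = spec$rating_slope,
                     intercept = spec$rating_intercept,
                     noise_sd = spec$rating_noise_sd,
                     seed = seeds[1 + 2L * spec$n_participants + i])
  }))
  list(trials = trials, params = truth)
}
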