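#' Optimizer settings for maximum-likelihood fitting
#'
#' Fitting uses bounded L-BFGS-B local searches from multiple start points:
#' one start at the midpoint of every bound plus `n_restarts` uniform draws
#' within the bounds, all seed-controlled. The best (lowest) NLL wins, ties
#' broken by first-found.
#'
#' @param n_restarts Number of uniform random restarts (default 10).
#' @param seed Integer seed for the restart draws.
#' @param factr L-BFGS-B convergence tolerance scale factor (default
#'   corresponds to ~1e-8 relative NLL tolerance).
#' @param maxit Maximum iterations per start.
#' @param gamma_max Upper bound for the inverse temperature.
#' @return A list of class `optimizer_config`.
#' @export
optimizer_config <- function(n_restarts = 10L, seed = 1L,
                             factr = 1e7, maxit = 200L, gamma_max = 10) {
  structure(list(n_restarts = as.integer(n_restarts), seed = as.integer(seed),
                 factr = factr, maxit = as.integer(maxit),
                 gamma_max = gamma_max),
            class = "optimizer_config")
}

params_from_vector <- function(theta, model_id) {
  th <- as.list(theta)
  agent_params(model_id,
               alpha = th$alpha, beta = th$beta, gamma = th$gamma,
               epsilon = th$epsilon %||% NULL,
               initial_norm = th$initial_norm %||% 10)
}

#' Fit one participant's choices by maximum likelihood
#'
#' Minimizes the choice negative log-likelihood over the model's free
#' parameters within their bounds, using seeded multi-start L-BFGS-B.
#' BIC and AIC use the number of choice trials as the sample size.
#'
#' @param records Trial records for a single participant (columns `offer`,
#'   `choice`; extra columns ignored).
#' @param model_id Model to fit (see [free_param_names()]).
#' @param config An [optimizer_config()].
#' @param extra_starts Optional list of named start vectors appended to the
#'   restart set (used internally to warm-start `_free` variants from the
#'   fixed-norm solution).
#' @return One-row tibble: `participant_id`, `model_id`, one column per free
#'   parameter (NA for parameters the model lacks), `log_likelihood`,
#'   `n_free`, `n_trials`, `bic`, `aic`, `n_restarts_used`, `converged`.
#' @export
#' @examples
#' sched <- make_schedule(task_config(), seed = 1)
#' rec <- simulate_agent(agent_params("FS_fixed", 2, 0, 2), sched, seed = 2)
#' fit_participant(rec, "FS_fixed", optimizer_config(n_restarts = 3))
fit_participant <- function(records, model_id,
                            config = optimizer_config(),
                            extra_starts = NULL) {
  check_model_id(model_id)
  offers <- pull_offers(records)
  accepted <- parse_choices(records)
  if (length(offers) == 0) abort("No choice trials to fit.")
  bounds <- param_bounds(model_id, gamma_max = config$gamma_max)
  pnames <- bounds$param

  fam <- model_family(model_id)
  free_norm <- model_has_free_norm(model_id)
  n_obs <- length(offers)
  objective <- function(theta) {
    nrm0 <- if (free_norm) theta[length(theta)] else 10
    norms <- switch(fam,
      FS = rep(nrm0, n_obs),
      RW = rw_trajectory(offers, nrm0, theta[4]),
      BO = bo_trajectory(offers, nrm0)
    )
    nll_from_norms(offers, norms, accepted, theta[1], theta[2], theta[3])
  }

  midpoint <- (bounds$lower + bounds$upper) / 2
  random_starts <- withr::with_seed(config$seed, {
    purrr::map(seq_len(config$n_restarts), function(i) {
      runif(length(pnames), bounds$lower, bounds$upper)
    })
  })
  starts <- c(list(midpoint), random_starts)
  for (es in extra_starts %||% list()) {
    starts <- c(starts, list(unname(es[pnames])))
  }

  best <- NULL
  any_converged <- FALSE
  for (s in starts) {
    res <- tryCatch(
      optim(s, objective, method = "L-BFGS-B",
            lower = bounds$lower, upper = bounds$upper,
            control = list(factr = config$factr, maxit = config$maxit)),
      error = function(e) list(par = s, value = objective(s),
                               convergence = 52L)
    )
    if (res$convergence == 0) any_converged <- TRUE
    if (is.null(best) || res$value < best$value - 1e-12) best <- res
  }

  theta <- setNames(best$par, pnames)
  n_trials <- length(offers)
  k <- length(pnames)
  ll <- -best$value
  out <- tibble::tibble(
    participant_id = if ("participant_id" %in% names(records)) {
      records$participant_id[1]
    } else NA_character_,
    model_id = model_id,
    alpha = theta[["alpha"]],
    beta = theta[["beta"]],
    gamma = theta[["gamma"]],
    epsilon = if ("epsilon" %in% pnames) theta[["epsilon"]] else NA_real_,
    initial_norm = if ("initial_norm" %in% pnames) {
      theta[["initial_norm"]]
    } else 10,
    log_likelihood = ll,
    n_free = k,
    n_trials = n_trials,
    bic = k * log(n_trials) - 2 * ll,
    aic = 2 * k - 2 * ll,
    n_restarts_used = length(starts),
    converged = any_converged
  )
  as_ug_fits(out)
}

as_ug_fits <- function(x) {
  class(x) <- unique(c("ug_fits", class(x)))
  x
}

#' Fit every model to every participant
#'
#' Fixed-norm variants are fitted before their free-norm counterparts so the
#' free fit can be warm-started from the fixed solution (with the norm at
#' 10), guaranteeing the nested model never scores a worse likelihood.
#'
#' @param trials Tidy trial records for the cohort (`participant_id`,
#'   `offer`, `choice`).
#' @param model_ids Models to fit (default all six).
#' @param config An [optimizer_config()].
#' @return A `ug_fits` tibble with one row per (participant, model).
#' @export
fit_cohort <- function(trials, model_ids = MODEL_IDS,
                       config = optimizer_config()) {
  purrr::walk(model_ids, check_model_id)
  # fixed variants first so free variants can reuse their solution
  ord <- model_ids[order(model_has_free_norm(model_ids))]
  by_part <- split(trials, trials$participant_id)
  fits <- purrr::list_rbind(purrr::map(by_part, function(rec) {
    fixed_solutions <- list()
    purrr::list_rbind(purrr::map(ord, function(mid) {
      extra <- NULL
      fixed_id <- sub("_free$", "_fixed", mid)
      if (model_has_free_norm(mid) && !is.null(fixed_solutions[[fixed_id]])) {
        extra <- list(c(fixed_solutions[[fixed_id]], initial_norm = 10))
      }
      fit <- fit_participant(rec, mid, config = config, extra_starts = extra)
      if (!model_has_free_norm(mid)) {
        sol <- unlist(fit[1, free_param_names(mid)])
        fixed_solutions[[mid]] <<- sol
      }
      fit
    }))
  }))
  as_ug_fits(fits)
}

#' Exhaustive coarse-grid likelihood search
#'
#' Evaluates the choice NLL on a regular grid of `n_points` values per free
#' parameter (bound endpoints included) and returns the best node. Serves as
#' a brute-force check that the local optimizer is not trapped far from the
#' global optimum. The evaluation is vectorized over the inequity and
#' temperature parameters for each candidate norm trajectory.
#'
#' @inheritParams fit_participant
#' @param n_points Grid points per free parameter (default 11).
#' @param gamma_max Upper bound for the inverse temperature.
#' @return A list with `nll` (best grid NLL) and `params` (named vector of
#'   the best node).
#' @export
grid_search <- function(records, model_id, n_points = 11L, gamma_max = 10) {
  check_model_id(model_id)
  offers <- pull_offers(records)
  accepted <- parse_choices(records)
  bounds <- param_bounds(model_id, gamma_max = gamma_max)
  grids <- purrr::pmap(bounds, function(param, lower, upper) {
    seq(lower, upper, length.out = n_points)
  })
  names(grids) <- bounds$param

  traj_grid <- expand.grid(
    epsilon = grids$epsilon %||% NA_real_,
    initial_norm = grids$initial_norm %||% 10
  )
  ab <- expand.grid(alpha = grids$alpha, beta = grids$beta)
  sgn <- ifelse(accepted, 1, -1)

  best <- list(nll = Inf, params = NULL)
  for (i in seq_len(nrow(traj_grid))) {
    eps <- traj_grid$epsilon[i]
    nrm0 <- traj_grid$initial_norm[i]
    fam <- model_family(model_id)
    norms <- switch(fam,
      FS = rep(nrm0, length(offers)),
      RW = rw_trajectory(offers, nrm0, eps),
      BO = bo_trajectory(offers, nrm0)
    )
    d_neg <- pmax(norms - offers, 0)
    d_pos <- pmax(offers - norms, 0)
    # utilities for all (alpha, beta) nodes at once: nodes x trials
    u <- matrix(offers, nrow(ab), length(offers), byrow = TRUE) -
      outer(ab$alpha, d_neg) - outer(ab$beta, d_pos)
    for (g in grids$gamma) {
      lp <- plogis(sweep(u * g, 2, sgn, `*`), log.p = TRUE)
      nlls <- -rowSums(pmax(lp, LOG_P_FLOOR))
      j <- which.min(nlls)
      if (nlls[j] < best$nll) {
        params <- c(alpha = ab$alpha[j], beta = ab$beta[j], gamma = g)
        if (fam == "RW") params <- c(params, epsilon = eps)
        if (model_has_free_norm(model_id)) {
          params <- c(params, initial_norm = nrm0)
        }
        best <- list(nll = nlls[j], params = params)
      }
    }
  }
  best
}
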