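# Registry of the six candidate responder models. "fixed" variants pin the
# initial norm at an equal split (10 of 20 tokens); "free" variants estimate
# it. FS: static norm; BO: Bayesian observer with Normal-Inverse-chi^2
# conjugate updating of the offer distribution; RW: Rescorla-Wagner
# norm-prediction-error updating.
MODEL_IDS <- c("FS_fixed", "FS_free", "BO_fixed", "BO_free",
               "RW_fixed", "RW_free")

model_family <- function(model_id) {
  check_model_id(model_id)
  sub("_.*$", "", model_id)
}

model_has_free_norm <- function(model_id) {
  grepl("_free$", model_id)
}

check_model_id <- function(model_id) {
  if (length(model_id) != 1 || !model_id %in% MODEL_IDS) {
    abort(paste0("Unknown model_id; must be one of: ",
                 paste(MODEL_IDS, collapse = ", ")))
  }
  invisible(model_id)
}

#' Names of a model's free parameters
#'
#' All models estimate envy (`alpha`), guilt (`beta`) and the softmax inverse
#' temperature (`gamma`). Rescorla-Wagner models add the norm learning rate
#' (`epsilon`); `_free` variants add the initial norm (`initial_norm`).
#'
#' @param model_id One of `"FS_fixed"`, `"FS_free"`, `"BO_fixed"`,
#'   `"BO_free"`, `"RW_fixed"`, `"RW_free"`.
#' @return Character vector of free-parameter names.
#' @export
#' @examples
#' free_param_names("RW_free")
free_param_names <- function(model_id) {
  check_model_id(model_id)
  out <- c("alpha", "beta", "gamma")
  if (model_family(model_id) == "RW") out <- c(out, "epsilon")
  if (model_has_free_norm(model_id)) out <- c(out, "initial_norm")
  out
}

#' Number of free parameters of a model
#'
#' @inheritParams free_param_names
#' @return Integer count: 3 (FS/BO fixed), 4 (FS/BO free, RW fixed)
#'   or 5 (RW free).
#' @export
count_free_params <- function(model_id) {
  length(free_param_names(model_id))
}

#' Parameter bounds used for fitting and sampling
#'
#' Envy and guilt weights lie in \[0, 10\], the learning rate in \[0, 1\] and
#' the initial norm in \[0, endowment\]. The inverse temperature defaults to
#' \[0, 10\]: fitted temperatures well above 1 are routinely observed, so the
#' upper bound is configurable rather than pinned at 1.
#'
#' @inheritParams free_param_names
#' @param gamma_max Upper bound for the inverse temperature (default 10).
#' @param endowment Token endowment (upper bound for the initial norm).
#' @return A tibble with columns `param`, `lower`, `upper`.
#' @export
param_bounds <- function(model_id, gamma_max = 10, endowment = 20) {
  all_bounds <- tibble::tibble(
    param = c("alpha", "beta", "gamma", "epsilon", "initial_norm"),
    lower = c(0, 0, 0, 0, 0),
    upper = c(10, 10, gamma_max, 1, endowment)
  )
  dplyr::filter(all_bounds, .data$param %in% free_param_names(model_id))
}

#' Bundle responder-model parameters
#'
#' @inheritParams free_param_names
#' @param alpha Envy weight: disutility per token of receiving less than the
#'   norm (\[0, 10\]).
#' @param beta Guilt weight: disutility per token of receiving more than the
#'   norm (\[0, 10\]).
#' @param gamma Softmax inverse temperature (>= 0); 0 means choices at
#'   chance.
#' @param epsilon Norm learning rate in \[0, 1\] (Rescorla-Wagner models
#'   only).
#' @param initial_norm Starting norm in tokens; forced to 10 (the equal
#'   split) for `_fixed` variants.
#' @return A list of class `agent_params`.
#' @export
#' @examples
#' agent_params("RW_fixed", alpha = 2.58, beta = 0.17, gamma = 1.78,
#'              epsilon = 0.16)
agent_params <- function(model_id, alpha, beta, gamma,
                         epsilon = NULL, initial_norm = 10) {
  check_model_id(model_id)
  if (model_family(model_id) == "RW") {
    if (is.null(epsilon)) abort("RW models require `epsilon`.")
    if (epsilon < 0 || epsilon > 1) abort("`epsilon` must be in [0, 1].")
  } else if (!is.null(epsilon)) {
    abort("`epsilon` is only meaningful for RW models.")
  }
  if (!model_has_free_norm(model_id) && initial_norm != 10) {
    abort("`_fixed` variants pin initial_norm at 10.")
  }
  if (alpha < 0 || beta < 0 || gamma < 0) {
    abort("alpha, beta and gamma must be non-negative.")
  }
  structure(
    list(model_id = model_id, alpha = alpha, beta = beta, gamma = gamma,
         epsilon = epsilon, initial_norm = initial_norm),
    class = "agent_params"
  )
}

#' @export
print.agent_params <- function(x, ...) {
  vals <- unlist(x[free_param_names(x$model_id)])
  cat("<agent_params>", x$model_id, "\n")
  print(round(vals, 4))
  invisible(x)
}

#' Fehr-Schmidt inequity-aversion utility of an offer
#'
#' `U = s - alpha * max(norm - s, 0) - beta * max(s - norm, 0)`: the offer's
#' token value penalized by envy when it falls below the internal fairness
#' norm and by guilt when it exceeds it. Vectorized over offers and norms.
#'
#' @param offer Offer(s) in tokens.
#' @param norm Internal norm(s) in tokens.
#' @param alpha,beta Envy and guilt weights.
#' @return Utility, same length as the inputs.
#' @export
#' @examples
#' fs_utility(4, 10, alpha = 1, beta = 0.5)   # 4 - 1*6      = -2
#' fs_utility(12, 10, alpha = 1, beta = 0.5)  # 12 - 0.5*2   = 11
fs_utility <- function(offer, norm, alpha, beta) {
  offer - alpha * pmax(norm - offer, 0) - beta * pmax(offer - norm, 0)
}

#' Softmax acceptance probability
#'
#' Logistic of `utility * gamma`. At `gamma = 0` choices are at chance; as
#' `gamma` grows choices become deterministic in the sign of the utility.
#' Numerically stable for large `|utility * gamma|`.
#'
#' @param utility Utility value(s).
#' @param gamma Inverse temperature (>= 0).
#' @return Acceptance probability in (0, 1).
#' @export
#' @examples
#' p_accept(0, 5)    # 0.5
#' p_accept(1, 1)    # plogis(1)
p_accept <- function(utility, gamma) {
  if (any(gamma < 0)) abort("`gamma` must be >= 0.")
  plogis(utility * gamma)
}

#' Rescorla-Wagner norm update
#'
#' `x_t = x_{t-1} + epsilon * (s_t - x_{t-1})`: the norm moves toward the
#' received offer by a fraction `epsilon` of the norm-prediction error.
#'
#' @param norm Current norm in tokens.
#' @param offer Received offer in tokens.
#' @param epsilon Learning rate in \[0, 1\].
#' @return Updated norm (a convex combination of `norm` and `offer`).
#' @export
#' @examples
#' rw_update(10, 4, 0.25)  # 8.5
rw_update <- function(norm, offer, epsilon) {
  if (any(epsilon < 0 | epsilon > 1)) abort("`epsilon` must be in [0, 1].")
  norm + epsilon * (offer - norm)
}

#' Initial Bayesian-observer state
#'
#' The observer treats offers as draws from a Gaussian with unknown mean and
#' variance under a conjugate Normal-Inverse-chi^2 prior with hyperparameters
#' `k` (pseudo-count on the mean), `nu` (degrees of freedom), `mu_hat`
#' (current norm estimate) and `sigma2_hat` (variance estimate). Defaults are
#' `k = 4`, `nu = 10`, `sigma2_hat = 4` with `mu_hat = 10` (equal split).
#'
#' @param mu_hat Initial norm estimate in tokens.
#' @param k,nu,sigma2_hat Prior hyperparameters (all > 0).
#' @return A list of class `bo_state`.
#' @export
bo_state <- function(mu_hat = 10, k = 4, nu = 10, sigma2_hat = 4) {
  if (k <= 0 || nu <= 0 || sigma2_hat <= 0) {
    abort("k, nu and sigma2_hat must be > 0.")
  }
  structure(list(k = k, nu = nu, mu_hat = mu_hat, sigma2_hat = sigma2_hat),
            class = "bo_state")
}

#' Bayesian-observer conjugate update after one offer
#'
#' Increments `k` and `nu` by one, moves `mu_hat` toward the offer with
#' weight `1 / k_t`, and updates the variance estimate via
#' `nu_t * sigma2_t = nu_{t-1} * sigma2_{t-1} +
#'  (k_{t-1} / k_t) * (s_t - mu_hat_{t-1})^2`.
#'
#' @param state A [bo_state()].
#' @param offer Received offer in tokens.
#' @return The updated `bo_state`.
#' @export
#' @examples
#' bo_update(bo_state(), offer = 4)  # mu_hat 8.8, sigma2_hat 68.8/11
bo_update <- function(state, offer) {
  stopifnot(inherits(state, "bo_state"))
  k_new <- state$k + 1
  nu_new <- state$nu + 1
  mu_new <- state$mu_hat + (offer - state$mu_hat) / k_new
  sigma2_new <- (state$nu * state$sigma2_hat +
                   (state$k / k_new) * (offer - state$mu_hat)^2) / nu_new
  bo_state(mu_hat = mu_new, k = k_new, nu = nu_new, sigma2_hat = sigma2_new)
}

#' Per-trial norm trajectory implied by a model
#'
#' Returns the norm used to evaluate each offer: the pre-update value at that
#' trial. The norm is updated after every offer, from the offer alone (the
#' choice plays no role). FS models keep the norm constant; BO models apply
#' the conjugate update; RW models apply the prediction-error rule.
#'
#' @param params An [agent_params()].
#' @param offers Numeric vector of offers, or a schedule/trial tibble with an
#'   `offer` column.
#' @return Numeric vector of norms, one per trial; the first entry equals
#'   `initial_norm`.
#' @export
#' @examples
#' p <- agent_params("RW_fixed", 1, 0, 2, epsilon = 0.5)
#' norm_trajectory(p, c(4, 4))  # 10, 7
norm_trajectory <- function(params, offers) {
  stopifnot(inherits(params, "agent_params"))
  offers <- pull_offers(offers)
  family <- model_family(params$model_id)
  n <- length(offers)
  if (family == "FS") return(rep(params$initial_norm, n))
  if (family == "RW") {
    return(rw_trajectory(offers, params$initial_norm, params$epsilon))
  }
  bo_trajectory(offers, params$initial_norm)
}

pull_offers <- function(offers) {
  if (is.data.frame(offers)) {
    if (!"offer" %in% names(offers)) abort("Data frame needs an `offer` column.")
    offers <- offers$offer
  }
  as.numeric(offers)
}

rw_trajectory <- function(offers, initial_norm, epsilon) {
  n <- length(offers)
  norms <- numeric(n)
  x <- initial_norm
  for (t in seq_len(n)) {
    norms[t] <- x
    x <- x + epsilon * (offers[t] - x)
  }
  norms
}

# BO mean recursion: mu_t = mu_{t-1} + (s_t - mu_{t-1}) / k_t with k_t = k0 + t.
# Only the mean enters the utility, so sigma2/nu are not tracked here.
bo_trajectory <- function(offers, initial_norm, k0 = 4) {
  n <- length(offers)
  norms <- numeric(n)
  mu <- initial_norm
  for (t in seq_len(n)) {
    norms[t] <- mu
    mu <- mu + (offers[t] - mu) / (k0 + t)
  }
  norms
}

# probabilities are clamped inside the log to keep the NLL finite
LOG_P_FLOOR <- log(1e-12)

#' Negative log-likelihood of a choice sequence under a model
#'
#' For each trial the acceptance probability is the softmax of the
#' Fehr-Schmidt utility evaluated at that trial's norm (see
#' [norm_trajectory()]); the NLL is `-sum(log P(choice_t))`. Log
#' probabilities are floored at `log(1e-12)` so the NLL is finite for all
#' in-bound parameters.
#'
#' @param params An [agent_params()].
#' @param offers Offers (vector or tibble with `offer`).
#' @param choices Character vector (`"accept"`/`"reject"`) or logical vector
#'   (`TRUE` = accept) of the same length as `offers`.
#' @return Non-negative scalar NLL.
#' @export
#' @examples
#' p <- agent_params("FS_fixed", 1, 0, 0)
#' negative_log_likelihood(p, rep(8, 60), rep("accept", 60))  # 60 * log(2)
negative_log_likelihood <- function(params, offers, choices) {
  offers <- pull_offers(offers)
  accepted <- parse_choices(choices)
  if (length(offers) != length(accepted)) {
    abort("`offers` and `choices` must have the same length.")
  }
  norms <- norm_trajectory(params, offers)
  nll_from_norms(offers, norms, accepted,
                 params$alpha, params$beta, params$gamma)
}

nll_from_norms <- function(offers, norms, accepted, alpha, beta, gamma) {
  u <- fs_utility(offers, norms, alpha, beta)
  x <- u * gamma
  lp <- plogis(ifelse(accepted, x, -x), log.p = TRUE)
  -sum(pmax(lp, LOG_P_FLOOR))
}

parse_choices <- function(choices) {
  if (is.logical(choices)) return(choices)
  if (is.data.frame(choices)) choices <- choices$choice
  ch <- tolower(as.character(choices))
  out <- ch == "accept" | ch == "1"
  bad <- !(ch %in% c("accept", "reject", "1", "2"))
  if (any(bad)) {
    abort(paste0("Unknown choice code(s): ",
                 paste(unique(ch[bad]), collapse = ", ")))
  }
  out
}
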