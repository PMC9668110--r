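#' Offer distribution for one task block
#'
#' Offers within a block are drawn from a Gaussian in token units, then
#' rounded to integer tokens and clipped into the allowed offer range.
#'
#' @param mean Mean offer in tokens.
#' @param sd Standard deviation in tokens (>= 0; 0 gives a degenerate
#'   distribution at `round(mean)`).
#' @return A list with elements `mean` and `sd`, class `offer_distribution`.
#' @export
#' @examples
#' offer_distribution(8, 1.5)
offer_distribution <- function(mean, sd = 1.5) {
  if (!is.numeric(mean) || !is.numeric(sd) || length(mean) != 1 || length(sd) != 1) {
    abort("`mean` and `sd` must be single numbers.")
  }
  if (sd < 0) abort("`sd` must be >= 0.")
  structure(list(mean = mean, sd = sd), class = "offer_distribution")
}

#' Configure the three-block conditioning Ultimatum Game task
#'
#' The default design is the conditioning paradigm: a 20-trial baseline block
#' of medium offers (mean 8, SD 1.5 tokens of a 20-token endowment), a
#' 20-trial conditioning block of low offers (mean 4, SD 1.5), and a 20-trial
#' post-conditioning block drawn from the same medium distribution as
#' baseline. An emotion-rating prompt follows each offer independently with
#' probability `rating_probability`.
#'
#' @param endowment Total tokens split each trial (integer, default 20).
#' @param blocks A data frame with columns `block` (label), `n_trials`
#'   (integer) and `mean`, `sd` (offer distribution in tokens). Defaults to
#'   the baseline/conditioning/post design described above.
#' @param rating_probability Probability that a trial is followed by a
#'   1-9 emotion rating prompt (default 0.67).
#' @param offer_min,offer_max Integer bounds for emitted offers
#'   (defaults 0 and `endowment`).
#' @return A list of class `task_config`.
#' @export
#' @examples
#' task_config()
task_config <- function(endowment = 20L,
                        blocks = NULL,
                        rating_probability = 0.67,
                        offer_min = 0L,
                        offer_max = endowment) {
  if (is.null(blocks)) {
    blocks <- tibble::tibble(
      block = c("baseline", "conditioning", "post"),
      n_trials = c(20L, 20L, 20L),
      mean = c(8, 4, 8),
      sd = c(1.5, 1.5, 1.5)
    )
  }
  blocks <- tibble::as_tibble(blocks)
  required <- c("block", "n_trials", "mean", "sd")
  if (!all(required %in% names(blocks))) {
    abort(paste0("`blocks` must have columns: ", paste(required, collapse = ", ")))
  }
  if (any(blocks$sd < 0)) abort("Block offer SDs must be >= 0.")
  if (any(blocks$n_trials < 1)) abort("Each block needs at least one trial.")
  if (!(0 <= offer_min && offer_min <= offer_max && offer_max <= endowment)) {
    abort("Need 0 <= offer_min <= offer_max <= endowment.")
  }
  if (rating_probability < 0 || rating_probability > 1) {
    abort("`rating_probability` must be in [0, 1].")
  }
  structure(
    list(
      endowment = as.integer(endowment),
      blocks = blocks,
      rating_probability = rating_probability,
      offer_min = as.integer(offer_min),
      offer_max = as.integer(offer_max)
    ),
    class = "task_config"
  )
}

#' @export
print.task_config <- function(x, ...) {
  cat("<task_config> endowment", x$endowment, "tokens,",
      sum(x$blocks$n_trials), "trials, rating p =", x$rating_probability, "\n")
  print(x$blocks)
  invisible(x)
}

#' Generate a seeded offer schedule
#'
#' Draws each block's offers independently from that block's Gaussian
#' distribution, rounds half-away-from-zero to integer tokens, and clips into
#' `[offer_min, offer_max]`. Rating prompts are independent Bernoulli draws
#' with the configured probability. The same `(config, seed)` pair always
#' yields an identical schedule.
#'
#' @param config A [task_config()].
#' @param seed Integer seed.
#' @return A tibble with one row per trial: `trial` (1-based), `block`,
#'   `offer` (integer tokens) and `rating_flag` (logical).
#' @export
#' @examples
#' sched <- make_schedule(task_config(), seed = 1)
#' dplyr::count(sched, block)
make_schedule <- function(config = task_config(), seed = 1L) {
  stopifnot(inherits(config, "task_config"))
  n_total <- sum(config$blocks$n_trials)
  withr::with_seed(seed, {
    offers <- purrr::pmap(config$blocks, function(block, n_trials, mean, sd) {
      raw <- rnorm(n_trials, mean, sd)
      pmin(pmax(round_half_away(raw), config$offer_min), config$offer_max)
    })
    flags <- runif(n_total) < config$rating_probability
  })
  tibble::tibble(
    trial = seq_len(n_total),
    block = rep(config$blocks$block, config$blocks$n_trials),
    offer = as.integer(unlist(offers)),
    rating_flag = flags
  )
}
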