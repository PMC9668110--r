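#' Per-participant rejection rates
#'
#' Percentage of rejected offers per participant within each block, or
#' within each (block, offer size) cell. Cells with no trials are simply
#' absent (never 0/0).
#'
#' @param records Trial records (`participant_id`, `block`, `offer`,
#'   `choice`).
#' @param by `"block"` or `"block_offer"`.
#' @return A tibble with `participant_id`, `block`, optionally `offer`,
#'   `n_trials`, `rejection_rate` (percent, 0-100).
#' @export
rejection_rates <- function(records, by = c("block", "block_offer")) {
  by <- match.arg(by)
  groups <- if (by == "block") {
    c("participant_id", "block")
  } else {
    c("participant_id", "block", "offer")
  }
  records |>
    dplyr::mutate(rejected = !parse_choices(.data$choice)) |>
    dplyr::summarise(
      n_trials = dplyr::n(),
      rejection_rate = 100 * mean(.data$rejected),
      .by = dplyr::all_of(groups)
    )
}

#' Sliding-window rejection curve
#'
#' Mean rejection percentage over a trailing window of trials (the window
#' ending at trial `t`, so the curve starts at trial `window`), computed per
#' participant and averaged across participants.
#'
#' @param records Trial records.
#' @param window Window length in trials (default 5).
#' @return A tibble with `trial`, `rejection_rate` (percent, averaged across
#'   participants) and `n_participants`.
#' @export
sliding_rejection <- function(records, window = 5L) {
  n_trials <- max(records$trial)
  if (window < 1 || window > n_trials) {
    abort("`window` must be between 1 and the number of trials.")
  }
  per_part <- records |>
    dplyr::mutate(rejected = as.numeric(!parse_choices(.data$choice))) |>
    dplyr::arrange(.data$participant_id, .data$trial) |>
    dplyr::mutate(
      window_rate = 100 * slide_mean(.data$rejected, window),
      .by = "participant_id"
    ) |>
    dplyr::filter(.data$trial >= window)
  dplyr::summarise(per_part,
                   rejection_rate = mean(.data$window_rate),
                   n_participants = dplyr::n(),
                   .by = "trial")
}

slide_mean <- function(x, window) {
  cs <- cumsum(x)
  out <- rep(NA_real_, length(x))
  idx <- seq(window, length(x))
  out[idx] <- (cs[idx] - c(0, cs)[idx - window + 1]) / window
  out
}

#' Cohen's d from a paired t statistic
#'
#' For a paired design, `d = |t| / sqrt(n)` where `n` is the number of
#' pairs.
#'
#' @param t Paired t statistic.
#' @param n Number of pairs.
#' @return Non-negative effect size.
#' @export
#' @examples
#' cohens_d_from_t(-3.89, 30)  # ~0.71
cohens_d_from_t <- function(t, n) abs(t) / sqrt(n)

# 95% CI for paired-design d via the noncentral t distribution: find the
# noncentrality parameters whose t quantiles bracket the observed t, then
# rescale by sqrt(n).
cohens_d_ci <- function(t, n, conf = 0.95) {
  lims <- c((1 + conf) / 2, (1 - conf) / 2)
  ncp <- vapply(lims, function(pr) {
    # pt() warns about reduced precision at extreme ncp probes; harmless
    # for root bracketing
    f <- function(ncp) {
      suppressWarnings(pt(abs(t), df = n - 1, ncp = ncp)) - pr
    }
    lo <- -10 * (abs(t) + 5)
    hi <- 10 * (abs(t) + 5)
    tryCatch(uniroot(f, c(lo, hi))$root, error = function(e) NA_real_)
  }, numeric(1))
  ncp / sqrt(n)
}

#' Paired contrast between two conditions
#'
#' Classical two-tailed paired t-test with the paired-design effect size
#' `d = |t| / sqrt(n)` and a noncentral-t 95% CI for d. The sign convention
#' is `post - pre`, so a decrease gives a negative t while d is reported as
#' a magnitude.
#'
#' @param pre,post Equal-length per-participant value vectors (n >= 2).
#' @return A list of class `ug_paired`: `t`, `df`, `p`, `mean_diff`,
#'   `sem_diff`, `cohens_d`, `ci_d` (length-2, NA when unavailable), `n`.
#' @export
paired_contrast <- function(pre, post) {
  if (length(pre) != length(post)) abort("`pre` and `post` must be paired.")
  keep <- !is.na(pre) & !is.na(post)
  pre <- pre[keep]
  post <- post[keep]
  n <- length(pre)
  if (n < 2) abort("Need at least 2 complete pairs.")
  diffs <- post - pre
  if (sd(diffs) == 0) {
    if (all(diffs == 0)) {
      res <- list(t = 0, df = n - 1L, p = 1, mean_diff = 0,
                  sem_diff = 0, cohens_d = 0, ci_d = c(NA_real_, NA_real_),
                  n = n)
      return(structure(res, class = "ug_paired"))
    }
    warn("Zero variance of differences; t is undefined.")
    res <- list(t = NA_real_, df = n - 1L, p = NA_real_,
                mean_diff = mean(diffs), sem_diff = 0,
                cohens_d = NA_real_, ci_d = c(NA_real_, NA_real_), n = n)
    return(structure(res, class = "ug_paired"))
  }
  tt <- t.test(post, pre, paired = TRUE)
  t_stat <- unname(tt$statistic)
  structure(
    list(t = t_stat, df = unname(tt$parameter), p = tt$p.value,
         mean_diff = mean(diffs), sem_diff = sd(diffs) / sqrt(n),
         cohens_d = cohens_d_from_t(t_stat, n),
         ci_d = sort(abs(cohens_d_ci(t_stat, n))),
         n = n),
    class = "ug_paired"
  )
}

#' @export
print.ug_paired <- function(x, ...) {
  cat(sprintf("<ug_paired> t(%d) = %.2f, p = %.4g, mean diff = %.2f (SEM %.2f), d = %.2f\n",
              x$df, x$t, x$p, x$mean_diff, x$sem_diff, x$cohens_d))
  invisible(x)
}

#' Benjamini-Hochberg step-up correction
#'
#' Implements the step-up false-discovery-rate procedure: sort the p-values
#' ascending, assign ranks, compute each critical value `(rank / m) * q`,
#' find the largest p-value smaller than its critical value (the cutoff),
#' and declare every p-value at or below the cutoff significant. The
#' significant set is always a prefix of the rank ordering.
#'
#' @param p_values Numeric p-values in \[0, 1\].
#' @param q False discovery rate (default 0.05).
#' @param labels Optional labels (e.g., offer sizes) carried through.
#' @return A tibble of class `ug_bh` sorted by rank: `label`, `p`, `rank`,
#'   `critical`, `significant`; the cutoff p-value (or NA) is stored in
#'   `attr(, "cutoff_p")`.
#' @export
#' @examples
#' bh_correct(c(.001, .001, .021, .041, .062), q = .05,
#'            labels = c(5, 6, 8, 7, 9))
bh_correct <- function(p_values, q = 0.05, labels = NULL) {
  if (length(p_values) == 0) abort("Need at least one p-value.")
  if (any(p_values < 0 | p_values > 1)) abort("p-values must be in [0, 1].")
  if (q <= 0 || q >= 1) abort("`q` must be in (0, 1).")
  m <- length(p_values)
  labels <- labels %||% seq_len(m)
  ord <- order(p_values)
  out <- tibble::tibble(
    label = labels[ord],
    p = p_values[ord],
    rank = seq_len(m),
    critical = seq_len(m) / m * q
  )
  below <- which(out$p < out$critical)
  cutoff <- if (length(below) > 0) out$p[max(below)] else NA_real_
  out$significant <- if (is.na(cutoff)) {
    rep(FALSE, m)
  } else {
    out$p <= cutoff
  }
  attr(out, "cutoff_p") <- cutoff
  class(out) <- c("ug_bh", class(out))
  out
}

#' Mixed-effects logistic regression of rejection on offer size
#'
#' Fits rejection (the positive class) on offer size with per-participant
#' random intercepts and slopes via `lme4::glmer`. The predictor is coded
#' as tokens *below* the endowment midpoint (`(endowment/2) - offer`), so a
#' positive coefficient — and an odds ratio above 1 — means each token
#' removed from the offer multiplies the odds of rejection. If the mixed
#' fit fails or does not converge, a participant-clustered pooled logistic
#' regression (sandwich variance) is used and flagged.
#'
#' @param records Trial records.
#' @param endowment Token endowment (for the predictor coding; default 20).
#' @return A list of class `ug_offer_glm`: `coefficient` (log-odds per token
#'   decrease in offer), `odds_ratio`, `ci` (95%, odds-ratio scale), `z`,
#'   `p`, `method` (`"mixed"` or `"pooled_clustered"`), `fit`.
#' @export
offer_size_regression <- function(records, endowment = 20) {
  dat <- records |>
    dplyr::mutate(
      rejected = as.integer(!parse_choices(.data$choice)),
      offer_deficit = endowment / 2 - .data$offer
    )
  if (dplyr::n_distinct(dat$participant_id) < 2) {
    abort("Need at least 2 participants.")
  }
  if (dplyr::n_distinct(dat$rejected) < 2) {
    abort("All choices identical; the regression is separable.")
  }
  mixed <- tryCatch({
    fit <- lme4::glmer(
      rejected ~ offer_deficit + (1 + offer_deficit | participant_id),
      data = dat, family = binomial()
    )
    if (length(fit@optinfo$conv$lme4$messages %||% character()) > 0) {
      abort("mixed fit did not converge")
    }
    fit
  }, error = function(e) NULL, warning = function(w) NULL)

  if (!is.null(mixed)) {
    sm <- summary(mixed)$coefficients
    est <- sm["offer_deficit", "Estimate"]
    se <- sm["offer_deficit", "Std. Error"]
    z <- sm["offer_deficit", "z value"]
    p <- sm["offer_deficit", "Pr(>|z|)"]
    method <- "mixed"
    fit <- mixed
  } else {
    warn("Mixed-effects fit failed to converge; falling back to participant-clustered pooled logistic regression.")
    fit <- glm(rejected ~ offer_deficit, data = dat, family = binomial())
    vc <- sandwich::vcovCL(fit, cluster = dat$participant_id)
    est <- coef(fit)[["offer_deficit"]]
    se <- sqrt(vc["offer_deficit", "offer_deficit"])
    z <- est / se
    p <- 2 * pnorm(-abs(z))
    method <- "pooled_clustered"
  }
  ci_log <- est + c(-1, 1) * qnorm(0.975) * se
  structure(
    list(coefficient = est, odds_ratio = exp(est), ci = exp(ci_log),
         z = z, p = p, method = method, fit = fit),
    class = "ug_offer_glm"
  )
}

#' @export
print.ug_offer_glm <- function(x, ...) {
  cat(sprintf(
    "<ug_offer_glm> [%s] log-odds of rejection per token decrease in offer = %.3f\n  OR = %.2f (95%% CI %.2f-%.2f), z = %.2f, p = %.3g\n",
    x$method, x$coefficient, x$odds_ratio, x$ci[1], x$ci[2], x$z, x$p))
  invisible(x)
}

#' Baseline vs post-conditioning emotion-rating contrast
#'
#' Paired contrast of per-participant mean ratings between the baseline and
#' post-conditioning blocks. Participants missing ratings in either block
#' are excluded (their count is reported via the result's `n`).
#'
#' @param records Trial records with a `rating` column.
#' @param blocks Length-2 character vector: the pre and post block labels.
#' @return A `ug_paired` result (see [paired_contrast()]).
#' @export
rating_contrast <- function(records, blocks = c("baseline", "post")) {
  means <- records |>
    dplyr::filter(.data$block %in% blocks, !is.na(.data$rating)) |>
    dplyr::summarise(mean_rating = mean(.data$rating),
                     .by = c("participant_id", "block")) |>
    tidyr::pivot_wider(names_from = "block", values_from = "mean_rating")
  for (b in blocks) if (!b %in% names(means)) means[[b]] <- NA_real_
  n_excluded <- sum(is.na(means[[blocks[1]]]) | is.na(means[[blocks[2]]]))
  if (n_excluded > 0) {
    warn(paste0(n_excluded, " participant(s) excluded: missing ratings in a block."))
  }
  paired_contrast(means[[blocks[1]]], means[[blocks[2]]])
}

#' Block rejection-rate contrast
#'
#' The primary norm-adaptation measure: per-participant rejection rates are
#' contrasted between two blocks drawing from the same offer distribution
#' (baseline vs post-conditioning by default). Optionally restricted to one
#' offer size; participants lacking that size in either block are excluded.
#'
#' @param records Trial records.
#' @param blocks Length-2 character vector: pre and post block labels.
#' @param offer_size Optional single offer size to condition on.
#' @return A `ug_paired` result on percentage rejection rates.
#' @export
block_contrast <- function(records, blocks = c("baseline", "post"),
                           offer_size = NULL) {
  if (!is.null(offer_size)) {
    records <- dplyr::filter(records, .data$offer == offer_size)
  }
  rates <- rejection_rates(records, by = "block") |>
    dplyr::filter(.data$block %in% blocks) |>
    dplyr::select("participant_id", "block", "rejection_rate") |>
    tidyr::pivot_wider(names_from = "block", values_from = "rejection_rate")
  for (b in blocks) if (!b %in% names(rates)) rates[[b]] <- NA_real_
  paired_contrast(rates[[blocks[1]]], rates[[blocks[2]]])
}

#' Per-offer-size contrasts with FDR correction
#'
#' Runs [block_contrast()] for each offer size present in both blocks for at
#' least `min_n` participants, then applies [bh_correct()] to the resulting
#' p-values.
#'
#' @param records Trial records.
#' @param blocks Pre/post block labels.
#' @param q False discovery rate.
#' @param min_n Minimum participants with the size in both blocks.
#' @return A list: `tests` (tibble of per-size results) and `bh` (the
#'   `ug_bh` table).
#' @export
offer_size_contrasts <- function(records, blocks = c("baseline", "post"),
                                 q = 0.05, min_n = 5L) {
  sizes <- records |>
    dplyr::filter(.data$block %in% blocks) |>
    dplyr::distinct(.data$participant_id, .data$block, .data$offer) |>
    dplyr::count(.data$offer, .data$participant_id) |>
    dplyr::filter(.data$n == 2L) |>
    dplyr::count(.data$offer) |>
    dplyr::filter(.data$n >= min_n) |>
    dplyr::pull(.data$offer)
  if (length(sizes) == 0) abort("No offer size occurs in both blocks often enough.")
  tests <- purrr::list_rbind(purrr::map(sort(sizes), function(s) {
    pr <- dplyr::filter(records, .data$offer == s)
    keep <- pr |>
      dplyr::filter(.data$block %in% blocks) |>
      dplyr::distinct(.data$participant_id, .data$block) |>
      dplyr::count(.data$participant_id) |>
      dplyr::filter(.data$n == 2L) |>
      dplyr::pull(.data$participant_id)
    res <- block_contrast(dplyr::filter(pr, .data$participant_id %in% keep),
                          blocks = blocks)
    tibble::tibble(offer = s, t = res$t, df = res$df, p = res$p,
                   mean_diff = res$mean_diff, cohens_d = res$cohens_d,
                   n = res$n)
  }))
  usable <- dplyr::filter(tests, !is.na(.data$p))
  list(tests = tests,
       bh = bh_correct(usable$p, q = q, labels = usable$offer))
}
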