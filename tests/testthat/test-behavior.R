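make_block_records <- function(choices_by_block, participant_id = "p01",
                               offers = NULL) {
  blocks <- rep(names(choices_by_block),
                lengths(choices_by_block))
  ch <- unlist(choices_by_block, use.names = FALSE)
  tibble::tibble(
    participant_id = participant_id,
    trial = seq_along(ch),
    block = blocks,
    offer = if (is.null(offers)) rep(8L, length(ch)) else offers,
    choice = ch,
    rating = NA_integer_
  )
}

test_that("rejection rates are per-participant percentages by group", {
  rec <- make_block_records(list(
    baseline = c(rep("reject", 3), rep("accept", 17)),
    post = rep("reject", 20)
  ))
  rates <- rejection_rates(rec, by = "block")
  expect_equal(rates$rejection_rate[rates$block == "baseline"], 15)
  expect_equal(rates$rejection_rate[rates$block == "post"], 100)
  expect_equal(rates$n_trials, c(20L, 20L))
})

test_that("pooled block rates equal trial-count-weighted per-size rates", {
  rec <- dplyr::filter(tiny_cohort()$trials, block == "baseline")
  pooled <- rejection_rates(rec, by = "block")
  by_size <- rejection_rates(rec, by = "block_offer")
  recombined <- by_size |>
    dplyr::summarise(
      rejection_rate = sum(rejection_rate * n_trials) / sum(n_trials),
      .by = "participant_id"
    )
  merged <- dplyr::inner_join(pooled, recombined, by = "participant_id",
                              suffix = c("_pooled", "_weighted"))
  expect_equal(merged$rejection_rate_pooled, merged$rejection_rate_weighted)
})

test_that("sliding windows have the right support, bounds and identities", {
  rec <- make_block_records(list(b = rep("accept", 60)))
  curve <- sliding_rejection(rec, window = 5)
  expect_equal(nrow(curve), 56L)
  expect_equal(curve$trial, 5:60)
  expect_equal(curve$rejection_rate, rep(0, 56))

  mixed <- make_block_records(list(b = rep(c("accept", "reject"), 30)))
  raw <- sliding_rejection(mixed, window = 1)
  expect_equal(raw$rejection_rate,
               100 * as.numeric(mixed$choice == "reject"))
  expect_true(all(sliding_rejection(mixed, 5)$rejection_rate >= 0 &
                    sliding_rejection(mixed, 5)$rejection_rate <= 100))
  # a window tiling a constant-behavior block reproduces the block rate
  allrej <- make_block_records(list(b = rep("reject", 60)))
  expect_equal(sliding_rejection(allrej, 20)$rejection_rate, rep(100, 41))
  expect_error(sliding_rejection(mixed, 61), "window")
})

test_that("paired contrasts give classical t, d and directional sign", {
  x <- c(10, 20, 30, 25, 15)
  same <- paired_contrast(x, x)
  expect_equal(same$t, 0)
  expect_equal(same$cohens_d, 0)

  pre <- c(40, 55, 30, 45, 60, 35)
  post <- c(30, 45, 28, 35, 50, 30)
  res <- paired_contrast(pre, post)
  ref <- t.test(post, pre, paired = TRUE)
  expect_equal(res$t, unname(ref$statistic))
  expect_equal(res$p, ref$p.value)
  expect_equal(res$df, length(pre) - 1)
  expect_lt(res$t, 0)  # decreases keep the negative sign
  expect_equal(res$cohens_d, abs(res$t) / sqrt(length(pre)))
  expect_equal(res$mean_diff, mean(post - pre))
  # scale invariance of t and d
  res2 <- paired_contrast(3 * pre, 3 * post)
  expect_equal(res2$t, res$t)
  expect_equal(res2$cohens_d, res$cohens_d)
})

test_that("effect sizes from the paired t statistic round as published", {
  expect_equal(round(cohens_d_from_t(-3.89, 30), 2), 0.71)
  expect_equal(round(cohens_d_from_t(-2.44, 30), 2), 0.45)
  # invariance to the sign convention of t
  expect_equal(cohens_d_from_t(3.89, 30), cohens_d_from_t(-3.89, 30))
})

test_that("the FDR step-up procedure reproduces its worked example", {
  res <- bh_correct(c(.001, .001, .021, .041, .062), q = .05,
                    labels = c(5, 6, 8, 7, 9))
  expect_equal(attr(res, "cutoff_p"), .021)
  expect_equal(res$significant, c(TRUE, TRUE, TRUE, FALSE, FALSE))
  expect_equal(sort(res$label[res$significant]), c(5, 6, 8))
  expect_equal(res$critical, (1:5) / 5 * .05)
})

test_that("FDR edge cases and structural properties hold", {
  none <- bh_correct(rep(1, 4))
  expect_false(any(none$significant))
  expect_true(is.na(attr(none, "cutoff_p")))
  all_sig <- bh_correct(rep(0, 4))
  expect_true(all(all_sig$significant))
  expect_error(bh_correct(numeric()), "p-value")
  expect_error(bh_correct(c(0.5, 1.2)), "0, 1")

  withr::with_seed(17, {
    for (i in 1:20) {
      p <- runif(sample(3:12, 1))
      res <- bh_correct(p, q = 0.04)
      sig <- res$significant
      # significance set is a rank prefix
      if (any(sig)) expect_equal(sig, seq_along(sig) <= max(which(sig)))
      expect_true(all(diff(res$critical) > 0))
      # monotone in q: larger q never removes significances
      res2 <- bh_correct(p, q = 0.2)
      expect_true(all(res2$significant[sig]))
      # cross-check against the adjusted-p-value formulation
      expect_equal(sig, (stats::p.adjust(res$p, method = "BH") <= 0.04))
    }
  })
})

test_that("rejection odds increase as offers shrink in a monotone cohort", {
  cohort <- monotone_cohort()
  res <- suppressWarnings(offer_size_regression(cohort$trials))
  expect_gt(res$coefficient, 0)
  expect_gt(res$odds_ratio, 1)
  expect_equal(res$odds_ratio, exp(res$coefficient))
  expect_lt(res$p, 0.05)
  td <- tidy(res)
  expect_equal(td$estimate, res$coefficient)
  # zero coefficient maps to odds ratio 1 under the same transform
  expect_equal(exp(0), 1)
})

test_that("the regression rejects degenerate input", {
  rec <- make_block_records(list(b = rep("accept", 20)))
  rec2 <- dplyr::mutate(rec, participant_id = "p02")
  expect_error(offer_size_regression(dplyr::bind_rows(rec, rec2)),
               "identical")
  expect_error(offer_size_regression(rec), "participants")
})

test_that("rating contrasts compare per-participant block means", {
  rec <- purrr::list_rbind(purrr::map(1:4, function(i) {
    make_block_records(list(baseline = rep("accept", 10),
                            post = rep("accept", 10)),
                       participant_id = sprintf("p%02d", i)) |>
      dplyr::mutate(rating = rep(c(5L, 5L), each = 10))
  }))
  res <- rating_contrast(rec)
  expect_equal(res$t, 0)
  expect_equal(res$mean_diff, 0)

  cohort <- tiny_cohort()
  smoke <- suppressWarnings(rating_contrast(cohort$trials))
  expect_equal(smoke$df, smoke$n - 1)
  expect_true(is.finite(smoke$mean_diff))
})

test_that("per-offer-size contrasts correct over the tested sizes", {
  cohort <- monotone_cohort()
  out <- offer_size_contrasts(cohort$trials, q = 0.05, min_n = 5)
  expect_true(all(out$tests$offer %in% 0:20))
  expect_equal(nrow(out$bh), sum(!is.na(out$tests$p)))
  expect_true(all(out$bh$critical > 0))
})
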