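test_that("inequity-aversion utility matches hand-evaluated cases", {
  expect_equal(fs_utility(10, 10, alpha = 3, beta = 7), 10)
  expect_equal(fs_utility(4, 10, alpha = 1, beta = 0.5), -2)
  expect_equal(fs_utility(12, 10, alpha = 1, beta = 0.5), 11)
})

test_that("envy and guilt penalties are never simultaneously active", {
  withr::with_seed(8, {
    for (i in 1:50) {
      s <- runif(1, 0, 20); nrm <- runif(1, 0, 20)
      a <- runif(1, 0, 10); b <- runif(1, 0, 10)
      envy_term <- a * max(nrm - s, 0)
      guilt_term <- b * max(s - nrm, 0)
      expect_true(envy_term == 0 || guilt_term == 0)
      expect_equal(fs_utility(s, nrm, a, b), s - envy_term - guilt_term)
    }
  })
})

test_that("softmax acceptance probability behaves at its anchors", {
  expect_equal(p_accept(0, 5), 0.5)
  expect_equal(p_accept(-3, 0), 0.5)
  expect_equal(p_accept(1, 1), 1 / (1 + exp(-1)))
  # numerically stable in saturation
  expect_equal(p_accept(1e6, 10), 1)
  expect_equal(p_accept(-1e6, 10), 0)
  expect_error(p_accept(1, -1), "gamma")
})

test_that("acceptance probability increases with offer size when beta < 1", {
  offers <- 0:20
  for (b in c(0, 0.5, 0.9)) {
    u <- fs_utility(offers, norm = 10, alpha = 2, beta = b)
    p <- p_accept(u, gamma = 1.5)
    expect_true(all(diff(p) > 0))
  }
})

test_that("Rescorla-Wagner update is a convex step toward the offer", {
  expect_equal(rw_update(10, 4, 0), 10)
  expect_equal(rw_update(10, 4, 1), 4)
  expect_equal(rw_update(10, 4, 0.25), 8.5)
  withr::with_seed(21, {
    for (i in 1:50) {
      nrm <- runif(1, 0, 20); s <- runif(1, 0, 20); e <- runif(1)
      out <- rw_update(nrm, s, e)
      expect_gte(out, min(nrm, s))
      expect_lte(out, max(nrm, s))
    }
  })
  expect_error(rw_update(10, 4, 1.2), "epsilon")
})

test_that("Bayesian-observer update reproduces hand-computed hyperparameters", {
  s0 <- bo_state()  # k 4, nu 10, mu 10, sigma2 4
  up0 <- bo_update(s0, 10)
  expect_equal(up0$k, 5)
  expect_equal(up0$nu, 11)
  expect_equal(up0$mu_hat, 10)
  expect_equal(up0$sigma2_hat, 40 / 11)  # zero prediction error shrinks it

  up1 <- bo_update(s0, 4)
  expect_equal(up1$mu_hat, 8.8)
  expect_equal(up1$sigma2_hat, 68.8 / 11)
})

test_that("BO posterior mean stays between prior mean and offer, variance positive", {
  withr::with_seed(13, {
    st <- bo_state()
    for (i in 1:60) {
      s <- runif(1, 0, 20)
      nxt <- bo_update(st, s)
      expect_gte(nxt$mu_hat, min(st$mu_hat, s))
      expect_lte(nxt$mu_hat, max(st$mu_hat, s))
      expect_gt(nxt$sigma2_hat, 0)
      expect_equal(nxt$k, st$k + 1)
      expect_equal(nxt$nu, st$nu + 1)
      st <- nxt
    }
  })
})

test_that("norm trajectories follow each model's update rule", {
  offers <- c(4, 4)
  fs <- agent_params("FS_fixed", 1, 0, 1)
  expect_equal(norm_trajectory(fs, c(3, 9, 15)), rep(10, 3))

  rw <- agent_params("RW_fixed", 1, 0, 1, epsilon = 0.5)
  expect_equal(norm_trajectory(rw, offers), c(10, 7))

  bo <- agent_params("BO_fixed", 1, 0, 1)
  expect_equal(norm_trajectory(bo, rep(10, 8)), rep(10, 8))
  # mean recursion agrees with iterating the full conjugate update
  st <- bo_state()
  mus <- numeric(5)
  offs <- c(4, 7, 2, 11, 6)
  for (t in 1:5) {
    mus[t] <- st$mu_hat
    st <- bo_update(st, offs[t])
  }
  expect_equal(norm_trajectory(bo, offs), mus)
})

test_that("RW norms stay within the hull of initial norm and offers", {
  withr::with_seed(31, {
    for (i in 1:20) {
      offs <- sample(0:20, 60, replace = TRUE)
      e <- runif(1)
      p <- agent_params("RW_free", 1, 0, 1, epsilon = e,
                        initial_norm = runif(1, 0, 20))
      tr <- norm_trajectory(p, offs)
      expect_gte(min(tr), min(p$initial_norm, min(offs)))
      expect_lte(max(tr), max(p$initial_norm, max(offs)))
      expect_equal(tr[1], p$initial_norm)
    }
  })
})

test_that("choice NLL matches an independent per-trial hand computation", {
  # 5-trial toy set, RW learner: norms and probabilities computed with
  # plain arithmetic, independent of the package's likelihood path
  offs <- c(8, 3, 5, 12, 7)
  acc <- c(TRUE, FALSE, FALSE, TRUE, TRUE)
  a <- 1.2; b <- 0.3; g <- 0.8; e <- 0.25
  nrm <- 10
  nll_hand <- 0
  for (t in 1:5) {
    u <- offs[t] - a * max(nrm - offs[t], 0) - b * max(offs[t] - nrm, 0)
    p <- 1 / (1 + exp(-u * g))
    nll_hand <- nll_hand - log(if (acc[t]) p else 1 - p)
    nrm <- nrm + e * (offs[t] - nrm)
  }
  params <- agent_params("RW_fixed", a, b, g, epsilon = e)
  expect_equal(negative_log_likelihood(params, offs, acc), nll_hand,
               tolerance = 1e-10)
})

test_that("NLL is the chance value at zero temperature and ~0 when saturated", {
  params0 <- agent_params("FS_fixed", 2, 0.1, 0)
  choices <- rep(c("accept", "reject"), 30)
  expect_equal(negative_log_likelihood(params0, rep(8, 60), choices),
               60 * log(2), tolerance = 1e-9)
  # one saturated trial: utility * gamma = 30
  sat <- agent_params("FS_fixed", 0, 0, 10)
  expect_lt(negative_log_likelihood(sat, 3, "accept"), 1e-9)
})

test_that("NLL stays finite across extreme in-bound parameters", {
  offs <- rep(c(0, 20), 30)
  choices <- rep(c("reject", "accept"), 30)
  for (g in c(0, 10)) {
    for (a in c(0, 10)) {
      p <- agent_params("FS_fixed", a, 10, g)
      val <- negative_log_likelihood(p, offs, choices)
      expect_true(is.finite(val))
      expect_gte(val, 0)
    }
  }
})

test_that("free-norm variants at norm 10 reproduce their fixed counterparts", {
  offs <- withr::with_seed(4, sample(0:20, 60, replace = TRUE))
  choices <- withr::with_seed(5, sample(c("accept", "reject"), 60, TRUE))
  pairs <- list(c("FS_fixed", "FS_free"), c("BO_fixed", "BO_free"),
                c("RW_fixed", "RW_free"))
  for (pr in pairs) {
    eps <- if (grepl("RW", pr[1])) 0.3 else NULL
    fixed <- agent_params(pr[1], 2, 0.2, 1.5, epsilon = eps)
    free <- agent_params(pr[2], 2, 0.2, 1.5, epsilon = eps,
                         initial_norm = 10)
    expect_equal(negative_log_likelihood(fixed, offs, choices),
                 negative_log_likelihood(free, offs, choices))
  }
})

test_that("model metadata and parameter validation are enforced", {
  expect_error(agent_params("RW_fixed", 1, 0, 1), "epsilon")
  expect_error(agent_params("FS_fixed", 1, 0, 1, epsilon = 0.5), "RW")
  expect_error(agent_params("FS_fixed", 1, 0, 1, initial_norm = 5), "fixed")
  expect_error(agent_params("nope", 1, 0, 1), "model_id")
  expect_error(negative_log_likelihood(agent_params("FS_fixed", 1, 0, 1),
                                       1:5, c("accept", "reject")),
               "length")
})
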