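test_that("rate proposals apply exactly one multiplicative move type", {
  cfg <- bsl_config(seed = 1)
  cur <- c(k_1_2 = 0.3, k_1_3 = 0.1, k_2_1 = 2, k_2_3 = 0.5,
           k_3_1 = 1, k_3_2 = 0.7)
  # zero proposal scale: exp(0) leaves every rate untouched
  cfg0 <- bsl_config(scale_single = 0, scale_global = 0, scale_paired = 0)
  set.seed(2)
  expect_equal(propose_rates(cur, cfg0, 3), cur, ignore_attr = TRUE)

  set.seed(3)
  moved_counts <- integer(0)
  for (i in 1:200) {
    prop <- propose_rates(cur, cfg, 3)
    changed <- which(prop != cur)
    move <- attr(prop, "move")
    expect_true(all(prop > 0))
    if (move == "single") expect_lte(length(changed), 1L)
    if (move == "global") expect_true(length(changed) %in% c(0L, 6L))
    if (move == "paired" && length(changed)) {
      # opposing pair: k_ij and k_ji move by the same factor
      expect_identical(length(changed), 2L)
      nm <- names(cur)[changed]
      ij <- do.call(rbind, strsplit(sub("k_", "", nm), "_"))
      expect_identical(ij[1, ], rev(ij[2, ]))
      expect_equal(unname(prop[changed[1]] / cur[changed[1]]),
                   unname(prop[changed[2]] / cur[changed[2]]),
                   tolerance = 1e-12)
    }
    moved_counts <- c(moved_counts, length(changed))
  }

  # symmetry of the t-proposal: log-ratios center on zero
  set.seed(4)
  lr <- replicate(20000, {
    p <- propose_rates(c(k_1_2 = 1, k_2_1 = 1), cfg, 2)
    log(p[1] / 1)
  })
  lr <- lr[lr != 0]
  expect_lt(abs(mean(lr)) / (sd(lr) / sqrt(length(lr))), 4)
})

test_that("transition-count simulation matches the master equation", {
  # all rates zero: everyone stays put, counts are the diagonal split
  s0 <- simulate_transition_summary(c(0, 0), c(0.3, 0.7),
                                    bsl_config(M = 1000), seed = 1)
  m0 <- matrix(s0, 2, 2)
  expect_identical(sum(m0), 1000)
  expect_identical(m0[1, 2] + m0[2, 1], 0)

  # 2-state k12 = 1, k21 = 2: per-frame fractions follow expm(Q * 0.04)
  Q <- matrix(c(-1, 1, 2, -2), 2, 2, byrow = TRUE)
  E <- as.matrix(Matrix::expm(Q * 0.04))
  pi_eq <- c(2 / 3, 1 / 3)
  expected <- as.vector(diag(pi_eq) %*% E)
  s1 <- simulate_transition_summary(c(1, 2), pi_eq,
                                    bsl_config(M = 100000), seed = 2)
  # binomial-scale s.e. on each count fraction
  se <- sqrt(expected * (1 - expected) / 1e5)
  expect_true(all(abs(s1 / 1e5 - expected) < 3.5 * se + 1e-6))

  # the batch sampler is distributionally identical to the fine-step loop
  set.seed(3)
  batch <- sptkinetics:::simulate_summaries_batch(
    c(1, 2), pi_eq, bsl_config(n_sim = 400, M = 2000), dt_exp = 0.04)
  set.seed(4)
  fine <- t(replicate(400, simulate_transition_summary(
    c(1, 2), pi_eq, bsl_config(M = 2000))))
  for (j in 1:4) {
    se_j <- sqrt(stats::var(batch[, j]) / 400 + stats::var(fine[, j]) / 400)
    expect_lt(abs(mean(batch[, j]) - mean(fine[, j])), 3.5 * se_j)
  }

  # halving the fine step (doubling n_fine) leaves the expectation unchanged
  b2 <- sptkinetics:::simulate_summaries_batch(
    c(1, 2), pi_eq, bsl_config(n_sim = 400, n_fine = 200, M = 2000),
    dt_exp = 0.04)
  for (j in 1:4) {
    se_j <- sqrt(stats::var(batch[, j]) / 400 + stats::var(b2[, j]) / 400)
    expect_lt(abs(mean(batch[, j]) - mean(b2[, j])), 3.5 * se_j)
  }

  # rates violating the fine-step validity bound are rejected loudly
  expect_error(simulate_transition_summary(c(3000, 1), c(0.5, 0.5),
                                           bsl_config(M = 100)),
               class = "sptkinetics_invalid_rates")
})

test_that("synthetic log-likelihood behaves like a likelihood", {
  obs <- observed_transitions(epe1_T(), dt_exp = 0.04, n_obs = 20000)
  truth <- matrix_log_rates(epe1_T())
  cfg <- bsl_config(n_sim = 300, M = 2000)
  ll_truth <- synthetic_loglik(obs, truth, cfg, seed = 1)
  ll_far <- synthetic_loglik(obs, truth * 10, cfg, seed = 1)
  expect_gt(ll_truth, ll_far)

  # determinism contract
  expect_identical(synthetic_loglik(obs, truth, cfg, seed = 5),
                   synthetic_loglik(obs, truth, cfg, seed = 5))

  # the Gaussian maximum sits at the simulated mean
  set.seed(2)
  S <- sptkinetics:::simulate_summaries_batch(truth, obs$pi_eq, cfg, 0.04)
  mu <- colMeans(S)
  V <- stats::cov(S) + diag(cfg$eps_factor * sum(diag(stats::cov(S))) / 4, 4)
  at_mean <- mvtnorm::dmvnorm(mu, mu, V, log = TRUE)
  away <- mvtnorm::dmvnorm(mu + c(20, -20, 0, 0), mu, V, log = TRUE)
  expect_gt(at_mean, away)
})

test_that("rate inference matches the matrix-logarithm oracle", {
  T2 <- matrix(c(0.96, 0.04, 0.12, 0.88), 2, 2, byrow = TRUE)
  truth <- matrix_log_rates(T2)
  post <- infer_rate_constants(
    observed_transitions(T2, dt_exp = 0.04, n_obs = 20000),
    bsl_config(n_sim = 1000, chain_length = 15000, burn_in = 3000,
               M = 10000, seed = 8))
  expect_lt(abs(post$rates[["k_1_2"]] / truth[1] - 1), 0.05)
  expect_lt(abs(post$rates[["k_2_1"]] / truth[2] - 1), 0.05)
  # posterior structure invariants
  expect_true(all(post$rates > 0))
  expect_true(all(post$hdi95[, "lower"] <= post$rates))
  expect_true(all(post$hdi95[, "upper"] >= post$rates))
  expect_gt(post$acceptance_rate, 0.01)
  td <- tidy(post)
  expect_identical(td$term, c("k_1_2", "k_2_1"))
})

test_that("single-state input is a no-op for rate inference", {
  post <- infer_rate_constants(observed_transitions(matrix(1, 1, 1)),
                               bsl_config())
  expect_identical(post$K, 1L)
  expect_length(post$rates, 0L)
  expect_identical(nrow(tidy(post)), 0L)
})
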