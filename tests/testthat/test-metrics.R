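mock_posterior <- function(mu_draws, subject_id = "M1") {
  colnames(mu_draws) <- paste0("mu[", seq_len(ncol(mu_draws)), "]")
  structure(list(model = "block",
                 draws = list(mu = mu_draws,
                              sigma_mu = rep(0.1, nrow(mu_draws)),
                              sigma_eta = rep(0.1, nrow(mu_draws)),
                              sigma_y = rep(0.1, nrow(mu_draws))),
                 chain = rep(1:2, length.out = nrow(mu_draws)),
                 data = list(subject_id = subject_id),
                 meta = list(subject_id = subject_id,
                             n_draws = nrow(mu_draws))),
            class = "navlearn_posterior")
}

test_that("degenerate draws give an exact flat curve", {
  post <- mock_posterior(matrix(log(90), 200, 8))
  curve <- learning_curve(post)
  expect_equal(curve$mean, rep(90, 8))
  expect_equal(curve$sd, rep(0, 8))
})

test_that("curve summaries match brute-force recomputation from raw draws", {
  set.seed(5)
  mu <- matrix(rnorm(500 * 8, log(60), 0.2), 500, 8)
  curve <- learning_curve(mock_posterior(mu))
  for (b in 1:8) {
    expect_equal(curve$mean[b], mean(exp(mu[, b])))
    expect_equal(curve$sd[b], stats::sd(exp(mu[, b])))
  }
})

test_that("a fitted good learner's curve declines across blocks", {
  sim <- sim_subject("good", seed = 6)
  post <- fit_block_model(sim$trials, quick_config(seed = 6),
                          fallback_block_mean = TRUE)
  curve <- learning_curve(post)
  rho <- stats::cor(curve$mean, curve$block, method = "spearman")
  expect_lt(rho, 0)
})

test_that("amount of learning follows its defining arithmetic", {
  curve <- data.frame(block = 1:4, mean = c(60, 50, 45, 45),
                      sd = rep(1, 4))
  aol <- amount_of_learning(curve, chance_level = 90)
  expect_equal(aol$L, c(30, 10, 5, 0))
  expect_equal(aol$mean_amount, 11.25)
  expect_false(aol$degenerate)
  expect_equal(sum(aol$weights), 0, tolerance = 1e-12)
  expect_equal(sqrt(sum(aol$weights^2)), 1, tolerance = 1e-12)
})

test_that("a flat curve at chance yields zero learning and a degenerate flag", {
  curve <- data.frame(block = 1:8, mean = rep(90, 8), sd = rep(1, 8))
  aol <- amount_of_learning(curve, chance_level = 90)
  expect_equal(aol$L, rep(0, 8))
  expect_true(aol$degenerate)
  expect_equal(aol$weights, rep(0, 8))
})

test_that("learning amounts telescope to chance minus the final state", {
  set.seed(77)
  for (r in 1:1000) {
    m <- stats::runif(8, 5, 175)
    curve <- data.frame(block = 1:8, mean = m, sd = 1)
    aol <- amount_of_learning(curve, chance_level = 90)
    expect_equal(sum(aol$L), 90 - m[8], tolerance = 1e-9)
  }
})

test_that("contrast weights ignore constant shifts of the curve", {
  m <- c(85, 70, 52, 40, 33, 30, 28, 27)
  w1 <- amount_of_learning(data.frame(block = 1:8, mean = m, sd = 1))$weights
  w2 <- amount_of_learning(data.frame(block = 1:8, mean = m + 11, sd = 1),
                           chance_level = 90 + 11)$weights
  expect_equal(w1, w2, tolerance = 1e-9)
})

test_that("difference features equal the moments of the difference draws", {
  set.seed(9)
  n <- 8000
  d1 <- rnorm(n, log(80), 0.05)
  dB <- log(exp(d1) - rnorm(n, 20, 5))  # plant d ~ Normal(20, 5)
  post <- mock_posterior(cbind(d1, matrix(log(50), n, 6), dB))
  f <- difference_feature(post)
  d <- exp(d1) - exp(dB)
  expect_equal(f$diff_mean, mean(d))
  expect_equal(f$diff_sd, stats::sd(d) * sqrt((n - 1) / n))
  expect_lt(abs(f$diff_mean - 20), 3 * 5 / sqrt(n))
  expect_lt(abs(f$diff_sd - 5), 3 * 5 / sqrt(2 * n))
})

test_that("difference SD is invariant to constant shifts; identical blocks give zero mean", {
  set.seed(10)
  mu <- matrix(rnorm(2000, log(70), 0.1), 1000, 2)
  mu <- cbind(mu[, 1], mu[, 1])
  f <- difference_feature(mock_posterior(mu))
  expect_equal(f$diff_mean, 0)
  base <- matrix(rnorm(4000, log(60), 0.2), 2000, 2)
  shifted <- cbind(log(exp(base[, 1]) + 25), base[, 2])
  f1 <- difference_feature(mock_posterior(base))
  f2 <- difference_feature(mock_posterior(shifted))
  expect_equal(f1$diff_sd, f2$diff_sd, tolerance = 1e-9)
})

test_that("few draws trigger the stability warning", {
  post <- mock_posterior(matrix(rnorm(80 * 2, log(50), 0.1), 40, 2))
  expect_warning(difference_feature(post), "unstable")
})
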