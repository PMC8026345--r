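# Shared fits for the evaluation tests (test-scale sampler).
ev_sim <- sim_subject("good", seed = 41)
ev_block <- fit_block_model(ev_sim$trials, quick_config(seed = 41),
                            fallback_block_mean = TRUE)
ev_trial <- fit_trial_model(ev_sim$trials, quick_config(seed = 41),
                            fallback_block_mean = TRUE)

test_that("replicated outcomes have the contracted shape and support", {
  ppc <- posterior_predictive(ev_block, ev_sim$trials, n_rep_draws = 300,
                              seed = 2)
  n_obs <- sum(!is.na(ev_sim$trials$abs_error[
    ev_sim$trials$trial_kind == "retrieval"]))
  expect_equal(dim(ppc$y_rep), c(300L, n_obs))
  expect_true(all(ppc$y_rep > 0 & ppc$y_rep <= 180))
  expect_true(all(ppc$coverage_by_block >= 0 & ppc$coverage_by_block <= 1))
  expect_error(posterior_predictive(ev_block, ev_sim$trials,
                                    n_rep_draws = 10^6), "exceeds")
})

test_that("well-specified subjects are covered by 95% predictive intervals", {
  ppc <- posterior_predictive(ev_block, ev_sim$trials, n_rep_draws = 1000,
                              seed = 3)
  expect_gte(ppc$coverage, 0.88)
  expect_lte(ppc$coverage, 1)
})

test_that("PPC refuses trials from a different subject", {
  other <- sim_subject("weak", seed = 43)
  expect_error(posterior_predictive(ev_block, other$trials), "do not match")
})

test_that("the generalized-Pareto fit recovers known tail shapes", {
  rgpd <- function(n, k, sigma) sigma * expm1(k * -log(runif(n))) / k
  set.seed(14)
  for (k_true in c(0.2, 0.7, 1.2)) {
    ks <- replicate(60, navlearn:::gpd_fit(rgpd(200, k_true, 1))$k)
    expect_lt(abs(mean(ks) - k_true), 0.12)
  }
})

test_that("smoothed importance weights are proper and khat small for light tails", {
  set.seed(15)
  sm <- navlearn:::psis_smooth(rnorm(4000))
  expect_true(all(sm$log_weights <= 0))
  w <- exp(sm$log_weights - navlearn:::log_sum_exp(sm$log_weights))
  expect_equal(sum(w), 1, tolerance = 1e-12)
  expect_lt(sm$k, 0.7)
})

test_that("elpd values are finite and each model's pointwise count matches", {
  for (post in list(ev_block, ev_trial)) {
    l <- loo_elpd(log_lik_matrix(post))
    expect_true(is.finite(l$elpd))
    expect_length(l$pointwise, sum(post$data$obs))
    expect_length(l$pareto_k, sum(post$data$obs))
  }
})

test_that("self-comparison is exactly zero and swapping is antisymmetric", {
  self <- loo_compare(ev_block, ev_block, ev_sim$trials)
  expect_identical(self$difference, 0)
  ab <- loo_compare(ev_block, ev_trial, ev_sim$trials)
  ba <- loo_compare(ev_trial, ev_block, ev_sim$trials)
  expect_equal(ab$difference, -ba$difference, tolerance = 1e-10)
  expect_equal(ab$se, ba$se, tolerance = 1e-10)
})

test_that("conditional comparisons flag their heavy-tailed importance ratios", {
  ab <- loo_compare(ev_block, ev_trial, ev_sim$trials)
  expect_true(ab$unreliable)
  marg <- loo_compare(ev_block, ev_trial, ev_sim$trials, marginal = TRUE)
  expect_false(marg$unreliable)
})

test_that("mismatched trial sets are rejected", {
  other <- sim_subject("good", seed = 57)
  post_other <- fit_block_model(other$trials, quick_config(seed = 57),
                                fallback_block_mean = TRUE)
  expect_error(loo_compare(ev_block, post_other, ev_sim$trials),
               "do not match")
})

test_that("trial-wise generated data prefer the trial model under the marginal comparison", {
  set.seed(9)
  wins <- 0L
  for (r in 1:3) {
    mu <- log(90) + cumsum(rnorm(96, -0.015, 0.12))
    y <- pmin(rlnorm(96, mu, 0.25), 179)
    tr <- toy_trials(1, B = 8, n = 12)
    tr$abs_error <- y
    tr$signed_error <- y
    cfg <- quick_config(seed = 100 + r)
    pb <- fit_block_model(tr, cfg)
    pt <- fit_trial_model(tr, cfg)
    if (loo_compare(pb, pt, tr, marginal = TRUE)$difference < 0) {
      wins <- wins + 1L
    }
  }
  expect_gte(wins, 2L)
})
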