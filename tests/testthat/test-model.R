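test_that("sampler bookkeeping matches chains x (iterations - warmup)", {
  tr <- toy_trials(c(80, 60, 95), B = 8, n = 3)
  post <- fit_block_model(tr, quick_config(seed = 2))
  expect_equal(post$meta$n_draws, 4L * 500L)
  expect_equal(nrow(post$draws$mu), 2000L)
  expect_equal(ncol(post$draws$mu), 8L)
  expect_equal(ncol(post$draws$eta), 24L)
  expect_equal(length(post$chain), 2000L)
})

test_that("noise-free data pin the state to the constant (block and trial model)", {
  tr <- toy_trials(42, B = 8, n = 3)
  cfg <- quick_config(seed = 5)
  pb <- fit_block_model(tr, cfg)
  expect_true(all(abs(colMeans(exp(pb$draws$mu)) - 42) / 42 < 0.05))
  pt <- fit_trial_model(tr, cfg)
  expect_true(all(abs(colMeans(exp(pt$draws$mu)) - 42) / 42 < 0.05))
})

test_that("the fitted state recovers a planted learning trajectory", {
  sim <- sim_subject("good", seed = 31)
  post <- fit_block_model(sim$trials, quick_config(seed = 31),
                          fallback_block_mean = TRUE)
  st <- exp(post$draws$mu)
  m <- colMeans(st)
  s <- apply(st, 2, stats::sd)
  hits <- sum(abs(m - sim$latent) <= 2 * s)
  expect_gte(hits, 7L)
})

test_that("block and trial states agree on low-noise data", {
  set.seed(3)
  s_b <- seq(80, 30, length.out = 8)
  tr <- toy_trials(1, B = 8, n = 3)
  tr$abs_error <- rlnorm(24, log(s_b[tr$block]), 0.05)
  tr$signed_error <- tr$abs_error
  cfg <- quick_config(seed = 13)
  pb <- fit_block_model(tr, cfg)
  pt <- fit_trial_model(tr, cfg)
  block_state <- colMeans(exp(pb$draws$mu))
  trial_state <- tapply(colMeans(exp(pt$draws$mu)), tr$block, mean)
  expect_true(all(abs(block_state - trial_state) <
                    3 * apply(exp(pb$draws$mu), 2, stats::sd) + 2))
})

test_that("the first-block state starts near chance with minimal data", {
  tr <- toy_trials(90, B = 2, n = 2)
  tr$abs_error <- c(88, 92, 85, 95)
  tr$signed_error <- tr$abs_error
  post <- fit_block_model(tr, quick_config(seed = 1,
                                           schedule = schedule_spec(NULL,
                                             blocks = 2,
                                             retrieval_per_block = 16,
                                             repetitions = 1,
                                             direction_split = FALSE)))
  med <- stats::median(exp(post$draws$mu[, 1]))
  expect_gt(med, 60)
  expect_lt(med, 135)
})

test_that("missing trials get the half-normal block-mean imputation", {
  sim <- sim_subject("weak", seed = 17)
  tr <- sim$trials
  # force a couple of timeouts in block 2
  idx <- which(tr$block == 2L)[1:3]
  tr$abs_error[idx] <- NA
  tr$signed_error[idx] <- NA
  tr$response_time[idx] <- NA
  tr$missing[idx] <- TRUE
  post <- fit_block_model(tr, quick_config(seed = 17))
  ord <- order(tr$block, tr$trial_in_block)
  miss_cols <- which(post$data$obs == FALSE)
  expect_gt(length(miss_cols), 0L)
  for (j in miss_cols) {
    b <- post$data$block[j]
    # support of HalfNormal(log(block mean), 1) starts at the block mean
    expect_true(all(post$draws$eta[, j] >= log(post$data$ybar[b]) - 1e-9))
  }
})

test_that("an all-missing block errors unless the fallback is requested", {
  sim <- sim_subject("top", seed = 19)
  tr <- sim$trials
  b4 <- tr$block == 4L
  tr$abs_error[b4] <- NA
  tr$signed_error[b4] <- NA
  tr$response_time[b4] <- NA
  tr$missing[b4] <- TRUE
  expect_error(fit_block_model(tr, quick_config(seed = 3)),
               "fallback_block_mean")
  post <- fit_block_model(tr, quick_config(seed = 3),
                          fallback_block_mean = TRUE)
  expect_equal(post$data$ybar[4], post$data$ybar[3])
})

test_that("fits need observed trials in at least two blocks and one subject", {
  tr <- toy_trials(50, B = 1, n = 4)
  expect_error(fit_block_model(tr, quick_config()), "two blocks")
  two <- rbind(toy_trials(50, B = 4, n = 2, subject_id = "A"),
               toy_trials(60, B = 4, n = 2, subject_id = "B"))
  expect_error(fit_block_model(two, quick_config()), "single subject")
})

test_that("posterior stores round-trip bitwise and reject truncation", {
  tr <- toy_trials(c(70, 55), B = 4, n = 2)
  post <- fit_block_model(tr, quick_config(seed = 8))
  dir <- withr::local_tempdir()
  persist_posterior(post, dir)
  back <- read_posterior(dir)
  expect_identical(back$draws$mu, post$draws$mu)
  expect_identical(back$draws$eta, post$draws$eta)
  expect_identical(back$draws$sigma_y, post$draws$sigma_y)
  expect_identical(back$chain, post$chain)
  expect_equal(back$data$y, post$data$y)

  # truncated draw file -> parse error, no partial object
  f <- file.path(dir, "draws.csv")
  lines <- readLines(f)
  writeLines(lines[1:floor(length(lines) / 2)], f)
  expect_error(read_posterior(dir), "truncated|inconsistent")
  expect_error(read_posterior(withr::local_tempdir()), "missing")
})

test_that("config validation rejects inconsistent sampler settings", {
  expect_error(run_config(sampler = NULL, iterations = 1000, warmup = 1000),
               "warmup")
  expect_error(run_config(sampler = NULL, chains = 1), "chains")
  expect_error(run_config(chance_level = 0), "chance_level")
})
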