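test_that("identical seeds give identical subjects", {
  a <- sim_subject("good", seed = 4)
  b <- sim_subject("good", seed = 4)
  expect_identical(a$trials, b$trials)
  expect_identical(a$latent, b$latent)
})

test_that("per-block error means match the truncated log-normal oracle", {
  # flat non-learner at 90 degrees: closed-form (numerical-integration)
  # mean of the 180-truncated log-normal
  arch <- archetype_spec("non", initial_state = 90, drift = 0,
                         state_jitter = 1e-6, trial_noise_sd = 0.6,
                         missing_prob = 0, rt_base = 5, rt_slope = 0)
  spec <- schedule_spec(NULL, blocks = 8, retrieval_per_block = 12,
                        repetitions = 3, direction_split = FALSE)
  draws <- unlist(lapply(1:90, function(s) {
    sim <- simulate_subject(arch, build_schedule(spec, seed = s), spec,
                            "old", seed = s)
    sim$trials$abs_error
  }))
  oracle <- truncated_lnorm_mean(log(90), 0.6)
  se <- stats::sd(draws) / sqrt(length(draws))
  expect_lt(abs(mean(draws) - oracle), 4 * se)
})

test_that("missingness rate matches its binomial oracle", {
  arch <- archetype_spec("weak", initial_state = 90, drift = 0,
                         state_jitter = 1, trial_noise_sd = 0.5,
                         missing_prob = 0.05, rt_base = 5, rt_slope = 0)
  spec <- behavioral_spec
  miss <- unlist(lapply(1:105, function(s) {
    simulate_subject(arch, build_schedule(spec, seed = s), spec, "old",
                     seed = 7000 + s)$trials$missing
  }))
  se <- sqrt(0.05 * 0.95 / length(miss))
  expect_lt(abs(mean(miss) - 0.05), 3 * se)
})

test_that("simulated errors stay inside (0, 180] and latents in [1, 180]", {
  for (an in names(default_archetypes())) {
    sim <- sim_subject(an, seed = 21)
    y <- sim$trials$abs_error[!is.na(sim$trials$abs_error)]
    expect_true(all(y > 0 & y <= 180))
    expect_true(all(sim$latent >= 1 & sim$latent <= 180))
    obs <- !is.na(sim$trials$signed_error)
    expect_equal(abs(sim$trials$signed_error[obs]),
                 sim$trials$abs_error[obs])
  }
})

test_that("latent trajectories decline in expectation under positive drift", {
  lat <- sapply(1:40, function(s) sim_subject("good", seed = s)$latent)
  avg <- rowMeans(lat)
  expect_true(all(diff(avg) < 0))
})

test_that("cohorts have the requested size and reproducible composition", {
  co <- simulate_cohort(25, 32, seed = 1)
  expect_equal(nrow(co$truth), 57L)
  expect_equal(sum(co$truth$age_group == "young"), 25L)
  expect_equal(length(unique(co$trials$subject_id)), 57L)
  co2 <- simulate_cohort(25, 32, seed = 1)
  expect_identical(co$trials, co2$trials)
})

test_that("archetype draws follow the mixing proportions (multinomial oracle)", {
  mix <- default_cohort_mix()
  co <- simulate_cohort(100, 100, mix = mix, seed = 5)
  for (g in c("young", "old")) {
    counts <- table(factor(co$truth$archetype[co$truth$age_group == g],
                           levels = colnames(mix)))
    for (a in colnames(mix)) {
      p <- mix[g, a]
      se <- sqrt(100 * p * (1 - p))
      expect_lt(abs(counts[[a]] - 100 * p), max(3 * se, 1))
    }
  }
})

test_that("single-archetype mix yields uniform labels; bad mix errors", {
  mix <- default_cohort_mix()
  mix[, ] <- 0
  mix[, "top"] <- 1
  co <- simulate_cohort(3, 3, mix = mix, seed = 2)
  expect_true(all(co$truth$archetype == "top"))
  bad <- default_cohort_mix()
  bad[1, 1] <- bad[1, 1] + 0.2
  expect_error(simulate_cohort(2, 2, mix = bad, seed = 1), "sum to 1")
})

test_that("older adults show the block-5 response-time bump only with the direction split", {
  arch <- archetype_spec("weak", initial_state = 90, drift = 0,
                         state_jitter = 1, trial_noise_sd = 0.5,
                         missing_prob = 0, rt_base = 6, rt_slope = 0,
                         rt_block5_bump = 1.5)
  plan <- build_schedule(behavioral_spec, seed = 1)
  rt_of <- function(group, spec) {
    rts <- sapply(1:150, function(s) {
      rt_change_feature(simulate_subject(arch, plan, spec, group,
                                         seed = s)$trials)
    })
    mean(rts)
  }
  old_split <- rt_of("old", behavioral_spec)
  se <- 0.5 * sqrt(2 / 12) / sqrt(150)  # rt noise 0.5 s, 12 trials/block
  expect_lt(abs(old_split - 1.5), 3 * se)
  expect_lt(abs(rt_of("young", behavioral_spec)), 3 * se)
})
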