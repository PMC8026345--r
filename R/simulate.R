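# Synthetic cohort generator: simulates subjects from learner archetypes on
# a balanced trial schedule, returning trials plus the planted ground truth.

#' Simulate one subject
#'
#' Draws a latent per-block error trajectory
#' `s_b = clamp(initial_state - drift (b-1) + random walk, 1, 180)` and
#' emits one trial record per scheduled trial: absolute errors are
#' log-normal with log-mean `log(s_b)` and SD `trial_noise_sd`, truncated
#' to 180 degrees by resampling (pointing error is physically bounded);
#' timeouts are flagged missing with probability `missing_prob`; response
#' times decay linearly across blocks with a block-5 bump for older adults
#' under the direction-split schedule, floored at 0.3 s and capped at the
#' timeout. Control trials (scanner preset) get near-ceiling small errors.
#'
#' @param archetype an [archetype_spec()].
#' @param plan a trial plan from [build_schedule()].
#' @param spec the [schedule_spec()] the plan was built from.
#' @param age_group `"young"` or `"old"`.
#' @param seed integer seed; identical seeds give identical records.
#' @param subject_id subject identifier token.
#' @return A list with `trials` (canonical trial table) and `latent`
#'   (ground-truth per-block state, degrees).
#' @export
simulate_subject <- function(archetype, plan, spec, age_group, seed,
                             subject_id = "S1") {
  stopifnot(inherits(archetype, "navlearn_archetype"))
  age_group <- match.arg(age_group, c("young", "old"))
  B <- spec$blocks
  with_local_seed(seed, {
    latent <- pmin(pmax(archetype$initial_state -
                          archetype$drift * (seq_len(B) - 1L) +
                          cumsum(stats::rnorm(B, 0, archetype$state_jitter)),
                        1), 180)
    n <- nrow(plan)
    retr <- plan$trial_kind == "retrieval"
    s_trial <- latent[plan$block]

    abs_error <- numeric(n)
    abs_error[retr] <- rlnorm_trunc(sum(retr), log(s_trial[retr]),
                                    archetype$trial_noise_sd, upper = 180)
    abs_error[!retr] <- pmin(abs(stats::rnorm(sum(!retr), 0, 8)), 180)

    sign <- sample(c(-1, 1), n, replace = TRUE)
    signed_error <- sign * abs_error
    signed_error[abs_error == 180] <- 180  # keep within (-180, 180]

    missing <- retr & stats::runif(n) < archetype$missing_prob

    bump <- ifelse(plan$block == 5L & age_group == "old" &
                     isTRUE(spec$direction_split),
                   archetype$rt_block5_bump, 0)
    rt <- archetype$rt_base - archetype$rt_slope * (plan$block - 1L) + bump +
      stats::rnorm(n, 0, 0.5)
    rt <- pmin(pmax(rt, 0.3), spec$timeout)

    trials <- data.frame(subject_id = subject_id, age_group = age_group,
                         block = plan$block,
                         trial_in_block = plan$trial_in_block,
                         intersection = plan$intersection,
                         direction = plan$direction, target = plan$target,
                         trial_kind = plan$trial_kind,
                         abs_error = ifelse(missing, NA_real_, abs_error),
                         signed_error = ifelse(missing, NA_real_, signed_error),
                         response_time = ifelse(missing, NA_real_, rt),
                         missing = missing, stringsAsFactors = FALSE)
    list(trials = validate_trial_table(trials, spec), latent = latent)
  })
}

# Truncated log-normal sampler (resampling; truncation mass is small for
# realistic scales so this terminates quickly).
rlnorm_trunc <- function(n, meanlog, sdlog, upper = 180) {
  x <- stats::rlnorm(n, meanlog, sdlog)
  for (i in 1:100) {
    bad <- x > upper
    if (!any(bad)) break
    x[bad] <- stats::rlnorm(sum(bad), meanlog[bad], sdlog)
  }
  pmin(x, upper)
}

#' Simulate a cohort of subjects
#'
#' Draws each subject's archetype from the per-age-group mixing proportions
#' and simulates it on a freshly shuffled schedule. One global seed expands
#' into per-subject substreams via a counter-based scheme, so results are
#' reproducible and independent of simulation order.
#'
#' Alongside the planted latent trajectories, the ground-truth table
#' carries analytic difference features computed from the planted states:
#' `feat_diff_mean = s_1 - s_B` and a delta-method approximation of the
#' posterior SD of that difference,
#' `feat_diff_sd = sqrt(s_1^2 + s_B^2) * trial_noise_sd / sqrt(n_block)`.
#' These emulate the model-derived feature space at cohort scale without
#' requiring an MCMC fit per subject.
#'
#' @param n_young,n_old number of subjects per age group.
#' @param mix 2 x 5 matrix of archetype proportions (rows `young`, `old`),
#'   each row summing to 1; defaults to [default_cohort_mix()].
#' @param schedule preset name or [schedule_spec()].
#' @param seed global integer seed.
#' @param archetypes named list of [archetype_spec()]s.
#' @return A list with `trials` (all subjects, canonical table), `truth`
#'   (per-subject archetype label, latent trajectory, analytic features).
#' @export
simulate_cohort <- function(n_young, n_old, mix = default_cohort_mix(),
                            schedule = "behavioral", seed = 1L,
                            archetypes = default_archetypes()) {
  if (is.character(schedule)) schedule <- schedule_spec(schedule)
  if (any(abs(rowSums(mix) - 1) > 1e-8)) {
    stopf("archetype proportions must sum to 1 per age group")
  }
  if (!identical(colnames(mix), names(archetypes))) {
    stopf("mix columns must match archetype names")
  }
  groups <- rep(c("young", "old"), c(n_young, n_old))
  n <- length(groups)
  all_trials <- vector("list", n)
  truth <- vector("list", n)
  for (i in seq_len(n)) {
    sid <- sprintf("S%03d", i)
    s_i <- substream_seed(seed, i)
    arch_name <- with_local_seed(s_i, {
      p <- mix[groups[i], ]
      names(p)[findInterval(stats::runif(1), cumsum(p), left.open = TRUE) + 1L]
    })
    arch <- archetypes[[arch_name]]
    plan <- build_schedule(schedule, seed = substream_seed(s_i, 1L))
    sim <- simulate_subject(arch, plan, schedule, groups[i],
                            seed = substream_seed(s_i, 2L), subject_id = sid)
    B <- schedule$blocks
    nb <- schedule$retrieval_per_block
    s1 <- sim$latent[1]; sB <- sim$latent[B]
    all_trials[[i]] <- sim$trials
    truth[[i]] <- data.frame(
      subject_id = sid, age_group = groups[i], archetype = arch_name,
      t(stats::setNames(sim$latent, paste0("s_", seq_len(B)))),
      feat_diff_mean = s1 - sB,
      feat_diff_sd = sqrt(s1^2 + sB^2) * arch$trial_noise_sd / sqrt(nb),
      stringsAsFactors = FALSE)
  }
  list(trials = do.call(rbind, all_trials), truth = do.call(rbind, truth),
       schedule = schedule, seed = seed)
}
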