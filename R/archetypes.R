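#' Learner archetype specification
#'
#' Generative parameters of one learner archetype for the synthetic cohort:
#' the latent per-block error level starts at `initial_state` degrees,
#' decreases by `drift` degrees per block in expectation, and wanders with
#' random-walk innovations of SD `state_jitter`. Observed absolute pointing
#' errors are log-normal around the latent level with log-scale SD
#' `trial_noise_sd`, truncated at 180 degrees. Trials time out (and are
#' recorded as missing) with probability `missing_prob`. Response times
#' decay linearly from `rt_base` by `rt_slope` per block, with a transient
#' `rt_block5_bump` added in block 5 for older adults when the experiment
#' changes approach directions at its midpoint (behavioral preset).
#'
#' @param name one of `"top"`, `"good"`, `"intermediate"`, `"weak"`, `"non"`.
#' @param initial_state degrees in (0, 180].
#' @param drift expected per-block decrease in degrees.
#' @param state_jitter SD of latent random-walk innovations (degrees).
#' @param trial_noise_sd log-scale SD of trial errors.
#' @param missing_prob timeout probability in \[0, 0.2\].
#' @param rt_base,rt_slope,rt_block5_bump response-time parameters (seconds).
#' @return An object of class `navlearn_archetype`.
#' @export
archetype_spec <- function(name, initial_state, drift, state_jitter,
                           trial_noise_sd, missing_prob,
                           rt_base, rt_slope, rt_block5_bump = 0) {
  a <- list(name = match.arg(name, c("top", "good", "intermediate", "weak",
                                     "non")),
            initial_state = initial_state, drift = drift,
            state_jitter = state_jitter, trial_noise_sd = trial_noise_sd,
            missing_prob = missing_prob, rt_base = rt_base,
            rt_slope = rt_slope, rt_block5_bump = rt_block5_bump)
  if (initial_state <= 0 || initial_state > 180) {
    stopf("initial_state must be in (0, 180]")
  }
  if (state_jitter <= 0 || trial_noise_sd <= 0) {
    stopf("state_jitter and trial_noise_sd must be > 0")
  }
  if (missing_prob < 0 || missing_prob > 0.2) {
    stopf("missing_prob must be in [0, 0.2]")
  }
  class(a) <- "navlearn_archetype"
  a
}

#' Default learner archetypes
#'
#' Five archetypes spanning the learner spectrum. Top learners acquire the
#' layout largely during familiarization (low starting error, little left
#' to learn, precise responses); good learners start near chance and reach
#' ceiling within the first half with low noise; intermediate learners
#' improve throughout with higher noise; weak learners improve little with
#' high variability; non-learners stay at chance. The numeric values are
#' fixed package constants chosen so the archetypes occupy distinct regions
#' of the (difference-mean, difference-SD) feature space.
#'
#' @return Named list of five [archetype_spec()] objects.
#' @export
default_archetypes <- function() {
  list(
    top = archetype_spec("top", initial_state = 32, drift = 2.2,
                         state_jitter = 1.2, trial_noise_sd = 0.35,
                         missing_prob = 0.01, rt_base = 3.2, rt_slope = 0.12,
                         rt_block5_bump = 0.3),
    good = archetype_spec("good", initial_state = 78, drift = 9.5,
                          state_jitter = 1.6, trial_noise_sd = 0.40,
                          missing_prob = 0.01, rt_base = 4.0, rt_slope = 0.25,
                          rt_block5_bump = 0.4),
    intermediate = archetype_spec("intermediate", initial_state = 92,
                                  drift = 6.5, state_jitter = 2.0,
                                  trial_noise_sd = 0.52, missing_prob = 0.03,
                                  rt_base = 5.5, rt_slope = 0.20,
                                  rt_block5_bump = 1.2),
    weak = archetype_spec("weak", initial_state = 98, drift = 3.2,
                          state_jitter = 2.0, trial_noise_sd = 0.62,
                          missing_prob = 0.05, rt_base = 6.0, rt_slope = 0.12,
                          rt_block5_bump = 1.5),
    non = archetype_spec("non", initial_state = 91, drift = 0,
                         state_jitter = 1.8, trial_noise_sd = 0.75,
                         missing_prob = 0.08, rt_base = 6.5, rt_slope = 0.05,
                         rt_block5_bump = 1.5)
  )
}

#' Default archetype mixing proportions per age group
#'
#' Encodes the heterogeneity typical of ageing cohorts on this task:
#' among 25 younger adults, 7 top / 14 good / 3 intermediate / 0 weak /
#' 1 non-learner; among 32 older adults, 2 / 0 / 6 / 12 / 12 -- younger
#' adults are mostly fast learners while older adults spread across the
#' whole spectrum.
#'
#' @return A 2 x 5 matrix of proportions (rows `young`, `old`) summing to 1
#'   per row.
#' @export
default_cohort_mix <- function() {
  m <- rbind(young = c(top = 7, good = 14, intermediate = 3, weak = 0,
                       non = 1) / 25,
             old = c(top = 2, good = 0, intermediate = 6, weak = 12,
                     non = 12) / 32)
  m
}
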