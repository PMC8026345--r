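#' Run configuration
#'
#' Bundles the sampler settings, clustering range, cross-validation folds
#' and chance level used across the pipeline. The `"full"` sampler preset
#' is 4 chains x 4000 iterations with a 2000-iteration warm-up (8000
#' post-warm-up draws); the `"test"` preset (4 x 1000 / 500) is a
#' desk-scale configuration for quick runs.
#'
#' @param schedule `"behavioral"` or `"fmri"`, or a [schedule_spec()].
#' @param sampler `"full"`, `"test"`, or `NULL` to use the explicit
#'   chains/iterations/warmup arguments.
#' @param chains,iterations,warmup MCMC settings; warmup iterations are
#'   discarded.
#' @param seed integer seed governing every stochastic stage.
#' @param k_range candidate numbers of clusters for learner subtyping.
#' @param folds cross-validation folds for the age-group classifier.
#' @param chance_level chance-level absolute pointing error in degrees
#'   (90 under uniform random pointing).
#' @return An object of class `navlearn_config`.
#' @export
run_config <- function(schedule = "behavioral", sampler = "full",
                       chains = 4L, iterations = 4000L, warmup = 2000L,
                       seed = 1L, k_range = 3:7, folds = 10L,
                       chance_level = 90) {
  if (!is.null(sampler)) {
    preset <- match.arg(sampler, c("full", "test"))
    if (preset == "full") {
      chains <- 4L; iterations <- 4000L; warmup <- 2000L
    } else {
      chains <- 4L; iterations <- 1000L; warmup <- 500L
    }
  }
  if (is.character(schedule)) schedule <- schedule_spec(schedule)
  cfg <- list(schedule = schedule, chains = as.integer(chains),
              iterations = as.integer(iterations), warmup = as.integer(warmup),
              seed = as.integer(seed), k_range = as.integer(k_range),
              folds = as.integer(folds), chance_level = as.numeric(chance_level))
  class(cfg) <- "navlearn_config"
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  if (cfg$warmup >= cfg$iterations) {
    stopf("invalid config: warmup (%d) must be < iterations (%d)",
          cfg$warmup, cfg$iterations)
  }
  if (cfg$chains < 2L) stopf("invalid config: at least 2 chains required")
  if (any(cfg$k_range < 2L)) stopf("invalid config: k_range must be >= 2")
  if (cfg$folds < 2L) stopf("invalid config: folds must be >= 2")
  if (cfg$chance_level <= 0 || cfg$chance_level > 180) {
    stopf("invalid config: chance_level must be in (0, 180]")
  }
  invisible(cfg)
}
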