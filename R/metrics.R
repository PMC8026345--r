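# Derived learning metrics: curves in degrees, per-block amount of
# learning (and fMRI contrast weights), and difference-distribution
# features for subgrouping.

#' Learning curve in degrees
#'
#' Per-block posterior mean and SD of the hidden state on the degrees
#' scale, `exp(mu_b)`, over all retained draws.
#'
#' @param post a `navlearn_posterior` from [fit_block_model()].
#' @return A data frame with `block`, `mean`, `sd` and the subject id as
#'   attribute `subject_id`.
#' @export
learning_curve <- function(post) {
  stopifnot(inherits(post, "navlearn_posterior"))
  if (post$model != "block") {
    stopf("learning curves are defined for the block-wise model")
  }
  if (post$meta$n_draws < 1L) stopf("empty posterior")
  st <- exp(post$draws$mu)
  out <- data.frame(block = seq_len(ncol(st)),
                    mean = colMeans(st),
                    sd = apply(st, 2, stats::sd))
  attr(out, "subject_id") <- post$meta$subject_id
  out
}

#' Per-block amount of learning and contrast weights
#'
#' The first block's learning amount is referenced to chance-level
#' performance, `L_1 = chance - state_1`, crediting learning that already
#' happened during familiarization; subsequent blocks take consecutive
#' differences, `L_b = state_{b-1} - state_b`. The vector telescopes:
#' `sum(L) = chance - state_B`. Contrast weights for fMRI parametric
#' designs are the mean-centred `L` scaled to unit Euclidean norm; a
#' constant curve at chance yields an all-zero weight vector with
#' `degenerate = TRUE` rather than an error.
#'
#' @param curve a [learning_curve()].
#' @param chance_level chance-level error in degrees (default 90).
#' @return List with `L`, `mean_amount`, `weights`, `degenerate`.
#' @export
amount_of_learning <- function(curve, chance_level = 90) {
  if (nrow(curve) < 2L) stopf("need at least two blocks")
  m <- curve$mean
  L <- c(chance_level - m[1], -diff(m))
  centered <- L - mean(L)
  nrm <- sqrt(sum(centered^2))
  degenerate <- nrm < 1e-12
  weights <- if (degenerate) rep(0, length(L)) else centered / nrm
  list(L = L, mean_amount = mean(L), weights = weights,
       degenerate = degenerate)
}

#' Difference-distribution feature
#'
#' Per-draw difference between the first and last block's state on the
#' degrees scale, `d = exp(mu_1) - exp(mu_B)` (positive = improvement),
#' summarized by a maximum-likelihood normal fit -- i.e. the sample mean
#' and SD of the difference draws. The pair (mean, SD) is the feature
#' space for learner subtyping: the mean captures how much was learned,
#' the SD the uncertainty of that judgement.
#'
#' @param post a `navlearn_posterior` from [fit_block_model()].
#' @return List with `subject_id`, `diff_mean`, `diff_sd`.
#' @export
difference_feature <- function(post) {
  stopifnot(inherits(post, "navlearn_posterior"))
  B <- ncol(post$draws$mu)
  if (B < 2L) stopf("need at least two blocks")
  if (post$meta$n_draws < 100L) {
    warnf("only %d draws: difference-SD estimate may be unstable",
          post$meta$n_draws)
  }
  d <- exp(post$draws$mu[, 1]) - exp(post$draws$mu[, B])
  list(subject_id = post$meta$subject_id,
       diff_mean = mean(d),
       diff_sd = stats::sd(d) * sqrt((length(d) - 1) / length(d)))
}
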