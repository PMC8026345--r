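#' Run the full analysis pipeline on a synthetic cohort
#'
#' End-to-end orchestration: simulate a cohort, fit the block-wise and
#' trial-wise models per subject, check convergence, compare the models by
#' PSIS-LOO, derive learning metrics and difference features, cluster
#' subjects into learner subgroups, classify age group from (mean amount
#' of learning, response-time change), and screen the design cells for
#' pointing biases. Every stage draws its seed from `config$seed`, so a
#' given (config, cohort) pair reproduces byte-identical outputs. Subjects
#' whose block-model fit fails convergence are flagged in the report, not
#' dropped.
#'
#' @param config a [run_config()].
#' @param out_dir output directory; created if needed. Writes
#'   `trials.csv`, `truth.csv`, `metrics.csv`, `subgroups.csv`,
#'   `bias.csv`, `classifier.json` and `report.json`.
#' @param n_young,n_old cohort sizes per age group.
#' @param mix archetype mixing proportions (see [simulate_cohort()]).
#' @param archetypes archetype list (see [default_archetypes()]).
#' @return The pipeline report (invisibly): per-subject convergence, LOO
#'   differences, metrics, subgroup labels, classifier summary, bias
#'   table, and provenance.
#' @export
run_pipeline <- function(config, out_dir, n_young = 6L, n_old = 6L,
                         mix = default_cohort_mix(),
                         archetypes = default_archetypes()) {
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  t0 <- Sys.time()
  stage <- function(fmt, ...) {
    message(sprintf("[navlearn %5.1fs] %s",
                    as.numeric(Sys.time() - t0, units = "secs"),
                    sprintf(fmt, ...)))
  }

  stage("simulating cohort (%d young, %d old, seed %d)", n_young, n_old,
        config$seed)
  cohort <- simulate_cohort(n_young, n_old, mix = mix,
                            schedule = config$schedule, seed = config$seed,
                            archetypes = archetypes)
  write_trial_table(cohort$trials, file.path(out_dir, "trials.csv"))
  utils::write.csv(cohort$truth, file.path(out_dir, "truth.csv"),
                   row.names = FALSE)

  subjects <- unique(cohort$trials$subject_id)
  per_subject <- vector("list", length(subjects))
  for (i in seq_along(subjects)) {
    sid <- subjects[i]
    trials_i <- cohort$trials[cohort$trials$subject_id == sid, ]
    cfg_i <- config
    cfg_i$seed <- substream_seed(config$seed, 5000L + i)
    res <- tryCatch({
      pb <- fit_block_model(trials_i, cfg_i, fallback_block_mean = TRUE)
      pt <- fit_trial_model(trials_i, cfg_i, fallback_block_mean = TRUE)
      conv <- diagnose(pb)
      loo <- loo_compare(pb, pt, trials_i)
      curve <- learning_curve(pb)
      aol <- amount_of_learning(curve, config$chance_level)
      feat <- difference_feature(pb)
      list(subject_id = sid, converged = conv$pass,
           max_rhat = conv$max_rhat, min_ess = conv$min_ess,
           loo_difference = loo$difference, loo_se = loo$se,
           loo_unreliable = loo$unreliable,
           curve = curve, L = aol$L, mean_amount = aol$mean_amount,
           weights = aol$weights,
           diff_mean = feat$diff_mean, diff_sd = feat$diff_sd,
           rt_change = as.numeric(rt_change_feature(trials_i)))
    }, error = function(e) {
      stopf("pipeline stage 'fit' failed for subject %s: %s", sid,
            conditionMessage(e))
    })
    per_subject[[i]] <- res
    stage("subject %s: rhat %.3f, loo diff %+.0f", sid, res$max_rhat,
          res$loo_difference)
  }

  B <- config$schedule$blocks
  metrics <- do.call(rbind, lapply(per_subject, function(r) {
    data.frame(subject_id = r$subject_id,
               t(stats::setNames(r$L, paste0("L_", seq_len(B)))),
               mean_amount = r$mean_amount,
               diff_mean = r$diff_mean, diff_sd = r$diff_sd,
               rt_change = r$rt_change,
               t(stats::setNames(r$weights, paste0("w_", seq_len(B)))),
               max_rhat = r$max_rhat, converged = r$converged,
               loo_difference = r$loo_difference,
               stringsAsFactors = FALSE)
  }))
  write.csv_stable(metrics, file.path(out_dir, "metrics.csv"))

  stage("clustering %d subjects", nrow(metrics))
  k_range <- config$k_range[config$k_range < nrow(metrics)]
  subgroups <- cluster_learners(metrics[, c("subject_id", "diff_mean",
                                            "diff_sd")],
                                k_range = k_range,
                                seed = substream_seed(config$seed, 7001L))
  sg <- data.frame(subject_id = names(subgroups$labels),
                   label = as.integer(subgroups$labels),
                   selected_k = subgroups$selected_k,
                   stringsAsFactors = FALSE)
  write.csv_stable(sg, file.path(out_dir, "subgroups.csv"))

  stage("classifying age group")
  groups <- cohort$truth$age_group[match(metrics$subject_id,
                                         cohort$truth$subject_id)]
  folds <- min(config$folds, min(table(groups)))
  classifier <- classify_age(
    as.matrix(metrics[, c("mean_amount", "rt_change")]), groups,
    folds = folds, seed = substream_seed(config$seed, 7002L))
  jsonlite::write_json(
    list(mean_auc = classifier$mean_auc, sd_auc = classifier$sd_auc,
         fold_auc = classifier$fold_auc,
         probabilities = as.list(stats::setNames(classifier$probabilities,
                                                 metrics$subject_id))),
    file.path(out_dir, "classifier.json"), auto_unbox = TRUE, digits = NA)

  stage("screening pointing biases")
  bias <- bias_screen(cohort$trials)
  write.csv_stable(bias, file.path(out_dir, "bias.csv"))

  report <- list(
    subjects = lapply(per_subject, function(r) {
      r[c("subject_id", "converged", "max_rhat", "min_ess", "loo_difference",
          "loo_unreliable", "mean_amount", "diff_mean", "diff_sd",
          "rt_change")]
    }),
    selected_k = subgroups$selected_k,
    silhouette = as.list(subgroups$silhouette),
    classifier_mean_auc = classifier$mean_auc,
    n_bias_cells = nrow(bias),
    n_bias_significant_adjusted = sum(bias$significant_adjusted),
    provenance = list(seed = config$seed, chains = config$chains,
                      iterations = config$iterations, warmup = config$warmup,
                      schedule = config$schedule$preset,
                      package_version = as.character(
                        utils::packageVersion("navlearn")))
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  stage("done")
  invisible(report)
}

# CSV writer with stable formatting so identical inputs give identical bytes.
write.csv_stable <- function(df, path) {
  num <- vapply(df, is.numeric, TRUE) & !vapply(df, is.integer, TRUE)
  df[num] <- lapply(df[num], function(x) sprintf("%.12g", x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
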