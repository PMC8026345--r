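# Shared fixtures and independent oracles, built in code at test time.

quick_config <- function(seed = 1L, ...) {
  run_config(sampler = "test", seed = seed, ...)
}

full_config <- function(seed = 1L, ...) {
  run_config(sampler = "full", seed = seed, ...)
}

behavioral_spec <- schedule_spec("behavioral")

# One simulated subject from a named default archetype.
sim_subject <- function(archetype = "good", seed = 1L, age_group = "young",
                        spec = behavioral_spec) {
  plan <- build_schedule(spec, seed = seed)
  simulate_subject(default_archetypes()[[archetype]], plan, spec, age_group,
                   seed = seed + 1000L)
}

# Minimal hand-built trial table: `B` blocks of `n` retrieval trials with
# given absolute errors (recycled), no missing trials.
toy_trials <- function(y, B = 8L, n = 3L, subject_id = "T1") {
  y <- rep_len(y, B * n)
  data.frame(subject_id = subject_id, age_group = "young",
             block = rep(seq_len(B), each = n),
             trial_in_block = rep(seq_len(n), B),
             intersection = "I1", direction = "D1", target = "T1",
             trial_kind = "retrieval", abs_error = y, signed_error = y,
             response_time = 3, missing = FALSE, stringsAsFactors = FALSE)
}

# Brute-force silhouette (independent of cluster::silhouette): mean over
# points of (b - a) / max(a, b).
brute_silhouette <- function(x, labels) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1L) mean(d[i, own & seq_len(n) != i]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(cl) mean(d[i, labels == cl]), 0))
    s[i] <- if (sum(own) > 1L) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# Adjusted Rand index between two labelings.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  n <- sum(tab)
  sum_ij <- sum(choose(tab, 2))
  sum_a <- sum(choose(rowSums(tab), 2))
  sum_b <- sum(choose(colSums(tab), 2))
  expected <- sum_a * sum_b / choose(n, 2)
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Mean of a log-normal truncated above, by numerical integration
# (independent oracle for the simulator's emission distribution).
truncated_lnorm_mean <- function(meanlog, sdlog, upper = 180) {
  zn <- stats::integrate(function(x) stats::dlnorm(x, meanlog, sdlog),
                         0, upper)$value
  stats::integrate(function(x) x * stats::dlnorm(x, meanlog, sdlog),
                   0, upper)$value / zn
}
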