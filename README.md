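# navlearn

Bayesian state-space modelling of spatial-learning dynamics from angular
pointing errors.

## The problem

In spatial-learning experiments, subjects are repeatedly placed at virtual
street intersections and point toward unseen target landmarks. Each trial
yields an absolute angular error in [0°, 180°]; uniformly random pointing
averages 90° (chance). Raw errors are extremely noisy, so block averages
are a poor readout of what a subject has actually learned — and in ageing
research the question is precisely how the *hidden* learning state evolves
across repeated exposures to a novel environment, and how that differs
between younger and older adults.

`navlearn` estimates that hidden state per subject with a hierarchical
Bayesian state-space model and builds the surrounding analysis pipeline on
top of it: model validation, learning metrics and fMRI contrast weights,
learner subtyping, age-group classification, circular bias analysis, and a
synthetic cohort generator with known ground truth so everything is
testable without access to raw human data.

## The model

For one subject, with blocks *b* = 1..8 and trials *t*:

- μ₁ ~ Normal(log 90, 1) — the state starts at chance on the log scale
- μ_b ~ Normal(μ_{b−1}, σ_μ) — random walk across blocks
- η_t ~ Normal(μ_{b(t)}, σ_η) — trial effects shrunk toward the block state
- y_t ~ LogNormal(η_t, σ_y), truncated to (0, 180]
- missing (timed-out) trials: η_t ~ HalfNormal(log ȳ_b, 1), no likelihood
- σ_μ, σ_η, σ_y ~ HalfNormal(0, 1)

Fitted per subject by MCMC (JAGS, 4 chains; the headline configuration is
4000 iterations with 2000 warm-up, 8000 retained draws). The trial-wise
alternative model drops η and lets the state walk per trial; PSIS-LOO
(implemented from scratch, Pareto-smoothed importance sampling with a
Zhang–Stephens generalized-Pareto tail fit) compares the two. Downstream,
the per-block state exp(μ_b) in degrees yields learning curves, per-block
learning amounts L_b (block 1 referenced to 90° chance; the L vector
telescopes to 90° minus the final state), normalized fMRI contrast
weights, and the (mean, SD) of the first-minus-last difference
distribution used to cluster subjects into learner subgroups.

## Worked example

Simulate a small cohort, fit both models for one subject, and derive its
metrics (the cohort generator plants a known latent trajectory per
subject, so you can check the answer):

```r
library(navlearn)

cohort <- simulate_cohort(n_young = 2, n_old = 2, seed = 42)
trials <- subset(cohort$trials, subject_id == "S001")

cfg <- run_config(sampler = NULL, chains = 4, iterations = 12000,
                  warmup = 6000, seed = 1)
post <- fit_block_model(trials, cfg, fallback_block_mean = TRUE)
diagnose(post)
#> <navlearn_convergence> max Rhat 1.008, min ESS 1033 -> PASS

learning_curve(post)
#>       block mean   sd
#> mu[1]     1 80.3 11.4
#> mu[2]     2 71.2  9.7
#> mu[3]     3 92.8 13.3
#> mu[4]     4 51.0  6.3
#> mu[5]     5 39.9  4.9
#> mu[6]     6 28.3  3.4
#> mu[7]     7 25.3  3.1
#> mu[8]     8  9.6  1.2
```

This subject (planted archetype: good learner) starts near 80°, learns
quickly, and ends near 10° — the planted final latent state was 11.3°,
inside the posterior band. The learning decomposition and model
comparison:

```r
aol <- amount_of_learning(learning_curve(post), chance_level = 90)
aol$mean_amount
#> 10.05        # mean amount of learning, degrees per block

alt <- fit_trial_model(trials, cfg, fallback_block_mean = TRUE)
loo_compare(post, alt, trials)
#> <navlearn_loo> elpd difference 20.0 (SE 3.1) [unreliable: high Pareto-k]

difference_feature(post)
#> difference feature: mean 70.7 deg, SD 11.5 deg
```

The positive elpd difference favours the block-wise model (the flag marks
the heavy-tailed importance ratios that come with per-observation latents;
see the vignette for the marginal alternative). The difference feature —
70.7° learned, ±11.5° — is this subject's coordinate in the clustering
space used by `cluster_learners()`.

The whole pipeline (simulate → fit → compare → metrics → cluster →
classify → bias screen) runs as one call:

```r
report <- run_pipeline(run_config(sampler = "test", seed = 1),
                       out_dir = "out", n_young = 6, n_old = 6)
```

or from a shell via the thin wrapper `inst/scripts/navlearn.R`.

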