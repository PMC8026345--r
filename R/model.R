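# Hierarchical Bayesian state-space model of block-wise learning, fitted
# per subject by MCMC (JAGS), plus the trial-wise alternative model.
#
# Generative model (block-wise):
#   mu_1 ~ Normal(log(chance), 1)                  hidden state, log-degrees
#   mu_b ~ Normal(mu_{b-1}, sigma_mu)              random walk over blocks
#   eta_t ~ Normal(mu_{b(t)}, sigma_eta)           trial effect, shrunk to block
#   y_t ~ LogNormal(eta_t, sigma_y)                observed absolute error
#   missing t: eta_t ~ HalfNormal(log(ybar_b), 1)  prior imputation, no likelihood
#   sigma_* ~ HalfNormal(0, 1), bounded below at 1e-3 so degenerate
#              (zero-variance) data cannot collapse the slice sampler
#
# Bounded support: pointing error cannot exceed 180 degrees, and for noisy
# subjects near chance the log-normal tail above 180 is far from
# negligible, so the observation distribution is truncated at 180.
#
# Sampling detail: given (mu, sigma_eta, sigma_y), eta is conditionally
# Gaussian on the log scale, so it is integrated out analytically during
# MCMC (log y_t ~ Normal(mu_b, sqrt(sigma_eta^2 + sigma_y^2)), truncated
# at log 180) and recovered, draw by draw, from its closed-form Gaussian
# conditional afterwards (the slowly varying truncation normalizer is
# dropped in that conditional). Mixing over the weakly identified
# (sigma_eta, sigma_y) ridge is much better than in the centred form.

jags_block_marginal <- "
model {
  mu[1] ~ dnorm(log_chance, 1)
  for (b in 2:B) { mu[b] ~ dnorm(mu[b-1], prec_mu) }
  for (t in 1:Nobs) { ly[t] ~ dnorm(mu[block[t]], prec_tot) T(, log_ub) }
  sigma_mu ~ dnorm(0, 1) T(0.001,)
  sigma_eta ~ dnorm(0, 1) T(0.001,)
  sigma_y ~ dnorm(0, 1) T(0.001,)
  prec_mu <- pow(sigma_mu, -2)
  prec_tot <- 1 / (pow(sigma_eta, 2) + pow(sigma_y, 2))
}"

jags_trial <- "
model {
  mu[1] ~ dnorm(log_chance, 1)
  for (t in 2:T) { mu[t] ~ dnorm(mu[t-1], prec_mu) }
  for (i in 1:Nobs) { ly[i] ~ dnorm(mu[obs[i]], prec_y) T(, log_ub) }
  sigma_mu ~ dnorm(0, 1) T(0.001,)
  sigma_y ~ dnorm(0, 1) T(0.001,)
  prec_mu <- pow(sigma_mu, -2)
  prec_y <- pow(sigma_y, -2)
}"

error_upper_bound <- 180

# Extract and order one subject's retrieval trials; returns the data block
# shared by both fit functions.
prepare_subject_data <- function(trials, config, fallback_block_mean = FALSE) {
  trials <- validate_trial_table(trials, config$schedule)
  retr <- trials[trials$trial_kind == "retrieval", ]
  if (length(unique(retr$subject_id)) != 1L) {
    stopf("fit functions take a single subject's trials (got %d subjects)",
          length(unique(retr$subject_id)))
  }
  obs <- !is.na(retr$abs_error)
  blocks_obs <- unique(retr$block[obs])
  if (sum(obs) < 1L || length(blocks_obs) < 2L) {
    stopf("need at least one observed trial in at least two blocks")
  }
  ybar <- tapply(retr$abs_error[obs], retr$block[obs], mean)
  ybar_full <- rep(NA_real_, config$schedule$blocks)
  ybar_full[as.integer(names(ybar))] <- ybar
  empty <- which(is.na(ybar_full) &
                   seq_along(ybar_full) %in% unique(retr$block))
  if (length(empty) > 0L) {
    if (!fallback_block_mean) {
      stopf(paste0("block %d has missing trials but no observed trials, so ",
                   "its block mean is undefined; re-run with ",
                   "fallback_block_mean = TRUE to use the nearest observed ",
                   "block's mean as the missing-trial prior location"),
            empty[1])
    }
    for (b in empty) {
      nearest <- blocks_obs[which.min(abs(blocks_obs - b))]
      ybar_full[b] <- ybar_full[nearest]
    }
  }
  list(trials = retr, y = retr$abs_error, block = retr$block, obs = obs,
       ybar = ybar_full, subject_id = retr$subject_id[1])
}

run_jags <- function(model_string, data, monitor, config) {
  n_adapt <- max(100L, floor(config$warmup / 2L))
  inits <- lapply(seq_len(config$chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = substream_seed(config$seed, 1000L + ch))
  })
  jm <- rjags::jags.model(textConnection(model_string), data = data,
                          n.chains = config$chains, n.adapt = n_adapt,
                          inits = inits, quiet = TRUE)
  remaining <- config$warmup - n_adapt
  if (remaining > 0L) stats::update(jm, remaining, progress.bar = "none")
  rjags::coda.samples(jm, monitor, n.iter = config$iterations - config$warmup,
                      progress.bar = "none")
}

coda_to_matrix <- function(samples) {
  mat <- do.call(rbind, lapply(samples, as.matrix))
  chain <- rep(seq_along(samples), vapply(samples, nrow, 0L))
  list(mat = mat, chain = chain)
}

new_posterior <- function(model, draws, chain, data, config) {
  structure(list(
    model = model, draws = draws, chain = as.integer(chain),
    data = data,
    meta = list(model = model, chains = config$chains,
                iterations = config$iterations, warmup = config$warmup,
                seed = config$seed, subject_id = data$subject_id,
                chance_level = config$chance_level,
                n_draws = nrow(draws$mu))
  ), class = "navlearn_posterior")
}

#' @export
print.navlearn_posterior <- function(x, ...) {
  cat(sprintf("<navlearn_posterior> %s-wise model, subject %s\n",
              x$model, x$meta$subject_id))
  cat(sprintf("  %d post-warm-up draws (%d chains x %d)\n",
              x$meta$n_draws, x$meta$chains,
              x$meta$iterations - x$meta$warmup))
  invisible(x)
}

#' Fit the block-wise state-space model to one subject
#'
#' Estimates the hidden per-block learning state of a single subject from
#' their absolute pointing errors. The state follows a random walk on the
#' log-degrees scale starting from a prior centred at the chance level;
#' trial-level effects are shrunk toward the block state and observed
#' errors are log-normal around them. Missing (timed-out) trials receive a
#' half-normal prior imputation located at the log of the observed block
#' mean and contribute no likelihood.
#'
#' @param trials canonical trial table for one subject.
#' @param config a [run_config()]; its sampler settings, seed and chance
#'   level are used.
#' @param fallback_block_mean if a block consists entirely of missing
#'   trials its block mean is undefined; set `TRUE` to fall back to the
#'   nearest observed block's mean for the missing-trial prior location.
#' @return A `navlearn_posterior` holding draws of the block states `mu`
#'   (log-degrees), trial effects `eta`, and the scales `sigma_mu`,
#'   `sigma_eta`, `sigma_y`, with chain indices and sampler metadata.
#' @export
fit_block_model <- function(trials, config, fallback_block_mean = FALSE) {
  d <- prepare_subject_data(trials, config, fallback_block_mean)
  B <- config$schedule$blocks
  samples <- run_jags(jags_block_marginal,
                      data = list(ly = log(d$y[d$obs]),
                                  block = d$block[d$obs],
                                  Nobs = sum(d$obs), B = B,
                                  log_chance = log(config$chance_level),
                                  log_ub = log(error_upper_bound)),
                      monitor = c("mu", "sigma_mu", "sigma_eta", "sigma_y"),
                      config = config)
  cm <- coda_to_matrix(samples)
  mu <- cm$mat[, paste0("mu[", seq_len(B), "]"), drop = FALSE]
  sigma_eta <- cm$mat[, "sigma_eta"]
  sigma_y <- cm$mat[, "sigma_y"]

  # Exact conditional recovery of the trial effects eta given each draw:
  # observed trials are conjugate Gaussian on the log scale; missing trials
  # are pure prior draws from HalfNormal(log(ybar_b), 1).
  S <- nrow(mu)
  Tn <- length(d$y)
  eta <- matrix(NA_real_, S, Tn)
  eta_seed <- substream_seed(config$seed, 2000L)
  with_local_seed(eta_seed, {
    w_y <- 1 / sigma_y^2
    w_e <- 1 / sigma_eta^2
    for (t in seq_len(Tn)) {
      if (d$obs[t]) {
        m <- (log(d$y[t]) * w_y + mu[, d$block[t]] * w_e) / (w_y + w_e)
        eta[, t] <- stats::rnorm(S, m, sqrt(1 / (w_y + w_e)))
      } else {
        eta[, t] <- log(d$ybar[d$block[t]]) + abs(stats::rnorm(S, 0, 1))
      }
    }
  })
  colnames(mu) <- paste0("mu[", seq_len(B), "]")
  colnames(eta) <- paste0("eta[", seq_len(Tn), "]")
  new_posterior("block",
                draws = list(mu = mu, eta = eta,
                             sigma_mu = cm$mat[, "sigma_mu"],
                             sigma_eta = sigma_eta, sigma_y = sigma_y),
                chain = cm$chain,
                data = list(y = d$y, block = d$block, obs = d$obs,
                            ybar = d$ybar, subject_id = d$subject_id),
                config = config)
}

#' Fit the trial-wise alternative model
#'
#' The simpler comparison model: the trial effects are removed and the
#' latent state itself performs a random walk across trials
#' (`mu_t ~ Normal(mu_{t-1}, sigma_mu)`, `y_t ~ LogNormal(mu_t, sigma_y)`).
#' Missing trials carry a state but no likelihood term.
#'
#' @inheritParams fit_block_model
#' @return A `navlearn_posterior` with per-trial states `mu` and scales
#'   `sigma_mu`, `sigma_y`.
#' @export
fit_trial_model <- function(trials, config, fallback_block_mean = FALSE) {
  d <- prepare_subject_data(trials, config, fallback_block_mean)
  Tn <- length(d$y)
  samples <- run_jags(jags_trial,
                      data = list(ly = log(d$y[d$obs]),
                                  obs = which(d$obs), Nobs = sum(d$obs),
                                  T = Tn,
                                  log_chance = log(config$chance_level),
                                  log_ub = log(error_upper_bound)),
                      monitor = c("mu", "sigma_mu", "sigma_y"),
                      config = config)
  cm <- coda_to_matrix(samples)
  mu <- cm$mat[, paste0("mu[", seq_len(Tn), "]"), drop = FALSE]
  new_posterior("trial",
                draws = list(mu = mu,
                             sigma_mu = cm$mat[, "sigma_mu"],
                             sigma_y = cm$mat[, "sigma_y"]),
                chain = cm$chain,
                data = list(y = d$y, block = d$block, obs = d$obs,
                            ybar = d$ybar, subject_id = d$subject_id),
                config = config)
}

# Flatten a posterior's draws to a long (chain, draw, parameter, value)
# data frame; inverse of long_to_draws.
draws_to_long <- function(post) {
  draw_in_chain <- stats::ave(seq_along(post$chain), post$chain, FUN = seq_along)
  pieces <- lapply(names(post$draws), function(p) {
    v <- post$draws[[p]]
    if (is.matrix(v)) {
      data.frame(chain = rep(post$chain, ncol(v)),
                 draw = rep(draw_in_chain, ncol(v)),
                 parameter = rep(colnames(v), each = nrow(v)),
                 value = as.vector(v), stringsAsFactors = FALSE)
    } else {
      data.frame(chain = post$chain, draw = draw_in_chain, parameter = p,
                 value = v, stringsAsFactors = FALSE)
    }
  })
  do.call(rbind, pieces)
}

#' Persist / load a posterior store
#'
#' Language-neutral on-disk format: a tidy long CSV of draws (columns
#' `chain`, `draw`, `parameter`, `value`, printed with 17 significant
#' digits so doubles round-trip bitwise) plus a JSON sidecar holding the
#' sampler metadata and the fitted data. `path` is a directory containing
#' `draws.csv` and `meta.json`.
#'
#' @param post a `navlearn_posterior`.
#' @param path directory to write to / read from.
#' @return `persist_posterior` returns `path` invisibly; `read_posterior`
#'   returns the reconstructed `navlearn_posterior`, and fails (without a
#'   partial object) on truncated or inconsistent stores.
#' @export
persist_posterior <- function(post, path) {
  stopifnot(inherits(post, "navlearn_posterior"))
  if (post$meta$n_draws < 1L) stopf("refusing to persist an empty posterior")
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  long <- draws_to_long(post)
  long$value <- sprintf("%.17g", long$value)
  utils::write.csv(long, file.path(path, "draws.csv"), row.names = FALSE,
                   quote = FALSE)
  meta <- post$meta
  meta$chain_index <- post$chain
  meta$data <- post$data
  meta$n_rows <- nrow(long)
  jsonlite::write_json(meta, file.path(path, "meta.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname persist_posterior
#' @export
read_posterior <- function(path) {
  f_draws <- file.path(path, "draws.csv")
  f_meta <- file.path(path, "meta.json")
  if (!file.exists(f_draws) || !file.exists(f_meta)) {
    stopf("posterior store at %s is missing draws.csv or meta.json", path)
  }
  meta <- tryCatch(jsonlite::read_json(f_meta, simplifyVector = TRUE),
                   error = function(e) stopf("corrupted posterior metadata: %s",
                                             conditionMessage(e)))
  long <- tryCatch(utils::read.csv(f_draws, stringsAsFactors = FALSE),
                   error = function(e) stopf("corrupted posterior store: %s",
                                             conditionMessage(e)))
  if (!identical(names(long), c("chain", "draw", "parameter", "value")) ||
      nrow(long) != meta$n_rows) {
    stopf("posterior store at %s is truncated or inconsistent", path)
  }
  S <- meta$n_draws
  chain <- as.integer(meta$chain_index)
  params <- unique(long$parameter)
  grab <- function(pat) {
    cols <- grep(pat, params, value = TRUE)
    if (length(cols) == 0L) return(NULL)
    idx <- order(as.integer(sub(".*\\[(\\d+)\\]", "\\1", cols)))
    cols <- cols[idx]
    m <- vapply(cols, function(p) long$value[long$parameter == p],
                numeric(S))
    colnames(m) <- cols
    m
  }
  draws <- list(mu = grab("^mu\\["))
  for (p in c("eta")) {
    m <- grab(paste0("^", p, "\\["))
    if (!is.null(m)) draws[[p]] <- m
  }
  for (p in c("sigma_mu", "sigma_eta", "sigma_y")) {
    if (p %in% params) draws[[p]] <- long$value[long$parameter == p]
  }
  data <- meta$data
  data$obs <- as.logical(data$obs)
  cfg_like <- list(chains = meta$chains, iterations = meta$iterations,
                   warmup = meta$warmup, seed = meta$seed,
                   chance_level = meta$chance_level)
  post <- structure(list(model = meta$model, draws = draws, chain = chain,
                         data = data,
                         meta = meta[c("model", "chains", "iterations",
                                       "warmup", "seed", "subject_id",
                                       "chance_level", "n_draws")]),
                    class = "navlearn_posterior")
  if (nrow(post$draws$mu) != S) {
    stopf("posterior store at %s is truncated or inconsistent", path)
  }
  post
}
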