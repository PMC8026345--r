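# MCMC convergence diagnostics: split-Rhat and bulk effective sample size.

#' Split-chain potential scale reduction factor
#'
#' Each chain is split in half and the classical between/within-variance
#' Rhat is computed over the resulting half-chains, so within-chain trends
#' inflate the diagnostic as well as between-chain disagreement. Chains
#' with zero total variance (degenerate but perfectly agreeing draws)
#' return exactly 1.
#'
#' @param x numeric vector of draws.
#' @param chain integer chain index per draw.
#' @return The split-Rhat point estimate.
#' @export
split_rhat <- function(x, chain) {
  halves <- split_half_chains(x, chain)
  n <- min(lengths(halves))
  halves <- lapply(halves, function(h) h[seq_len(n)])
  means <- vapply(halves, mean, 0)
  vars <- vapply(halves, stats::var, 0)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (W < .Machine$double.eps && B < .Machine$double.eps) return(1)
  var_plus <- (n - 1) / n * W + B / n
  sqrt(var_plus / W)
}

split_half_chains <- function(x, chain) {
  if (length(unique(chain)) < 2L) {
    stopf("Rhat requires at least two chains")
  }
  out <- list()
  for (ch in unique(chain)) {
    v <- x[chain == ch]
    h <- floor(length(v) / 2L)
    out <- c(out, list(v[seq_len(h)], v[(h + 1L):(2L * h)]))
  }
  out
}

#' Bulk effective sample size
#'
#' Autocorrelation-based ESS summed over split half-chains (via
#' [coda::effectiveSize()]), capped at the total number of draws.
#'
#' @inheritParams split_rhat
#' @return Effective sample size estimate.
#' @export
bulk_ess <- function(x, chain) {
  halves <- split_half_chains(x, chain)
  ess <- sum(vapply(halves, function(h) {
    if (stats::var(h) < .Machine$double.eps) return(length(h))
    as.numeric(coda::effectiveSize(coda::mcmc(h)))
  }, 0))
  min(ess, length(x))
}

#' Convergence report for a fitted posterior
#'
#' Computes split-Rhat and bulk ESS for every sampled parameter (block
#' states / trial states and noise scales; the block model's trial effects
#' are exact conditional draws and inherit the states' convergence). The
#' fit passes if the largest Rhat and smallest ESS meet the thresholds.
#'
#' @param post a `navlearn_posterior` with at least two chains.
#' @param rhat_max,ess_min pass thresholds (defaults 1.05 and 400).
#' @return A `navlearn_convergence` object: per-parameter table plus a
#'   `pass` flag.
#' @export
diagnose <- function(post, rhat_max = 1.05, ess_min = 400) {
  stopifnot(inherits(post, "navlearn_posterior"))
  if (length(unique(post$chain)) < 2L) {
    stopf("Rhat is undefined for a single chain")
  }
  pars <- list()
  mu <- post$draws$mu
  for (j in seq_len(ncol(mu))) pars[[colnames(mu)[j]]] <- mu[, j]
  for (p in c("sigma_mu", "sigma_eta", "sigma_y")) {
    if (!is.null(post$draws[[p]])) pars[[p]] <- post$draws[[p]]
  }
  tab <- data.frame(
    parameter = names(pars),
    rhat = vapply(pars, split_rhat, 0, chain = post$chain),
    ess = vapply(pars, bulk_ess, 0, chain = post$chain),
    stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  structure(list(table = tab,
                 max_rhat = max(tab$rhat), min_ess = min(tab$ess),
                 pass = max(tab$rhat) <= rhat_max && min(tab$ess) >= ess_min,
                 thresholds = c(rhat_max = rhat_max, ess_min = ess_min)),
            class = "navlearn_convergence")
}

#' @export
print.navlearn_convergence <- function(x, ...) {
  cat(sprintf("<navlearn_convergence> max Rhat %.3f, min ESS %.0f -> %s\n",
              x$max_rhat, x$min_ess, if (x$pass) "PASS" else "FAIL"))
  invisible(x)
}
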