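# Circular statistics for signed pointing errors: wrapping, von Mises
# utilities, the Watson-Williams test, and the cohort-level bias screen.

#' Wrap a signed pointing error into (-180, 180]
#'
#' `((response - target + 180) mod 360) - 180`, with the -180 boundary
#' mapped to +180 so the result lies in (-180, 180].
#'
#' @param response_angle,target_angle angles in degrees.
#' @return Signed angular deviation in degrees.
#' @export
wrap_signed_error <- function(response_angle, target_angle) {
  w <- ((response_angle - target_angle + 180) %% 360) - 180
  w[w == -180] <- 180
  w
}

#' Monte-Carlo chance level of the absolute pointing error
#'
#' Under uniform random pointing the wrapped signed error is uniform on
#' (-180, 180], so the expected absolute error is 90 degrees exactly; this
#' estimates it by simulation as a calibration check.
#'
#' @param n number of simulated trials.
#' @param seed integer seed.
#' @return Mean absolute wrapped error in degrees.
#' @export
chance_level_mc <- function(n = 1e6, seed = 1L) {
  with_local_seed(seed, {
    response <- stats::runif(n, 0, 360)
    target <- stats::runif(n, 0, 360)
    mean(abs(wrap_signed_error(response, target)))
  })
}

deg2rad <- function(x) x * pi / 180

circ_resultant <- function(angles_deg) {
  a <- deg2rad(angles_deg)
  sqrt(sum(cos(a))^2 + sum(sin(a))^2)
}

# Maximum-likelihood concentration estimate from the mean resultant
# length, via the standard inverse-A(kappa) approximation.
kappa_from_rbar <- function(rbar) {
  if (rbar < 0.53) {
    2 * rbar + rbar^3 + 5 * rbar^5 / 6
  } else if (rbar < 0.85) {
    -0.4 + 1.39 * rbar + 0.43 / (1 - rbar)
  } else {
    1 / (rbar^3 - 4 * rbar^2 + 3 * rbar)
  }
}

#' Von Mises random deviates
#'
#' Best-Fisher rejection sampler; used by the calibration simulations.
#'
#' @param n number of deviates.
#' @param mu mean direction in degrees.
#' @param kappa concentration parameter (> 0).
#' @return Angles in degrees, wrapped into (-180, 180].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  got <- 0L
  while (got < n) {
    m <- n - got
    u1 <- stats::runif(m); u2 <- stats::runif(m); u3 <- stats::runif(m)
    z <- cos(pi * u1)
    f <- (1 + r * z) / (r + z)
    c0 <- kappa * (r - f)
    ok <- (c0 * (2 - c0) - u2 > 0) | (log(c0 / u2) + 1 - c0 >= 0)
    theta <- sign(u3[ok] - 0.5) * acos(f[ok])
    take <- min(sum(ok), m)
    out[got + seq_len(take)] <- theta[seq_len(take)]
    got <- got + take
  }
  wrap_signed_error(out * 180 / pi + mu, 0)
}

#' Watson-Williams test for equal mean directions
#'
#' Circular analogue of a one-way ANOVA: compares the mean directions of
#' two or more samples of angles via the resultant lengths, with the
#' classical correction factor `K = 1 + 3/(8 kappa)` where `kappa` is
#' estimated from the pooled mean resultant length. The test assumes
#' reasonably concentrated von Mises samples; a validity warning is
#' attached when the pooled mean resultant length falls below 0.45 or any
#' group has fewer than 5 observations.
#'
#' @param groups list of numeric vectors of angles in degrees.
#' @return List with `statistic` (F), `df` (numerator, denominator),
#'   `p.value`, `kappa`, `rbar_pooled`, `validity_warning`.
#' @export
watson_williams <- function(groups) {
  if (length(groups) < 2L) stopf("need at least two groups")
  ns <- lengths(groups)
  if (any(ns < 2L)) stopf("each group needs at least 2 observations")
  N <- sum(ns)
  k <- length(groups)
  Ri <- vapply(groups, circ_resultant, 0)
  R <- circ_resultant(unlist(groups))
  rbar_w <- sum(Ri) / N
  kappa <- kappa_from_rbar(rbar_w)
  K <- 1 + 3 / (8 * kappa)
  sumRi <- sum(Ri)
  denom <- N - sumRi
  Fstat <- if (denom < .Machine$double.eps) {
    if (sumRi - R < .Machine$double.eps) 0 else Inf
  } else {
    K * ((N - k) * (sumRi - R)) / ((k - 1) * denom)
  }
  Fstat <- max(Fstat, 0)
  p <- stats::pf(Fstat, k - 1, N - k, lower.tail = FALSE)
  list(statistic = Fstat, df = c(k - 1, N - k), p.value = p,
       kappa = kappa, rbar_pooled = rbar_w,
       validity_warning = rbar_w < 0.45 || any(ns < 5L))
}

#' Screen all design cells for age-group pointing biases
#'
#' Runs a Watson-Williams test comparing the signed pointing errors of the
#' two age groups in each intersection x direction x target cell (32 cells
#' in the full design), with Bonferroni adjustment over the cells actually
#' tested. Cells in which either age group is absent are skipped with a
#' notice.
#'
#' @param trials cohort trial table (both age groups).
#' @param alpha significance level (default 0.05).
#' @return Data frame with one row per tested cell: group sizes, F,
#'   degrees of freedom, raw and Bonferroni-adjusted p-values and
#'   decisions.
#' @export
bias_screen <- function(trials, alpha = 0.05) {
  retr <- trials[trials$trial_kind == "retrieval" &
                   !is.na(trials$signed_error), ]
  cells <- unique(retr[, c("intersection", "direction", "target")])
  cells <- cells[order(cells$intersection, cells$direction, cells$target), ]
  rows <- list()
  for (i in seq_len(nrow(cells))) {
    sel <- retr$intersection == cells$intersection[i] &
      retr$direction == cells$direction[i] & retr$target == cells$target[i]
    young <- retr$signed_error[sel & retr$age_group == "young"]
    old <- retr$signed_error[sel & retr$age_group == "old"]
    if (length(young) < 2L || length(old) < 2L) {
      message(sprintf("bias_screen: skipping cell %s/%s/%s (insufficient data)",
                      cells$intersection[i], cells$direction[i],
                      cells$target[i]))
      next
    }
    ww <- watson_williams(list(young = young, old = old))
    rows[[length(rows) + 1L]] <- data.frame(
      intersection = cells$intersection[i], direction = cells$direction[i],
      target = cells$target[i], n_young = length(young), n_old = length(old),
      F = ww$statistic, df1 = ww$df[1], df2 = ww$df[2], p = ww$p.value,
      validity_warning = ww$validity_warning, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  m <- nrow(out)
  out$p_bonferroni <- pmin(out$p * m, 1)
  out$significant_raw <- out$p < alpha
  out$significant_adjusted <- out$p_bonferroni < alpha
  rownames(out) <- NULL
  out
}
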