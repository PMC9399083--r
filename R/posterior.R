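# Posterior point/interval summaries and convergence diagnostics: posterior
# medians, shortest (highest posterior density) intervals, one-tailed
# posterior probabilities and the Gelman-Rubin potential scale reduction
# factor.

#' Highest posterior density interval
#'
#' Shortest contiguous interval of the sorted draws containing
#' `ceiling(mass * n)` draws; ties are broken by the lowest start.
#'
#' @param draws Numeric vector of posterior draws (length >= 2).
#' @param mass Probability mass, in (0, 1). Default 0.95.
#' @return Numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(draws, mass = 0.95) {
  if (length(draws) < 2) stop("need at least 2 draws for an HPD interval")
  if (!(mass > 0 && mass < 1)) stop("mass must be in (0, 1)")
  x <- sort(draws)
  n <- length(x)
  m <- ceiling(mass * n)
  if (m >= n) return(c(x[1], x[n]))
  starts <- seq_len(n - m + 1L)
  widths <- x[starts + m - 1L] - x[starts]
  i <- which.min(widths)  # which.min returns the first (lowest-start) minimum
  c(x[i], x[i + m - 1L])
}

#' One-tailed posterior probability
#'
#' The proportion of the posterior on the opposite side of zero from the
#' posterior median: for a positive median, the fraction of draws strictly
#' below zero; for a negative median, the fraction strictly above. Draws
#' exactly at zero count in neither tail; a median of exactly zero gives 0.5.
#'
#' @param draws Numeric vector of posterior draws (length >= 1).
#' @return Probability in \[0, 1\].
#' @export
one_tailed_p <- function(draws) {
  if (length(draws) < 1) stop("need at least 1 draw")
  med <- median(draws)
  if (med > 0) mean(draws < 0)
  else if (med < 0) mean(draws > 0)
  else 0.5
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Compares between-chain and within-chain variances:
#' `sqrt((((n - 1) / n) * W + B / n) / W)` with the standard definitions of
#' `W` (mean within-chain variance) and `B` (n times the variance of chain
#' means). Values below 1.2 (lenient) and 1.1 (strict) are conventionally
#' taken to indicate convergence.
#'
#' @param chain_blocks List of per-chain numeric vectors (>= 2 chains, equal
#'   lengths >= 2).
#' @return List with `psrf`, `converged_strict` (< 1.1), `converged_lenient`
#'   (< 1.2), and `degenerate` (zero within-chain variance).
#' @export
psrf <- function(chain_blocks) {
  if (length(chain_blocks) < 2)
    stop("PSRF needs at least 2 chains; diagnostic unavailable for a single chain")
  len <- vapply(chain_blocks, length, 1L)
  if (any(len < 2) || length(unique(len)) != 1)
    stop("chains must have equal lengths >= 2")
  n <- len[1]
  means <- vapply(chain_blocks, mean, 1)
  W <- mean(vapply(chain_blocks, var, 1))
  B <- n * var(means)
  if (W == 0)
    return(list(psrf = NA_real_, converged_strict = NA,
                converged_lenient = NA, degenerate = TRUE))
  r <- sqrt((((n - 1) / n) * W + B / n) / W)
  list(psrf = r, converged_strict = r < 1.1, converged_lenient = r < 1.2,
       degenerate = FALSE)
}

psrf_value <- function(chain_blocks) psrf(chain_blocks)$psrf

#' Summarise a fitted model
#'
#' Per-parameter posterior median, 95% HPD interval, one-tailed posterior
#' p-value, PSRF and retained draw count, ordered as a coefficient table:
#' the four focal blocks of structural coefficients (alive predictors, then
#' age), then free intercepts, measurement and covariance parameters.
#'
#' @param object A `gi_fit` (or `gi_draws`).
#' @param mass HPD mass (default 0.95).
#' @param ... Unused.
#' @return A data frame of class `gi_summary` with columns `parameter`,
#'   `block`, `median`, `hpd_lower`, `hpd_upper`, `p_one_tailed`, `psrf`,
#'   `n_draws`.
#' @export
summary.gi_fit <- function(object, mass = 0.95, ...) {
  draws <- if (inherits(object, "gi_fit")) object$draws else object
  chains <- draws$chains
  pooled <- do.call(rbind, chains)
  pars <- colnames(pooled)
  one <- function(name) {
    x <- pooled[, name]
    hpd <- hpd_interval(x, mass)
    rhat <- if (length(chains) >= 2) {
      blocks <- lapply(chains, function(m) m[, name])
      psrf(blocks)$psrf
    } else NA_real_
    data.frame(parameter = name,
               block = sub("\\[.*", "", name),
               median = median(x), hpd_lower = hpd[1], hpd_upper = hpd[2],
               p_one_tailed = one_tailed_p(x),
               psrf = rhat, n_draws = length(x),
               stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, lapply(pars, one))
  ord <- order(match(out$block, c("beta", "alpha", "lambda", "tau", "psi",
                                  "phantom_pi", "phantom_var")))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("gi_summary", class(out))
  out
}

#' @export
print.gi_summary <- function(x, digits = 3, ...) {
  y <- x
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], round, digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Posterior latent correlations
#'
#' Correlations among the latent investment factors, computed per retained
#' draw from the latent error covariance and then summarised by the
#' posterior median and HPD interval (the nonlinear transform is applied
#' before, not after, summarising).
#'
#' @param fit A `gi_fit` or `gi_draws`.
#' @param mass HPD mass.
#' @return Data frame with one row per factor pair: `pair`, `median`,
#'   `hpd_lower`, `hpd_upper`.
#' @export
latent_correlations <- function(fit, mass = 0.95) {
  draws <- if (inherits(fit, "gi_fit")) fit$draws else fit
  fn <- draws$problem_meta$factor_names
  G <- draws$problem_meta$G
  pooled <- do.call(rbind, draws$chains)
  rows <- list()
  for (b in seq_len(G - 1)) for (a in seq((b + 1), G)) {
    cov_ab <- pooled[, sprintf("psi[%s,%s]", fn[a], fn[b])]
    va <- pooled[, sprintf("psi[%s,%s]", fn[a], fn[a])]
    vb <- pooled[, sprintf("psi[%s,%s]", fn[b], fn[b])]
    r <- cov_ab / sqrt(va * vb)
    hpd <- hpd_interval(r, mass)
    rows[[length(rows) + 1L]] <- data.frame(
      pair = paste0(fn[a], "-", fn[b]), median = median(r),
      hpd_lower = hpd[1], hpd_upper = hpd[2], stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Convergence report
#'
#' PSRF per parameter with strict (1.1) and lenient (1.2) convergence flags.
#' Parameters with zero within-chain variance (fixed by identification, e.g.
#' the marker loading) are flagged degenerate rather than assigned a factor.
#'
#' @param fit A `gi_fit` or `gi_draws`.
#' @return Data frame `parameter`, `psrf`, `degenerate`, `converged_strict`,
#'   `converged_lenient`.
#' @export
convergence_report <- function(fit) {
  draws <- if (inherits(fit, "gi_fit")) fit$draws else fit
  chains <- draws$chains
  if (length(chains) < 2)
    stop("PSRF needs at least 2 chains; rerun with n_chains >= 2")
  do.call(rbind, lapply(colnames(chains[[1]]), function(p) {
    r <- psrf(lapply(chains, function(m) m[, p]))
    data.frame(parameter = p, psrf = r$psrf, degenerate = r$degenerate,
               converged_strict = r$converged_strict,
               converged_lenient = r$converged_lenient,
               stringsAsFactors = FALSE)
  }))
}

#' Trace and autocorrelation plots
#'
#' Base-graphics trace (all chains overlaid) and autocorrelation plots for a
#' named parameter; the visual counterpart of the PSRF report.
#'
#' @param fit A `gi_fit` or `gi_draws`.
#' @param parameter Parameter name (a column of the draws).
#' @param lag_max Maximum autocorrelation lag.
#' @export
plot_trace <- function(fit, parameter, lag_max = 50) {
  draws <- if (inherits(fit, "gi_fit")) fit$draws else fit
  chains <- lapply(draws$chains, function(m) m[, parameter])
  old <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(old))
  rng <- range(unlist(chains))
  graphics::plot(chains[[1]], type = "l", ylim = rng, xlab = "retained draw",
                 ylab = parameter, main = "trace", col = 1)
  if (length(chains) > 1)
    for (i in 2:length(chains)) graphics::lines(chains[[i]], col = i)
  pooled <- unlist(chains)
  if (var(pooled) > 0) {
    ac <- stats::acf(chains[[1]], lag.max = lag_max, plot = FALSE)
    graphics::plot(ac, main = "autocorrelation (chain 1)")
  }
  invisible(NULL)
}
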