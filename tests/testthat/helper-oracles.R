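# Shared fixtures and independent oracles used across the test files.
# All fixtures are built in code; the oracles are deliberately naive
# (closed forms, grids, rejection samplers) and independent of the sampler.

# --- closed-form conjugate posterior for Bayesian linear regression with
#     known noise variance: y = X b + e, e ~ N(0, v), b ~ N(0, prior_var I)
conjugate_lm_posterior <- function(X, y, v, prior_var) {
  prec <- crossprod(X) / v + diag(1 / prior_var, ncol(X))
  cov <- solve(prec)
  mean <- cov %*% (crossprod(X, y) / v)
  list(mean = drop(mean), sd = sqrt(diag(cov)), cov = cov)
}

# --- 1-D grid posterior for the binary-probit reduction:
#     P(y = 2 | x) = pnorm(beta * x / sqrt(psi + 1)), flat-ish normal prior
grid_posterior_beta <- function(x, y, psi = 1, prior_sd = 100,
                                grid = seq(-2, 4, length.out = 4001)) {
  s <- sqrt(psi + 1)
  loglik <- vapply(grid, function(b) {
    p <- pnorm(b * x / s)
    sum(ifelse(y == 2L, log(p), log1p(-p)))
  }, 1)
  logpost <- loglik + dnorm(grid, 0, prior_sd, log = TRUE)
  w <- exp(logpost - max(logpost))
  list(grid = grid, prob = w / sum(w))
}

# total variation distance between MCMC draws and a grid posterior, using
# equal-probability bins of the grid distribution
tv_distance <- function(draws, grid_post, n_bins = 20) {
  cdf <- cumsum(grid_post$prob)
  edges <- unique(c(-Inf, vapply(seq_len(n_bins - 1) / n_bins, function(q)
    grid_post$grid[which(cdf >= q)[1]], 1), Inf))
  p_grid <- diff(c(0, vapply(edges[-1], function(e)
    sum(grid_post$prob[grid_post$grid <= e]), 1)))
  p_mcmc <- as.vector(table(cut(draws, edges)) / length(draws))
  0.5 * sum(abs(p_grid - p_mcmc))
}

# batch-means Monte-Carlo standard error of the mean of a (possibly
# autocorrelated) chain
mcse_mean <- function(x, n_batches = 50) {
  n <- length(x)
  bs <- floor(n / n_batches)
  bm <- vapply(seq_len(n_batches), function(b)
    mean(x[((b - 1) * bs + 1):(b * bs)]), 1)
  sd(bm) / sqrt(n_batches)
}

ess_of <- function(x) max((sd(x) / mcse_mean(x))^2, 4)

# --- toy sampling problems -------------------------------------------------

# continuous single-factor, single-marker-indicator problem (degenerate
# augmentation-free mode); psi treated as known by excluding it from updates
toy_continuous_problem <- function(X, y, psi = 1) {
  n <- length(y)
  kinvest:::new_problem(
    Y = matrix(y, n, 1), obs = matrix(TRUE, n, 1),
    item_factor = 1L, ncat = 2L, lam_group = 0L, lam_fixed = 1,
    tau_group = 0L, tau_ncat = integer(), X = list(f1 = X),
    psi_scale = matrix(psi, 1, 1), psi_df = 3, continuous = TRUE)
}

# binary-item ordinal probit problem with fixed threshold at 0
toy_binary_problem <- function(x, y) {
  n <- length(y)
  kinvest:::new_problem(
    Y = matrix(y, n, 1), obs = matrix(TRUE, n, 1),
    item_factor = 1L, ncat = 2L, lam_group = 0L, lam_fixed = 1,
    tau_group = 1L, tau_ncat = c(y1 = 2L), X = list(f1 = cbind(x = x)),
    psi_scale = matrix(1, 1, 1), psi_df = 3, continuous = FALSE)
}

toy_chain_config <- function(iterations, burnin = 0, thin = 1, seed = 421) {
  chain_config(n_chains = 1, iterations = iterations, burnin = burnin,
               thin = thin, seed = seed)
}

# small study-scale cohort + design, memoised per seed so several test files
# can share one fit
fit_cache <- new.env(parent = emptyenv())

cached_small_fit <- function() {
  if (!is.null(fit_cache$small)) return(fit_cache$small)
  coh <- generate_cohort(default_truth(), 500, seed = 2024)
  design <- encode_design(apply_exclusions(coh$survey)$table)
  cfg <- chain_config(n_chains = 2, iterations = 1500, burnin = 700,
                      thin = 2, seed = 99)
  fit_cache$small <- list(cohort = coh, design = design,
                          fit = fit_bsem(design, default_model_spec(), cfg))
  fit_cache$small
}

# invariant checks on every retained draw of a fit
check_fit_invariants <- function(fit) {
  pooled <- pooled_draws(fit)
  spec <- fit$spec
  types <- spec$types
  marker <- spec$items$name[spec$items$is_marker]
  ok_marker <- all(pooled[, paste0("lambda[", marker, "_", types, "]")] == 1)
  ref <- spec$structural$reference_type
  ok_alpha <- all(pooled[, paste0("alpha[", ref, "]")] == 0)
  ok_tau <- TRUE
  for (it in spec$items$name) {
    tcols <- grep(paste0("tau\\[", it, ","), colnames(pooled))
    if (length(tcols) > 1) {
      tmat <- pooled[, tcols, drop = FALSE]
      ok_tau <- ok_tau && all(apply(tmat, 1, function(v) all(diff(v) > 0)))
    }
  }
  ok_psi <- TRUE
  G <- length(types)
  for (r in seq_len(nrow(pooled))) {
    P <- matrix(0, G, G)
    for (b in seq_len(G)) for (a in seq(b, G)) {
      v <- pooled[r, sprintf("psi[%s,%s]", types[a], types[b])]
      P[a, b] <- P[b, a] <- v
    }
    ev <- eigen(P, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) <= 0) { ok_psi <- FALSE; break }
  }
  list(marker = ok_marker, alpha_ref = ok_alpha, tau = ok_tau, psi = ok_psi)
}
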