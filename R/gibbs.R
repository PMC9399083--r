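# R-side interface to the compiled Gibbs sampler: problem assembly from a
# model spec + design data, deterministic initialization, chain orchestration
# and the fitted-model container.

UPDATE_BLOCKS <- c("ystar", "eta", "lambda", "tau", "beta", "phantom", "psi")

# Generic sampling problem (internal). Toy reductions used by the oracle
# tests are built through this same constructor, so the production model and
# the test models share one code path.
new_problem <- function(Y, obs, item_factor, ncat, lam_group, lam_fixed,
                        tau_group, tau_ncat, X, factor_names = names(X),
                        beta_var = 100^2, lam_var = 5, tau_var = 1,
                        psi_scale = NULL, psi_df = NULL,
                        continuous = FALSE,
                        Gamma = NULL, xph = NULL, ph_coef = NULL,
                        ph_names = NULL,
                        item_names = colnames(Y)) {
  G <- length(X)
  n <- nrow(Y)
  K <- ncol(Y)
  if (is.null(factor_names)) factor_names <- paste0("f", seq_len(G))
  if (is.null(item_names)) item_names <- paste0("y", seq_len(K))
  if (is.null(psi_scale)) psi_scale <- diag(G)
  if (is.null(psi_df)) psi_df <- G + 1
  if (psi_df <= G - 1) stop("improper inverse-Wishart df for dimension ", G)
  X <- lapply(X, function(x) {
    x <- as.matrix(x)
    if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
    x
  })
  nph <- if (is.null(Gamma)) 0L else ncol(Gamma)
  n_lam <- if (any(lam_group > 0)) max(lam_group) else 0L
  n_tau <- if (any(tau_group > 0)) max(tau_group) else 0L
  stopifnot(length(tau_ncat) == n_tau)

  # parameter names, in the order the sampler records them
  nm_beta <- unlist(lapply(seq_len(G), function(g) {
    cn <- colnames(X[[g]])
    ifelse(cn == "(Intercept)", paste0("alpha[", factor_names[g], "]"),
           paste0("beta[", factor_names[g], "<-", cn, "]"))
  }))
  nm_lam <- paste0("lambda[", item_names, "]")
  nm_tau <- unlist(lapply(seq_len(n_tau), function(t)
    paste0("tau[", if (!is.null(names(tau_ncat))) names(tau_ncat)[t] else t,
           ",", seq_len(tau_ncat[t] - 1L), "]")))
  nm_psi <- unlist(lapply(seq_len(G), function(b)
    paste0("psi[", factor_names[seq(b, G)], ",", factor_names[b], "]")))
  nm_ph <- if (nph > 0) as.vector(rbind(paste0("phantom_pi[", ph_names, "]"),
                                        paste0("phantom_var[", ph_names, "]")))
           else character()

  structure(list(
    Y = matrix(as.numeric(Y), n, K), obs = obs,
    item_factor = as.integer(item_factor), ncat = as.integer(ncat),
    lam_group = as.integer(lam_group), lam_fixed = as.numeric(lam_fixed),
    n_lam = as.integer(n_lam),
    tau_group = as.integer(tau_group), n_tau = as.integer(n_tau),
    tau_ncat = as.integer(tau_ncat),
    X = X, beta_var = beta_var, lam_var = lam_var, tau_var = tau_var,
    psi_scale = psi_scale, psi_df = psi_df,
    continuous = continuous,
    nph = as.integer(nph),
    Gamma = if (nph) Gamma else matrix(0, G, 0),
    xph = if (nph) xph else matrix(0, n, 0),
    ph_coef = if (nph) as.numeric(ph_coef) else numeric(),
    ph_pi_var = 100^2, ph_s2_shape = 2.5, ph_s2_rate = 0.5,
    factor_names = factor_names, item_names = item_names,
    par_names = c(nm_beta, nm_lam, nm_tau, nm_psi, nm_ph),
    n = n, K = K, G = G), class = "gi_problem")
}

# Assemble the sampling problem for the four-factor grandparental model.
problem_from_spec <- function(spec, design) {
  items <- spec$items
  G <- length(spec$types)
  n_items <- nrow(items)
  free_item <- spec$invariance$free_loading_item
  item_factor <- rep(seq_len(G), each = n_items)
  item_of <- rep(seq_len(n_items), times = G)

  lam_group <- integer(n_items * G)
  lam_fixed <- numeric(n_items * G)
  grp <- 0L
  shared_grp <- setNames(rep(NA_integer_, n_items), items$name)
  free_grp <- matrix(NA_integer_, n_items, G)
  for (k in seq_along(item_factor)) {
    j <- item_of[k]; g <- item_factor[k]
    if (items$is_marker[j]) {
      lam_group[k] <- 0L
      lam_fixed[k] <- 1
    } else if (items$name[j] == free_item) {
      lam_group[k] <- grp <- grp + 1L
    } else {
      if (is.na(shared_grp[j])) shared_grp[j] <- grp <- grp + 1L
      lam_group[k] <- shared_grp[j]
    }
  }
  if (isTRUE(spec$invariance$thresholds_invariant)) {
    tau_group <- item_of
    tau_ncat <- setNames(items$n_categories, items$name)
  } else {
    tau_group <- seq_along(item_factor)
    tau_ncat <- setNames(rep(items$n_categories, times = G), design$item_cols)
  }

  psi_scale <- spec$priors$psi_scale
  if (is.null(psi_scale)) psi_scale <- diag(G)

  nphant <- length(spec$phantoms)
  Gamma <- xph <- NULL; ph_coef <- numeric(); ph_names <- character()
  if (nphant) {
    Gamma <- matrix(0, G, nphant)
    xph <- matrix(0, design$n, nphant)
    for (p in seq_len(nphant)) {
      ph <- spec$phantoms[[p]]
      Gamma[match(ph$focal, spec$types), p] <- ph$gamma
      xph[, p] <- design$alive[, ph$exposure]
      ph_coef[p] <- ph$gamma
      ph_names[p] <- paste0(ph$exposure, "_alive->", ph$focal)
    }
  }

  new_problem(Y = design$Y, obs = design$obs, item_factor = item_factor,
              ncat = design$ncat, lam_group = lam_group, lam_fixed = lam_fixed,
              tau_group = tau_group, tau_ncat = tau_ncat,
              X = design$X, factor_names = spec$types,
              beta_var = spec$priors$beta_var,
              lam_var = spec$priors$loading_var,
              tau_var = spec$priors$threshold_var,
              psi_scale = psi_scale, psi_df = spec$priors$psi_df,
              Gamma = Gamma, xph = xph, ph_coef = ph_coef,
              ph_names = ph_names, item_names = design$item_cols)
}

# Deterministic-given-RNG-state initialization: free loadings at 1,
# thresholds from pooled marginal category proportions via inverse-normal
# cuts, beta = alpha = 0, Psi = prior scale shape (identity), eta = 0, and
# y* drawn from its category's truncated standard normal at mean 0.
init_state <- function(pb, init = NULL) {
  st <- list(
    lamg = rep(1, pb$n_lam),
    tau = vector("list", max(pb$n_tau, 0L)),
    beta = lapply(pb$X, function(x) rep(0, ncol(x))),
    psi = diag(pb$G),
    eta = matrix(0, pb$n, pb$G),
    ystar = matrix(0, pb$n, pb$K),
    F = matrix(0, pb$n, pb$nph),
    ph_pi = if (pb$nph) colMeans(pb$xph) else numeric(),
    ph_s2 = if (pb$nph) pmax(apply(pb$xph, 2, var), 1e-3) else numeric()
  )
  if (pb$continuous) {
    st$ystar <- pb$Y
    st$tau <- list()
  } else {
    for (t in seq_len(pb$n_tau)) {
      nc <- pb$tau_ncat[t]
      cnt <- rep(1e-3, nc)  # tiny pseudo-count keeps empty categories ordered
      for (k in which(pb$tau_group == t)) {
        y <- pb$Y[pb$obs[, k], k]
        tb <- tabulate(y, nbins = nc)
        cnt <- cnt + tb
      }
      cum <- cumsum(cnt)[-nc] / sum(cnt)
      cum <- pmin(pmax(cum, 1e-3), 1 - 1e-3)
      tv <- qnorm(cum) * sqrt(pb$tau_var)
      tv <- tv + cumsum(c(0, pmax(0, 1e-4 - diff(tv))))  # enforce strict order
      st$tau[[t]] <- tv
    }
    for (k in seq_len(pb$K)) {
      o <- pb$obs[, k]
      if (!any(o)) next
      tv <- st$tau[[pb$tau_group[k]]]
      c_ <- pb$Y[o, k]
      lo <- c(-Inf, tv)[c_]
      hi <- c(tv, Inf)[c_]
      u <- runif(sum(o), pnorm(lo), pnorm(hi))
      st$ystar[o, k] <- qnorm(pmin(pmax(u, 1e-12), 1 - 1e-12))
    }
  }
  if (!is.null(init)) st[names(init)] <- init
  st
}

#' Run one MCMC chain
#'
#' Low-level single-chain driver. One sweep updates, in fixed order: the
#' augmented responses y*, the factor scores eta, free loadings, thresholds,
#' the stacked structural coefficients, phantom-confounder blocks (if any)
#' and the latent error covariance. Reproducible from `(config$seed,
#' chain_id)`.
#'
#' @param problem Internal `gi_problem` (see [fit_bsem()] for the high-level
#'   entry point).
#' @param config A [chain_config()].
#' @param chain_id Chain number (1-based); offsets the seed.
#' @param update Character vector of blocks to update (default all); any of
#'   `"ystar", "eta", "lambda", "tau", "beta", "phantom", "psi"`. Blocks left
#'   out stay at their initial values, which turns the sampler into a draw
#'   from a single full conditional -- used by the oracle tests.
#' @param init Optional named list overriding parts of the initial state.
#' @param retain Character vector among `"eta", "ystar", "phantom"` of latent
#'   quantities to retain per kept iteration.
#' @return List with `draws` (retained x parameters matrix, named columns)
#'   plus any retained latents, and the chain metadata.
#' @export
run_chain <- function(problem, config, chain_id = 1, update = UPDATE_BLOCKS,
                      init = NULL, retain = character()) {
  stopifnot(inherits(problem, "gi_problem"))
  upd <- UPDATE_BLOCKS %in% update
  if (problem$continuous) upd[UPDATE_BLOCKS %in% c("ystar", "tau")] <- FALSE
  if (problem$n_tau == 0) upd[UPDATE_BLOCKS == "tau"] <- FALSE
  if (problem$n_lam == 0) upd[UPDATE_BLOCKS == "lambda"] <- FALSE
  if (problem$nph == 0) upd[UPDATE_BLOCKS == "phantom"] <- FALSE
  set.seed(config$seed + (chain_id - 1L) * config$seed_stride)
  st <- init_state(problem, init)
  out <- .gibbs_run_cpp(problem[c("Y", "obs", "item_factor", "ncat",
                                  "lam_group", "lam_fixed", "n_lam",
                                  "tau_group", "n_tau", "tau_ncat", "X",
                                  "beta_var", "lam_var", "tau_var",
                                  "psi_scale", "psi_df", "continuous",
                                  "nph", "Gamma", "xph", "ph_coef",
                                  "ph_pi_var", "ph_s2_shape", "ph_s2_rate")],
                        st, config$iterations, config$burnin, config$thin,
                        upd, "eta" %in% retain, "ystar" %in% retain,
                        "phantom" %in% retain)
  colnames(out$draws) <- problem$par_names
  out$chain_id <- chain_id
  out$seed <- config$seed + (chain_id - 1L) * config$seed_stride
  out
}

#' Run multiple chains
#'
#' Runs `config$n_chains` chains with distinct seeds and keeps the per-chain
#' structure (needed for the potential scale reduction factor). Pooled
#' summaries are invariant to chain order.
#'
#' @inheritParams run_chain
#' @return Object of class `gi_draws`: list with `chains` (list of retained
#'   draw matrices), `par_names`, `config`, `problem_meta`.
#' @export
run_chains <- function(problem, config, update = UPDATE_BLOCKS) {
  chains <- lapply(seq_len(config$n_chains), function(cid)
    run_chain(problem, config, chain_id = cid, update = update)$draws)
  structure(list(chains = chains, par_names = problem$par_names,
                 config = config,
                 problem_meta = list(n = problem$n, G = problem$G,
                                     factor_names = problem$factor_names,
                                     item_names = problem$item_names,
                                     continuous = problem$continuous)),
            class = "gi_draws")
}

#' @export
print.gi_draws <- function(x, ...) {
  cat("Posterior draws:", length(x$chains), "chain(s) x",
      nrow(x$chains[[1]]), "retained draws x", length(x$par_names),
      "parameters\n")
  invisible(x)
}

#' Pool retained draws across chains
#' @param draws A `gi_draws` or `gi_fit`.
#' @return Matrix of pooled draws (rows = draws, named columns).
#' @export
pooled_draws <- function(draws) {
  if (inherits(draws, "gi_fit")) draws <- draws$draws
  do.call(rbind, draws$chains)
}

#' Fit the Bayesian structural equation model
#'
#' The package's main estimator: Gibbs sampling with ordinal-probit data
#' augmentation for the four-factor grandparental investment model (or any
#' spec built with [default_model_spec()] and possibly [add_phantom()]).
#'
#' @param design A `gi_design` from [encode_design()].
#' @param spec A `gi_model_spec`.
#' @param config A [chain_config()].
#' @return Object of class `gi_fit`: `draws` (a `gi_draws`), `spec`, `config`
#'   and design metadata. The reference type's structural intercept, fixed to
#'   zero for identification, is included as a constant column.
#' @export
fit_bsem <- function(design, spec = default_model_spec(),
                     config = chain_config()) {
  pb <- problem_from_spec(spec, design)
  draws <- run_chains(pb, config)
  ref <- spec$structural$reference_type
  alpha_ref <- paste0("alpha[", ref, "]")
  draws$chains <- lapply(draws$chains, function(m) {
    m2 <- cbind(m, rep(0, nrow(m)))
    colnames(m2) <- c(colnames(m), alpha_ref)
    m2
  })
  draws$par_names <- c(draws$par_names, alpha_ref)
  structure(list(draws = draws, spec = spec, config = config,
                 design_meta = list(n = design$n, age_mean = design$age_mean,
                                    alive_means = colMeans(design$alive),
                                    item_cols = design$item_cols)),
            class = "gi_fit")
}

#' @export
print.gi_fit <- function(x, ...) {
  cat("Bayesian SEM fit: n =", x$design_meta$n, "\n")
  print(x$draws)
  cat("Use summary() for posterior medians, HPD intervals and diagnostics.\n")
  invisible(x)
}

#' Export retained draws to a rectangular file
#'
#' One row per retained iteration with a leading `chain` column, suitable
#' for external posterior-analysis toolchains.
#'
#' @param draws A `gi_draws` or `gi_fit`.
#' @param path CSV file path.
#' @export
write_draws_csv <- function(draws, path) {
  if (inherits(draws, "gi_fit")) draws <- draws$draws
  tabs <- lapply(seq_along(draws$chains), function(cid)
    data.frame(chain = cid, draws$chains[[cid]], check.names = FALSE))
  write.csv(do.call(rbind, tabs), path, row.names = FALSE)
  invisible(path)
}
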