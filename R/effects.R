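# Probit marginal effects (conditional category probabilities of the marker
# item) and the phantom-variable sensitivity analysis for unmeasured
# within-lineage confounding.

#' Ordinal category probabilities under the probit link
#'
#' `P(category c) = Phi((tau_c - lp) / s) - Phi((tau_{c-1} - lp) / s)` with
#' `tau_0 = -Inf` and `tau_top = +Inf`. For population-averaged
#' probabilities, `s = sqrt(lambda^2 * zeta + 1)` integrates the focal
#' latent's residual variance into the indicator's normal scale; `s = 1`
#' gives probabilities conditional on the latent residual being zero.
#'
#' @param thresholds Strictly increasing threshold vector.
#' @param linear_predictor Location of the underlying continuous response
#'   (loading times the latent mean under the scenario).
#' @param latent_sd_total Total standard deviation `s` (> 0).
#' @return Probability vector of length `length(thresholds) + 1`, summing
#'   to 1.
#' @export
category_probabilities <- function(thresholds, linear_predictor,
                                   latent_sd_total = 1) {
  if (length(thresholds) >= 2 && is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing")
  if (latent_sd_total <= 0) stop("latent_sd_total must be positive")
  cuts <- pnorm((c(thresholds, Inf) - linear_predictor) / latent_sd_total)
  diff(c(0, cuts))
}

#' Marginal-effect scenarios for the marker item
#'
#' For each scenario (a focal grandparent type and one alive-flag predictor
#' of interest), computes the marker item's category probabilities with the
#' predictor at 0 (dead) and at 1 (alive), all other covariates held at
#' their sample means. Parameters are taken at their posterior medians by
#' default; with `propagate = TRUE` the probabilities are computed per
#' retained draw and summarised by the posterior median.
#'
#' @param fit A `gi_fit`.
#' @param scenarios Data frame with columns `focal` and `predictor` (e.g.
#'   `"MGM_alive"`); defaults to every focal type x its three alive
#'   predictors.
#' @param mode `"averaged"` (default; integrates the focal latent's residual
#'   variance) or `"conditional"` (latent residual fixed at zero).
#' @param propagate Propagate the full posterior per draw instead of
#'   plugging in posterior medians.
#' @return Data frame with one row per scenario x predictor value x
#'   category: `focal`, `predictor`, `value`, `category`, `probability`.
#' @export
marginal_effect_table <- function(fit, scenarios = NULL,
                                  mode = c("averaged", "conditional"),
                                  propagate = FALSE) {
  mode <- match.arg(mode)
  spec <- fit$spec
  types <- spec$types
  marker <- spec$items$name[spec$items$is_marker]
  if (is.null(scenarios)) {
    scenarios <- do.call(rbind, lapply(types, function(g)
      data.frame(focal = g, predictor = paste0(setdiff(types, g), "_alive"),
                 stringsAsFactors = FALSE)))
  }
  pooled <- pooled_draws(fit)
  med <- apply(pooled, 2, median)
  alive_means <- fit$design_meta$alive_means

  prob_for <- function(par, g, pred, value) {
    others <- setdiff(types, g)
    preds <- paste0(others, "_alive")
    if (!pred %in% preds)
      stop("scenario predictor ", pred, " is not in the design of factor ", g)
    xbar <- setNames(alive_means[others], preds)
    xbar[pred] <- value
    alpha_nm <- paste0("alpha[", g, "]")
    # predictors enter the fitted model centred at their sample means
    eta_mean <- par[alpha_nm] +
      sum(par[paste0("beta[", g, "<-", preds, "]")] *
            (xbar - alive_means[others]))
    # age enters centred, so the sample-mean contribution is zero
    lam <- par[paste0("lambda[", marker, "_", g, "]")]
    tau <- par[paste0("tau[", marker, ",",
                      seq_len(spec$items$n_categories[spec$items$is_marker] - 1L), "]")]
    zeta <- par[paste0("psi[", g, ",", g, "]")]
    s <- if (mode == "averaged") sqrt(lam^2 * zeta + 1) else 1
    category_probabilities(unname(tau), unname(lam * eta_mean), s)
  }

  rows <- list()
  for (i in seq_len(nrow(scenarios))) {
    g <- scenarios$focal[i]; pred <- scenarios$predictor[i]
    for (value in c(0, 1)) {
      p <- if (!propagate) prob_for(med, g, pred, value) else {
        ps <- apply(pooled, 1, function(par) prob_for(par, g, pred, value))
        apply(ps, 1, median)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        focal = g, predictor = pred, value = value,
        category = seq_along(p), probability = unname(p),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("gi_effects", class(out))
  out
}

#' Add a phantom confounder to a model specification
#'
#' Adds an indicator-less latent variable (mean 0, variance 1 fixed) with a
#' fixed path `multiplier * gamma` into the focal latent's structural
#' equation and a fixed path `multiplier * gamma` to the spouse-survival
#' predictor, which becomes endogenous with a linear auxiliary equation
#' (free intercept and residual variance). Mimics an unmeasured
#' within-lineage resource confounder of chosen strength; between-lineage
#' targets are rejected.
#'
#' @param spec A `gi_model_spec`.
#' @param focal Focal grandparent type receiving the outcome path.
#' @param exposure Grandparent type whose alive flag receives the exposure
#'   path; must be the focal type's within-lineage spouse.
#' @param gamma Path magnitude (>= 0; same fixed value on both paths,
#'   positive sign, mimicking resource-availability confounding).
#' @param multiplier Confounding multiplier (the standard scenarios are 1
#'   and 2).
#' @return The augmented `gi_model_spec`.
#' @export
add_phantom <- function(spec, focal, exposure = SPOUSE[[focal]], gamma,
                        multiplier = 1) {
  if (!focal %in% spec$types || !exposure %in% spec$types)
    stop("unknown grandparent type")
  lin <- setNames(grandparent_types()$lineage, GP_TYPES)
  if (lin[focal] != lin[exposure])
    stop("only within-lineage confounding is modelled; ", exposure, " and ",
         focal, " are in different lineages")
  if (gamma < 0) stop("gamma must be >= 0")
  spec$phantoms <- c(spec$phantoms,
                     list(list(focal = focal, exposure = exposure,
                               gamma = gamma * multiplier)))
  spec
}

#' Maximum absolute within-lineage structural effect
#'
#' The study's calibration for the confounding strength: the largest
#' absolute posterior median among the four spouse-survival coefficients.
#'
#' @param summary_tab A `gi_summary` (from [summary.gi_fit()]).
#' @return Scalar gamma.
#' @export
max_within_lineage_effect <- function(summary_tab) {
  pairs <- sprintf("beta[%s<-%s_alive]", GP_TYPES, SPOUSE[GP_TYPES])
  max(abs(summary_tab$median[match(pairs, summary_tab$parameter)]))
}

#' Phantom-variable sensitivity scan
#'
#' Fits the base model and re-fits with phantom within-lineage confounders
#' at each multiplier (default 1x and 2x), with independent phantoms on all
#' four spouse-survival -> focal-latent pairs. Unless supplied, gamma is the
#' maximum absolute within-lineage base effect, recomputed from the base
#' fit. Coefficients whose 95% HPD excludes zero in the base model but not
#' under confounding are flagged sign-unstable.
#'
#' @param design A `gi_design`.
#' @param spec Base `gi_model_spec`.
#' @param config A [chain_config()].
#' @param gamma Confounding path strength; default recomputed from the base
#'   fit.
#' @param multipliers Confounding multipliers (default `c(1, 2)`).
#' @param base_fit Optional precomputed base `gi_fit` (avoids refitting).
#' @return Object of class `gi_sensitivity`: list with `table` (one row per
#'   structural coefficient with median/HPD columns per multiplier block and
#'   the sign-stability flag), `gamma`, and `fits`.
#' @export
sensitivity_scan <- function(design, spec = default_model_spec(),
                             config = chain_config(), gamma = NULL,
                             multipliers = c(1, 2), base_fit = NULL) {
  if (is.null(base_fit)) base_fit <- fit_bsem(design, spec, config)
  base_sum <- summary(base_fit)
  if (is.null(gamma)) gamma <- max_within_lineage_effect(base_sum)

  fits <- list(base = base_fit)
  sums <- list(base = base_sum)
  for (m in multipliers) {
    spec_m <- spec
    for (g in GP_TYPES)
      spec_m <- add_phantom(spec_m, focal = g, exposure = SPOUSE[[g]],
                            gamma = gamma, multiplier = m)
    fit_m <- fit_bsem(design, spec_m, config)
    key <- paste0("x", m)
    fits[[key]] <- fit_m
    sums[[key]] <- summary(fit_m)
  }

  coef_rows <- grep("^beta\\[.*_alive\\]$", base_sum$parameter, value = TRUE)
  tab <- data.frame(parameter = coef_rows, stringsAsFactors = FALSE)
  for (key in names(sums)) {
    s <- sums[[key]]
    i <- match(coef_rows, s$parameter)
    tab[[paste0("median_", key)]] <- s$median[i]
    tab[[paste0("lower_", key)]] <- s$hpd_lower[i]
    tab[[paste0("upper_", key)]] <- s$hpd_upper[i]
  }
  excl0 <- function(lo, hi) lo > 0 | hi < 0
  base_sig <- excl0(tab$lower_base, tab$upper_base)
  still_sig <- rep(TRUE, nrow(tab))
  for (m in multipliers) {
    key <- paste0("x", m)
    still_sig <- still_sig & excl0(tab[[paste0("lower_", key)]],
                                   tab[[paste0("upper_", key)]])
  }
  tab$sign_stable <- !base_sig | still_sig
  structure(list(table = tab, gamma = gamma, multipliers = multipliers,
                 fits = fits), class = "gi_sensitivity")
}

#' @export
print.gi_sensitivity <- function(x, digits = 3, ...) {
  cat("Phantom-confounding sensitivity scan (gamma =",
      round(x$gamma, digits), "; multipliers",
      paste(x$multipliers, collapse = ", "), ")\n")
  y <- x$table
  num <- vapply(y, is.numeric, TRUE)
  y[num] <- lapply(y[num], round, digits)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}
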