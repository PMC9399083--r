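# Synthetic grandchild cohorts with known truth, emulating the structure of
# adolescent-report grandparental-investment surveys: per-child survival flags
# for the four grandparent types, four ordinal items per living grandparent,
# and all-missing items for deceased grandparents.

SPOUSE <- c(MGM = "MGF", MGF = "MGM", PGM = "PGF", PGF = "PGM")

#' Default generator truth
#'
#' True parameter values used to simulate cohorts. Survival proportions
#' (83.7/68.8/73.2/57.1% for MGM/MGF/PGM/PGF), grandchild age (mean 13.39,
#' sd 1.41, truncated to 11-16) and the structural coefficients and latent
#' correlations match the survey population the generator emulates; loadings
#' (0.9 for non-marker items), thresholds and latent error variances are
#' synthetic plumbing values chosen to give non-degenerate category
#' frequencies -- they are NOT estimates from any survey.
#'
#' @param beta_age True age coefficient shared by all four factors (synthetic
#'   default -0.05 per year).
#' @param nonresponse Item nonresponse probability for living grandparents.
#' @param gamma_x,gamma_y Within-lineage confounder path strengths (named
#'   vectors with entries `maternal`, `paternal`, or scalars); default 0 (no
#'   confounding). `gamma_x` acts on survival on the linear-probability
#'   scale; `gamma_y` shifts the focal latent.
#' @return Object of class `gi_truth`.
#' @export
default_truth <- function(beta_age = -0.05, nonresponse = 0.05,
                          gamma_x = 0, gamma_y = 0) {
  beta <- rbind(
    MGM = c(MGM_alive = NA, MGF_alive = 0.157, PGM_alive = 0.057, PGF_alive = 0.059),
    MGF = c(MGM_alive = -0.044, MGF_alive = NA, PGM_alive = -0.033, PGF_alive = 0.009),
    PGM = c(MGM_alive = -0.207, MGF_alive = -0.001, PGM_alive = NA, PGF_alive = 0.058),
    PGF = c(MGM_alive = -0.207, MGF_alive = -0.025, PGM_alive = 0.062, PGF_alive = NA)
  )
  corr <- diag(4)
  rownames(corr) <- colnames(corr) <- GP_TYPES
  corr["MGM", "MGF"] <- corr["MGF", "MGM"] <- 0.881
  corr["PGM", "PGF"] <- corr["PGF", "PGM"] <- 0.958
  corr["MGM", "PGM"] <- corr["PGM", "MGM"] <- 0.263
  corr["MGM", "PGF"] <- corr["PGF", "MGM"] <- 0.219
  corr["MGF", "PGM"] <- corr["PGM", "MGF"] <- 0.303
  corr["MGF", "PGF"] <- corr["PGF", "MGF"] <- 0.263
  lambda <- matrix(0.9, nrow = 4, ncol = 4,
                   dimnames = list(ITEM_NAMES, GP_TYPES))
  lambda["Q38", ] <- 1
  tau <- list(
    Q15 = c(-1.2, 0.0, 1.2),
    Q26 = c(-1.2, 0.0, 1.2),
    Q27 = c(-1.2, 0.0, 1.2),
    Q38 = c(-1.8, 0.1)
  )
  expand2 <- function(x) {
    if (length(x) == 1L) x <- c(maternal = unname(x), paternal = unname(x))
    x[c("maternal", "paternal")]
  }
  truth <- list(
    alive_probs = c(MGM = 0.837, MGF = 0.688, PGM = 0.732, PGF = 0.571),
    age_mean = 13.39, age_sd = 1.41, age_range = c(11, 16),
    beta = beta, beta_age = rep(beta_age, 4L), alpha = rep(0, 4L),
    lambda = lambda, tau = tau,
    psi_corr = corr, zeta = rep(1, 4L),
    nonresponse = nonresponse,
    gamma_x = expand2(gamma_x), gamma_y = expand2(gamma_y),
    synthetic_fields = c("lambda", "tau", "zeta", "beta_age", "alpha")
  )
  class(truth) <- "gi_truth"
  truth
}

#' Assembled latent error covariance of a generator truth
#' @param truth A `gi_truth`.
#' @return The 4x4 covariance `diag(sqrt(zeta)) %*% corr %*% diag(sqrt(zeta))`.
#' @export
truth_psi <- function(truth) {
  s <- sqrt(truth$zeta)
  psi <- truth$psi_corr * tcrossprod(s)
  dimnames(psi) <- dimnames(truth$psi_corr)
  psi
}

check_truth <- function(truth) {
  if (any(truth$alive_probs <= 0 | truth$alive_probs > 1))
    stop("alive probabilities must lie in (0, 1]")
  ev <- eigen(truth_psi(truth), symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("latent error covariance is not positive definite")
  for (nm in names(truth$tau))
    if (is.unsorted(truth$tau[[nm]], strictly = TRUE))
      stop("thresholds for ", nm, " are not strictly increasing")
  invisible(TRUE)
}

#' Draw grandparent survival indicators
#'
#' Independent Bernoulli survival per grandparent type, with rows in which
#' all four grandparents are dead redrawn (rejection) so that every
#' grandchild has at least one living grandparent, mirroring the survey's
#' inclusion rule. Optionally couples the two spouses of a lineage through a
#' shared Gaussian latent.
#'
#' @param n Number of grandchildren.
#' @param alive_probs Length-4 survival probabilities (MGM, MGF, PGM, PGF).
#' @param seed Optional integer seed.
#' @param lineage_rho Within-lineage survival correlation on the latent
#'   Gaussian scale (default 0 = off).
#' @return `n` x 4 integer 0/1 matrix.
#' @export
draw_survival <- function(n, alive_probs = default_truth()$alive_probs,
                          seed = NULL, lineage_rho = 0) {
  if (length(n) != 1L || is.na(n) || n < 1) stop("n must be a positive count")
  if (length(alive_probs) != 4L || any(alive_probs < 0 | alive_probs > 1))
    stop("alive_probs must be four probabilities in [0, 1]")
  if (all(alive_probs == 0))
    stop("impossible constraint: all survival probabilities are zero but every row needs a living grandparent")
  if (!is.null(seed)) set.seed(seed)
  draw_rows <- function(m) {
    if (lineage_rho == 0) {
      matrix(rbinom(m * 4L, 1L, rep(alive_probs, each = m)), nrow = m)
    } else {
      u <- cbind(rnorm(m), rnorm(m))[, c(1, 1, 2, 2)]
      z <- sqrt(lineage_rho) * u + sqrt(1 - lineage_rho) * matrix(rnorm(m * 4L), m)
      (z < rep(qnorm(alive_probs), each = m)) + 0L
    }
  }
  alive <- draw_rows(n)
  repeat {
    dead <- which(rowSums(alive) == 0L)
    if (!length(dead)) break
    alive[dead, ] <- draw_rows(length(dead))
  }
  colnames(alive) <- GP_TYPES
  alive
}

categorize <- function(ystar, tau) {
  findInterval(ystar, tau) + 1L
}

#' Generate a synthetic grandchild cohort
#'
#' Per grandchild: survival flags and age are drawn, latent investments
#' follow the structural model `eta = alpha + B x + beta_age * (age - mean)
#' (+ gamma_y * confounder) + zeta` with multivariate-normal errors, and each
#' LIVING grandparent's items arise by thresholding `lambda * eta + N(0, 1)`.
#' Items of deceased grandparents are entirely missing; living grandparents'
#' items are additionally subject to independent item nonresponse. The Q26
#' column is emitted in its RAW (reversed) orientation so that downstream
#' preprocessing must apply the reverse-scaling step.
#'
#' @param truth A `gi_truth` (see [default_truth()]).
#' @param n Cohort size.
#' @param seed Optional integer seed.
#' @return A list of class `gi_cohort` with elements `survey` (data frame:
#'   `child_id`, `age`, four `*_alive` flags, sixteen `Qxx_TYPE` ordinal
#'   columns with `NA` for missing), `truth`, `eta` (true latent scores,
#'   oracle access for recovery tests), and `present` (the n x 16 logical
#'   response-presence matrix before emission).
#' @export
generate_cohort <- function(truth = default_truth(), n, seed = NULL) {
  check_truth(truth)
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  lin <- setNames(grandparent_types()$lineage, GP_TYPES)

  # within-lineage confounders: one per ordered pair, indexed by focal type;
  # the confounder of focal g shifts g's latent and the survival of g's spouse
  gx <- setNames(truth$gamma_x[lin], names(lin))  # per-type lookup
  gy <- setNames(truth$gamma_y[lin], names(lin))
  has_conf <- any(gx != 0) || any(gy != 0)
  Fc <- if (has_conf) matrix(rnorm(n * 4L), n, 4L, dimnames = list(NULL, GP_TYPES))
        else matrix(0, n, 4L, dimnames = list(NULL, GP_TYPES))

  # survival: linear-probability confounding so cov(alive, confounder) = gamma_x
  p_base <- truth$alive_probs
  probs <- matrix(rep(p_base, each = n), n, 4L, dimnames = list(NULL, GP_TYPES))
  if (has_conf)
    for (g in GP_TYPES)
      probs[, g] <- pmin(pmax(probs[, g] + gx[g] * Fc[, SPOUSE[g]], 0.005), 0.995)
  alive <- matrix(rbinom(n * 4L, 1L, probs), n, 4L, dimnames = list(NULL, GP_TYPES))
  repeat {
    dead <- which(rowSums(alive) == 0L)
    if (!length(dead)) break
    pr <- probs[dead, , drop = FALSE]
    alive[dead, ] <- rbinom(length(pr), 1L, pr)
  }

  # age: truncated normal by CDF inversion
  plo <- pnorm(truth$age_range[1], truth$age_mean, truth$age_sd)
  phi <- pnorm(truth$age_range[2], truth$age_mean, truth$age_sd)
  age <- qnorm(runif(n, plo, phi), truth$age_mean, truth$age_sd)
  age_c <- age - truth$age_mean

  # latent investments
  psi <- truth_psi(truth)
  Lz <- chol(psi)
  zeta_err <- matrix(rnorm(n * 4L), n, 4L) %*% Lz
  eta <- matrix(0, n, 4L, dimnames = list(NULL, GP_TYPES))
  for (gi in seq_along(GP_TYPES)) {
    g <- GP_TYPES[gi]
    others <- setdiff(GP_TYPES, g)
    eta[, g] <- truth$alpha[gi] +
      alive[, others, drop = FALSE] %*% truth$beta[g, paste0(others, "_alive")] +
      truth$beta_age[gi] * age_c +
      gy[g] * Fc[, g] + zeta_err[, gi]
  }

  # ordinal responses for living grandparents
  resp <- matrix(NA_integer_, n, 16L)
  present <- matrix(FALSE, n, 16L)
  cols <- character(16L)
  k <- 0L
  for (g in GP_TYPES) for (item in ITEM_NAMES) {
    k <- k + 1L
    cols[k] <- paste0(item, "_", g)
    liv <- alive[, g] == 1L
    keep <- liv & (runif(n) >= truth$nonresponse)
    present[, k] <- keep
    m <- sum(keep)
    if (m) {
      ys <- truth$lambda[item, g] * eta[keep, g] + rnorm(m)
      cat_h <- categorize(ys, truth$tau[[item]])
      # Q26 is recorded reversed in the raw survey
      if (item == "Q26") cat_h <- length(truth$tau[[item]]) + 2L - cat_h
      resp[keep, k] <- cat_h
    }
  }
  colnames(resp) <- cols

  survey <- data.frame(child_id = seq_len(n), age = age,
                       setNames(as.data.frame(alive), paste0(GP_TYPES, "_alive")),
                       as.data.frame(resp), check.names = FALSE)
  structure(list(survey = survey, truth = truth, eta = eta, present = present),
            class = "gi_cohort")
}

#' @export
print.gi_cohort <- function(x, ...) {
  cat("Synthetic grandchild cohort: n =", nrow(x$survey), "\n")
  cat("  living grandparents (proportions):",
      paste(sprintf("%s %.3f", GP_TYPES,
                    colMeans(x$survey[paste0(GP_TYPES, "_alive")])),
            collapse = ", "), "\n")
  invisible(x)
}

#' Write / read the generator truth as a YAML sidecar
#'
#' Used by recovery workflows to score fitted posteriors against the values
#' that generated the data. Fields whose defaults are synthetic plumbing
#' (not study estimates) are listed under `synthetic_fields`.
#'
#' @param truth A `gi_truth`.
#' @param path File path.
#' @export
write_truth <- function(truth, path) {
  x <- unclass(truth)
  x$beta <- setNames(lapply(seq_len(nrow(x$beta)), function(i) as.list(x$beta[i, ])),
                     rownames(x$beta))
  x$psi_corr <- apply(x$psi_corr, 1, as.list)
  x$lambda <- apply(x$lambda, 2, as.list)  # column-major: items within type
  # yaml drops names on atomic vectors; keep them via lists
  for (nm in c("alive_probs", "gamma_x", "gamma_y"))
    x[[nm]] <- as.list(x[[nm]])
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_truth
#' @export
read_truth <- function(path) {
  x <- yaml::read_yaml(path)
  truth <- default_truth()
  beta <- truth$beta
  for (g in names(x$beta)) beta[g, ] <- unlist(lapply(x$beta[[g]], function(v)
    if (is.null(v) || (is.character(v) && v == "NA")) NA_real_ else as.numeric(v)))
  corr <- matrix(as.numeric(unlist(x$psi_corr)), 4L, byrow = TRUE,
                 dimnames = dimnames(truth$psi_corr))
  for (nm in setdiff(names(x), c("beta", "psi_corr")))
    truth[[nm]] <- if (nm %in% c("alive_probs", "gamma_x", "gamma_y"))
      unlist(x[[nm]]) else if (nm == "tau") lapply(x[[nm]], as.numeric)
      else if (nm == "lambda") matrix(unlist(x[[nm]]), 4L,
                                      dimnames = dimnames(truth$lambda))
      else x[[nm]]
  truth$beta <- beta
  truth$psi_corr <- corr
  truth$age_range <- as.numeric(truth$age_range)
  class(truth) <- "gi_truth"
  truth
}
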