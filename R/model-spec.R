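#' @useDynLib kinvest, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats median pnorm qnorm quantile rbinom rnorm runif sd setNames var
#' @importFrom utils read.csv write.csv
NULL

#' Grandparent types
#'
#' The four grandparent types, with lineage and sex derived from the code.
#'
#' @return A data frame with columns `code` (`MGM`, `MGF`, `PGM`, `PGF`),
#'   `lineage` (`maternal`/`paternal`) and `sex` (`female`/`male`).
#' @export
grandparent_types <- function() {
  data.frame(
    code = c("MGM", "MGF", "PGM", "PGF"),
    lineage = c("maternal", "maternal", "paternal", "paternal"),
    sex = c("female", "male", "female", "male"),
    stringsAsFactors = FALSE
  )
}

GP_TYPES <- c("MGM", "MGF", "PGM", "PGF")
ITEM_NAMES <- c("Q15", "Q26", "Q27", "Q38")

#' Survey item definitions
#'
#' The four investment items asked per living grandparent: contact frequency
#' (Q15), having been looked after (Q26, recorded on a reversed scale),
#' dependability (Q27) and financial assistance (Q38, the marker item that
#' sets the latent scale).
#'
#' @return Data frame with columns `name`, `n_categories`, `reverse_coded`,
#'   `is_marker`.
#' @export
item_specs <- function() {
  data.frame(
    name = ITEM_NAMES,
    n_categories = c(4L, 4L, 4L, 3L),
    reverse_coded = c(FALSE, TRUE, FALSE, FALSE),
    is_marker = c(FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Build the default model specification
#'
#' Constructs the four-factor measurement-and-structural model: one latent
#' investment factor per grandparent type, each measured by the four ordinal
#' items through a probit threshold link. The marker item's loading is fixed
#' to 1 in every group, one item's loading is free per grandparent type
#' (partial invariance; `Q15` by default), the remaining loadings and all
#' thresholds are shared across types. Each factor is regressed on the alive
#' flags of the other three grandparent types plus centred grandchild age,
#' with a full 4x4 latent error covariance. The structural intercept of the
#' reference type is fixed to 0 to identify latent locations.
#'
#' @param free_loading_item Item whose loading varies by grandparent type;
#'   must not be the marker item. Default `"Q15"`.
#' @param reference_type Grandparent type whose structural intercept is fixed
#'   to zero. Default `"MGM"`.
#' @param priors Optional prior overrides, see [default_priors()].
#' @return An object of class `gi_model_spec`.
#' @export
default_model_spec <- function(free_loading_item = "Q15",
                               reference_type = "MGM",
                               priors = default_priors()) {
  items <- item_specs()
  if (!free_loading_item %in% items$name)
    stop("unknown item: ", free_loading_item)
  if (items$is_marker[items$name == free_loading_item])
    stop("the free (non-invariant) loading must not be the marker item")
  if (!reference_type %in% GP_TYPES)
    stop("unknown grandparent type: ", reference_type)
  spec <- list(
    types = GP_TYPES,
    items = items,
    invariance = list(
      thresholds_invariant = TRUE,
      free_loading_item = free_loading_item
    ),
    structural = list(
      reference_type = reference_type,
      covariate = "age",
      predictors = setNames(
        lapply(GP_TYPES, function(g) c(paste0(setdiff(GP_TYPES, g), "_alive"), "age")),
        GP_TYPES
      )
    ),
    priors = priors,
    resid_var = 1,
    phantoms = list()
  )
  class(spec) <- "gi_model_spec"
  spec
}

#' Default prior hyperparameters
#'
#' Diffuse normal priors for structural coefficients and free intercepts
#' (mean 0, variance 100^2), loadings (variance 5) and thresholds
#' (variance 1); inverse-Wishart prior for the 4x4 latent error covariance
#' with identity scale and 5 degrees of freedom.
#'
#' @param beta_var,loading_var,threshold_var Prior variances.
#' @param psi_df Inverse-Wishart degrees of freedom.
#' @param psi_scale Inverse-Wishart scale matrix (default identity).
#' @return A list of hyperparameters.
#' @export
default_priors <- function(beta_var = 100^2, loading_var = 5,
                           threshold_var = 1, psi_df = 5, psi_scale = NULL) {
  list(beta_var = beta_var, loading_var = loading_var,
       threshold_var = threshold_var, psi_df = psi_df, psi_scale = psi_scale)
}

#' Count free parameters of a model specification
#'
#' @param spec A `gi_model_spec`.
#' @return Named integer vector with counts of free loadings, threshold
#'   entries, structural coefficients (including free intercepts) and unique
#'   latent covariance entries.
#' @export
count_parameters <- function(spec) {
  G <- length(spec$types)
  items <- spec$items
  free_item <- spec$invariance$free_loading_item
  n_free_loadings <- sum(!items$is_marker & items$name != free_item) + G
  n_thresholds <- sum(items$n_categories - 1L)
  n_beta <- sum(vapply(spec$structural$predictors, length, 1L))
  n_alpha <- G - 1L
  c(loadings = n_free_loadings, thresholds = n_thresholds,
    structural = n_beta + n_alpha, psi = (G * (G + 1L)) %/% 2L)
}

#' Validate a model specification
#'
#' Problems are reported, not raised: an empty report means the model is
#' estimable as specified.
#'
#' @param spec A `gi_model_spec` (or a structure claiming to be one).
#' @return Object of class `gi_validation`: a data frame of violations with
#'   columns `rule` and `message`; zero rows when the spec is valid.
#' @export
validate_spec <- function(spec) {
  bad <- list()
  note <- function(rule, message) bad[[length(bad) + 1L]] <<- data.frame(
    rule = rule, message = message, stringsAsFactors = FALSE)

  items <- spec$items
  if (is.null(items) || !all(c("name", "n_categories", "is_marker") %in% names(items))) {
    note("items", "item table missing or malformed")
  } else {
    if (sum(items$is_marker) != 1L)
      note("marker", "exactly one marker item is required per factor")
    if (any(items$n_categories < 2L))
      note("categories", "every ordinal item needs at least 2 categories")
    if (any(items$n_categories > 7L))
      note("categories", "items with more than 7 categories are not supported")
  }
  inv <- spec$invariance
  if (!is.null(items) && sum(items$is_marker) == 1L &&
      identical(inv$free_loading_item, items$name[items$is_marker]))
    note("free-loading", "the non-invariant loading must not be the marker item")
  for (g in spec$types) {
    preds <- spec$structural$predictors[[g]]
    if (paste0(g, "_alive") %in% preds)
      note("self-regression", paste0(g, " regressed on its own alive flag"))
    if (length(preds) != length(spec$types))
      note("design", paste0(g, ": expected ", length(spec$types),
                            " predictors (other alive flags + age)"))
  }
  pr <- spec$priors
  for (v in c("beta_var", "loading_var", "threshold_var"))
    if (!is.null(pr[[v]]) && pr[[v]] <= 0)
      note("prior", paste0(v, " must be positive"))
  G <- length(spec$types)
  if (!is.null(pr$psi_df) && pr$psi_df <= G - 1)
    note("improper IW", paste0("inverse-Wishart df must exceed dimension - 1 = ", G - 1))
  for (ph in spec$phantoms) {
    lin <- grandparent_types()
    if (lin$lineage[lin$code == ph$exposure] != lin$lineage[lin$code == ph$focal])
      note("phantom", "phantom confounding must be within-lineage")
    if (ph$gamma < 0) note("phantom", "phantom path magnitude must be >= 0")
  }
  out <- if (length(bad)) do.call(rbind, bad) else
    data.frame(rule = character(), message = character(), stringsAsFactors = FALSE)
  class(out) <- c("gi_validation", class(out))
  out
}

#' @export
print.gi_validation <- function(x, ...) {
  if (nrow(x) == 0) cat("Model specification valid: no violations.\n")
  else {
    cat("Model specification problems:\n")
    for (i in seq_len(nrow(x))) cat(sprintf("  [%s] %s\n", x$rule[i], x$message[i]))
  }
  invisible(x)
}

#' @export
print.gi_model_spec <- function(x, ...) {
  cnt <- count_parameters(x)
  cat("Latent investment model specification\n")
  cat("  factors:    ", paste(x$types, collapse = ", "), "\n")
  cat("  items:      ", paste(sprintf("%s(%d)", x$items$name, x$items$n_categories),
                              collapse = ", "),
      " (marker:", x$items$name[x$items$is_marker], ")\n")
  cat("  invariance:  thresholds shared; free loading:",
      x$invariance$free_loading_item, "\n")
  cat("  reference:  ", x$structural$reference_type, "(intercept fixed to 0)\n")
  cat("  free params: ", paste(sprintf("%s=%d", names(cnt), cnt), collapse = ", "), "\n")
  if (length(x$phantoms))
    cat("  phantoms:   ",
        paste(vapply(x$phantoms, function(p)
          sprintf("%s_alive->%s (gamma=%.3f)", p$exposure, p$focal, p$gamma), ""),
          collapse = ", "), "\n")
  invisible(x)
}

#' Write / read a model specification as YAML
#'
#' Round-trips all fields; every default is overridable by key in the file.
#'
#' @param spec A `gi_model_spec`.
#' @param path File path.
#' @return `read_model_spec` returns a `gi_model_spec`.
#' @export
write_model_spec <- function(spec, path) {
  x <- unclass(spec)
  x$items <- as.list(x$items)
  yaml::write_yaml(x, path, precision = 15L)
  invisible(path)
}

#' @rdname write_model_spec
#' @export
read_model_spec <- function(path) {
  x <- yaml::read_yaml(path)
  base <- default_model_spec()
  spec <- utils::modifyList(unclass(base), x[setdiff(names(x), "items")])
  if (!is.null(x$items)) spec$items <- as.data.frame(x$items, stringsAsFactors = FALSE)
  spec$priors$psi_scale <- if (!is.null(x$priors$psi_scale))
    matrix(unlist(x$priors$psi_scale), length(spec$types)) else NULL
  if (length(spec$phantoms)) spec$phantoms <- lapply(spec$phantoms, as.list)
  class(spec) <- "gi_model_spec"
  spec
}

#' MCMC chain configuration
#'
#' Defaults are the heavy-thinning production settings: three chains of
#' 300,000 iterations each, a burn-in of 150,000 and thinning by every 50th
#' iteration (interpreted per chain). Reduced settings are appropriate for
#' recovery studies.
#'
#' @param n_chains Number of chains.
#' @param iterations Iterations per chain.
#' @param burnin Burn-in iterations per chain.
#' @param thin Thinning interval.
#' @param seed Base seed; chain `c` uses `seed + (c - 1) * seed_stride`.
#' @param seed_stride Per-chain seed offset.
#' @return A `gi_chain_config` list.
#' @export
chain_config <- function(n_chains = 3, iterations = 300000, burnin = 150000,
                         thin = 50, seed = 1, seed_stride = 1000) {
  if (burnin >= iterations) stop("burn-in must be smaller than iterations")
  if (thin < 1) stop("thinning interval must be >= 1")
  if ((iterations - burnin) %% thin != 0)
    warning("(iterations - burnin) is not divisible by thin; ",
            "the last partial interval is dropped")
  structure(list(n_chains = as.integer(n_chains),
                 iterations = as.integer(iterations),
                 burnin = as.integer(burnin), thin = as.integer(thin),
                 seed = as.integer(seed), seed_stride = as.integer(seed_stride)),
            class = "gi_chain_config")
}

#' Retained draws per chain implied by a chain configuration
#' @param config A `gi_chain_config`.
#' @return Integer count of retained post-burn-in draws per chain.
#' @export
n_retained <- function(config) {
  as.integer((config$iterations - config$burnin) %/% config$thin)
}
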