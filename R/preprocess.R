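# Recoding and exclusion rules, and assembly of sampler-ready design data.

#' Reverse-scale an ordinal category
#'
#' Maps category `c` on a `1..n_categories` scale to `n_categories + 1 - c`;
#' missing values stay missing. Used to harmonise the reversed Q26 item with
#' the orientation of the other investment items.
#'
#' @param category Integer category vector (may contain `NA`).
#' @param n_categories Number of categories of the item's scale.
#' @return Reversed integer categories.
#' @export
reverse_scale <- function(category, n_categories) {
  ok <- is.na(category) | (category >= 1 & category <= n_categories)
  if (!all(ok))
    stop("category out of range 1..", n_categories, " at position ",
         which(!ok)[1])
  n_categories + 1L - as.integer(category)
}

#' Apply the survey's exclusion rules
#'
#' Drops, in this order: (1) grandchildren with no living grandparent,
#' (2) grandchildren co-residing with a grandparent (column `coresident`, if
#' present), (3) grandchildren with no response in any of the sixteen items
#' or with missing age. The log records counts per rule in that order, so
#' the (order-dependent) counts are auditable.
#'
#' @param survey Survey data frame (see [generate_cohort()] for the layout).
#' @return List with elements `table` (retained rows) and `log` (named
#'   integer vector `no_living`, `coresident`, `empty_or_no_age`).
#' @export
apply_exclusions <- function(survey) {
  alive_cols <- paste0(GP_TYPES, "_alive")
  item_cols <- intersect(as.vector(outer(ITEM_NAMES, GP_TYPES, paste, sep = "_")),
                         names(survey))
  log <- c(no_living = 0L, coresident = 0L, empty_or_no_age = 0L)
  if (nrow(survey)) {
    keep <- rowSums(survey[alive_cols], na.rm = TRUE) > 0
    log["no_living"] <- sum(!keep)
    survey <- survey[keep, , drop = FALSE]
  }
  if (nrow(survey) && "coresident" %in% names(survey)) {
    keep <- !(survey$coresident %in% 1)
    log["coresident"] <- sum(!keep)
    survey <- survey[keep, , drop = FALSE]
  }
  if (nrow(survey)) {
    any_resp <- rowSums(!is.na(survey[item_cols])) > 0
    keep <- any_resp & !is.na(survey$age)
    log["empty_or_no_age"] <- sum(!keep)
    survey <- survey[keep, , drop = FALSE]
  }
  rownames(survey) <- NULL
  list(table = survey, log = log)
}

#' Encode sampler-ready design data
#'
#' Maps survey columns to the model's (factor, item) layout, harmonises
#' reverse-coded items, builds the per-factor structural design matrices
#' (alive flags of the other three grandparent types plus centred grandchild
#' age, and a free intercept for non-reference types), and the response
#' presence mask. Responses recorded for a deceased grandparent are treated
#' as a data error.
#'
#' @param survey Survey data frame that has passed [apply_exclusions()].
#' @param spec A `gi_model_spec`.
#' @param strict_deceased Error (default) if a response is present for a
#'   deceased grandparent; `FALSE` downgrades to a warning and masks the cell.
#' @return Object of class `gi_design`: list with `Y` (n x 16 integer
#'   categories, `NA` missing), `obs` (logical mask), `X` (per-factor design
#'   matrices), `alive`, `n`, `item_cols`, `age_mean`, `ncat`.
#' @export
encode_design <- function(survey, spec = default_model_spec(),
                          strict_deceased = TRUE) {
  v <- validate_spec(spec)
  if (nrow(v) > 0)
    stop("invalid model spec: ", paste(v$message, collapse = "; "))
  alive_cols <- paste0(GP_TYPES, "_alive")
  need <- c("age", alive_cols)
  miss <- setdiff(need, names(survey))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))
  n <- nrow(survey)
  items <- spec$items
  item_cols <- as.vector(t(outer(GP_TYPES, items$name, function(g, q) paste0(q, "_", g))))
  miss <- setdiff(item_cols, names(survey))
  if (length(miss)) stop("missing required column(s): ", paste(miss, collapse = ", "))

  Y <- matrix(NA_integer_, n, length(item_cols), dimnames = list(NULL, item_cols))
  for (g in GP_TYPES) for (j in seq_len(nrow(items))) {
    col <- paste0(items$name[j], "_", g)
    val <- as.integer(survey[[col]])
    rng_ok <- is.na(val) | (val >= 1L & val <= items$n_categories[j])
    if (!all(rng_ok))
      stop("response out of range in column ", col, " at row ", which(!rng_ok)[1])
    if (items$reverse_coded[j]) val <- reverse_scale(val, items$n_categories[j])
    Y[, col] <- val
  }

  alive <- as.matrix(survey[alive_cols]) == 1
  colnames(alive) <- GP_TYPES
  # responses only where the grandparent is alive
  for (g in GP_TYPES) {
    cols <- paste0(items$name, "_", g)
    bad <- !alive[, g] & rowSums(!is.na(Y[, cols, drop = FALSE])) > 0
    if (any(bad)) {
      msg <- paste0("response recorded for deceased ", g, " at row ", which(bad)[1])
      if (strict_deceased) stop(msg)
      warning(msg, "; masking")
      Y[bad, cols] <- NA_integer_
    }
  }

  age_mean <- mean(survey$age)
  age_c <- survey$age - age_mean
  ref <- spec$structural$reference_type
  # all structural predictors enter centred: slopes are unchanged, the
  # reference factor's latent location is pinned at the covariate means,
  # and the coefficients decouple from the slowly mixing threshold location
  alive_means <- colMeans(alive)
  alive_c <- sweep(alive + 0, 2, alive_means)
  X <- lapply(GP_TYPES, function(g) {
    others <- setdiff(GP_TYPES, g)
    Xg <- cbind(alive_c[, others, drop = FALSE], age = age_c)
    colnames(Xg) <- c(paste0(others, "_alive"), "age")
    if (g != ref) Xg <- cbind(`(Intercept)` = rep(1, nrow(Xg)), Xg)
    Xg
  })
  names(X) <- GP_TYPES

  structure(list(Y = Y, obs = !is.na(Y), X = X, alive = alive + 0L, n = n,
                 item_cols = item_cols, age_mean = age_mean,
                 ncat = rep(items$n_categories, times = length(GP_TYPES))),
            class = "gi_design")
}

#' @export
print.gi_design <- function(x, ...) {
  cat("Sampler-ready design data: n =", x$n, ", items =", length(x$item_cols), "\n")
  cat("  observed response cells:", sum(x$obs), "of", length(x$obs), "\n")
  invisible(x)
}
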