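test_that("category probabilities integrate the probit cells", {
  expect_equal(category_probabilities(0, 0, 1), c(0.5, 0.5))
  p <- category_probabilities(c(-1, 1), 0, 1)
  expect_equal(p, c(pnorm(-1), pnorm(1) - pnorm(-1), pnorm(-1)),
               tolerance = 1e-12)
  # limit: all mass in the top category
  p10 <- category_probabilities(c(-1, 1), 10, 1)
  expect_gt(p10[3], 0.999)
  expect_error(category_probabilities(c(1, -1), 0), "increasing")
  expect_error(category_probabilities(0, 0, 0), "positive")
})

test_that("category probabilities are translation-equivariant and normalised", {
  set.seed(31)
  for (i in 1:10) {
    tau <- sort(rnorm(3))
    lp <- rnorm(1)
    s <- runif(1, 0.5, 2)
    shift <- rnorm(1)
    p0 <- category_probabilities(tau, lp, s)
    p1 <- category_probabilities(tau + shift, lp + shift, s)
    expect_equal(p0, p1, tolerance = 1e-12)
    expect_lt(abs(sum(p0) - 1), 1e-12)
  }
})

test_that("marginal effects respond to the coefficient of interest", {
  sm <- cached_small_fit()
  tab <- marginal_effect_table(sm$fit)
  # probabilities per scenario sum to 1
  agg <- aggregate(probability ~ focal + predictor + value, tab, sum)
  expect_true(all(abs(agg$probability - 1) < 1e-12))

  # positive coefficient: bottom-category probability strictly lower when
  # the predictor is alive (probit monotonicity); test on the scenario with
  # the largest positive median
  s <- summary(sm$fit)
  alive_rows <- s[grepl("^beta\\[.*_alive\\]$", s$parameter), ]
  top <- alive_rows[which.max(alive_rows$median), "parameter"]
  gg <- sub("beta\\[([A-Z]+)<-.*", "\\1", top)
  pp <- sub(".*<-(.*)\\]", "\\1", top)
  sub_tab <- tab[tab$focal == gg & tab$predictor == pp & tab$category == 1, ]
  expect_lt(sub_tab$probability[sub_tab$value == 1],
            sub_tab$probability[sub_tab$value == 0])

  # a null coefficient leaves the probability vector unchanged
  fit0 <- sm$fit
  fit0$draws$chains <- lapply(fit0$draws$chains, function(m) {
    m[, top] <- 0
    m
  })
  tab0 <- marginal_effect_table(fit0, scenarios = data.frame(
    focal = gg, predictor = pp, stringsAsFactors = FALSE))
  expect_equal(tab0$probability[tab0$value == 0],
               tab0$probability[tab0$value == 1], tolerance = 1e-12)

  # scenario referencing a predictor outside the focal design errors
  expect_error(marginal_effect_table(sm$fit, scenarios = data.frame(
    focal = "MGM", predictor = "MGM_alive")), "not in the design")
})

test_that("averaged and conditional modes differ by the latent variance", {
  sm <- cached_small_fit()
  sc <- data.frame(focal = "MGM", predictor = "MGF_alive",
                   stringsAsFactors = FALSE)
  pa <- marginal_effect_table(sm$fit, sc, mode = "averaged")
  pc <- marginal_effect_table(sm$fit, sc, mode = "conditional")
  # the averaged distribution is flatter (more dispersed over categories)
  expect_false(isTRUE(all.equal(pa$probability, pc$probability)))
})

test_that("phantom augmentation adds one latent and two fixed paths", {
  spec <- default_model_spec()
  aug <- add_phantom(spec, focal = "MGM", gamma = 0.157, multiplier = 2)
  expect_identical(length(aug$phantoms), 1L)
  expect_identical(aug$phantoms[[1]]$exposure, "MGF")
  expect_equal(aug$phantoms[[1]]$gamma, 0.314)
  # everything else unchanged
  expect_identical(aug$items, spec$items)
  expect_identical(aug$structural, spec$structural)
  # between-lineage confounding is rejected
  expect_error(add_phantom(spec, focal = "MGM", exposure = "PGF",
                           gamma = 0.1), "within-lineage")
  expect_error(add_phantom(spec, focal = "MGM", gamma = -0.1), ">= 0")
})

test_that("a zero-strength phantom is a no-op up to Monte-Carlo error", {
  sm <- cached_small_fit()
  spec0 <- default_model_spec()
  for (g in c("MGM", "MGF", "PGM", "PGF"))
    spec0 <- add_phantom(spec0, focal = g, gamma = 0)
  cfg <- chain_config(n_chains = 2, iterations = 1500, burnin = 700, thin = 2,
                      seed = 99)
  fit0 <- fit_bsem(sm$design, spec0, cfg)
  s_base <- summary(sm$fit)
  s0 <- summary(fit0)
  pars <- grep("^beta\\[.*_alive\\]$", s_base$parameter, value = TRUE)
  diff <- abs(s_base$median[match(pars, s_base$parameter)] -
              s0$median[match(pars, s0$parameter)])
  expect_lt(mean(diff), 0.05)
})

test_that("confounding attenuates the within-lineage coefficient monotonically", {
  coh <- generate_cohort(default_truth(), 700, seed = 555)
  design <- encode_design(apply_exclusions(coh$survey)$table)
  cfg <- chain_config(n_chains = 2, iterations = 1600, burnin = 800, thin = 2,
                      seed = 77)
  base <- fit_bsem(design, default_model_spec(), cfg)
  scan <- sensitivity_scan(design, default_model_spec(), cfg, gamma = 0.157,
                           multipliers = c(1, 2), base_fit = base)
  tab <- scan$table
  row <- tab[tab$parameter == "beta[MGM<-MGF_alive]", ]
  # on data generated without confounding the fixed positive phantom paths
  # absorb covariance: median moves downward as the multiplier grows
  expect_gt(row$median_base, row$median_x1 - 0.02)
  expect_gt(row$median_x1, row$median_x2 - 0.02)
  expect_gt(row$median_base, row$median_x2)
  # base column equals the unmodified model's summary
  s_base <- summary(base)
  expect_equal(row$median_base,
               s_base$median[s_base$parameter == "beta[MGM<-MGF_alive]"])
  expect_true(all(c("sign_stable", "median_x1", "median_x2") %in% names(tab)))
})
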