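test_that("default truth reproduces the study population parameters", {
  tr <- default_truth()
  expect_equal(unname(tr$alive_probs), c(0.837, 0.688, 0.732, 0.571))
  expect_equal(c(tr$age_mean, tr$age_sd), c(13.39, 1.41))
  expect_equal(unname(tr$beta["MGM", "MGF_alive"]), 0.157)
  expect_equal(unname(tr$beta["PGM", "MGM_alive"]), -0.207)
  expect_equal(unname(tr$beta["PGF", "MGM_alive"]), -0.207)
  expect_equal(unname(tr$psi_corr["PGM", "PGF"]), 0.958)
  expect_equal(unname(tr$psi_corr["MGM", "MGF"]), 0.881)
  # assembled latent error covariance is positive definite
  ev <- eigen(truth_psi(tr), symmetric = TRUE, only.values = TRUE)$values
  expect_gt(min(ev), 0)
  # plumbing values are flagged as synthetic
  expect_true(all(c("lambda", "tau", "zeta") %in% tr$synthetic_fields))
})

test_that("survival draws match their probabilities within binomial error", {
  n <- 100000
  p <- default_truth()$alive_probs
  alive <- draw_survival(n, p, seed = 101)
  # the >=1-alive rejection shifts the marginals slightly upward; the shift
  # is bounded by the all-dead probability (~1.2%)
  shift <- prod(1 - p)
  tol <- 3 * sqrt(p * (1 - p) / n) + shift
  expect_true(all(abs(colMeans(alive) - p) < tol))
  expect_true(all(rowSums(alive) >= 1))

  expect_true(all(draw_survival(50, rep(1, 4)) == 1))
  one <- draw_survival(50, c(1, 0, 0, 0))
  expect_true(all(one[, 1] == 1) && all(one[, -1] == 0))
  expect_error(draw_survival(10, rep(0, 4)), "impossible")
  expect_error(draw_survival(-1, p), "positive count")
})

test_that("cohorts are reproducible and missingness follows mortality", {
  tr <- default_truth()
  a <- generate_cohort(tr, 5, seed = 33)
  b <- generate_cohort(tr, 5, seed = 33)
  expect_identical(a$survey, b$survey)

  # deceased grandparent => all four items missing
  coh <- generate_cohort(tr, 2000, seed = 34)
  for (g in c("MGM", "MGF", "PGM", "PGF")) {
    dead <- coh$survey[[paste0(g, "_alive")]] == 0
    cols <- paste0(c("Q15", "Q26", "Q27", "Q38"), "_", g)
    expect_true(all(is.na(coh$survey[dead, cols])))
    # living grandparents answer with probability 1 - nonresponse
    liv_resp <- !is.na(as.matrix(coh$survey[!dead, cols]))
    expect_lt(abs(mean(liv_resp) - (1 - tr$nonresponse)), 0.01)
  }

  # a type with survival probability ~0 yields entirely missing columns
  tr0 <- tr
  tr0$alive_probs["MGM"] <- 1e-9
  coh0 <- generate_cohort(tr0, 200, seed = 35)
  expect_true(all(is.na(coh0$survey[paste0(c("Q15", "Q26", "Q27", "Q38"), "_MGM")])))
})

test_that("generated latent scores reproduce the true error covariance", {
  tr <- default_truth()
  coh <- generate_cohort(tr, 100000, seed = 36)
  # residualise eta on its structural mean before comparing with psi
  X <- cbind(as.matrix(coh$survey[paste0(c("MGM", "MGF", "PGM", "PGF"), "_alive")]),
             coh$survey$age - tr$age_mean)
  R <- apply(coh$eta, 2, function(e) residuals(lm(e ~ X)))
  emp <- cor(R)
  expect_lt(max(abs(emp - tr$psi_corr)), 0.02)
})

test_that("binary-item category frequencies match the probit integral", {
  # single effective threshold at 0, no structural effects, loading 1:
  # P(cat 2) = P(eta + e > 0) with var(eta + e) = zeta + 1 = 2 => 0.5;
  # with threshold tau, P(cat 2) = 1 - pnorm(tau / sqrt(2))
  tr <- default_truth()
  tr$beta[!is.na(tr$beta)] <- 0
  tr$beta_age <- rep(0, 4)
  tr$psi_corr <- diag(4); dimnames(tr$psi_corr) <- dimnames(default_truth()$psi_corr)
  tr$lambda[] <- 1
  tr$tau <- list(Q15 = 0.7, Q26 = 0, Q27 = -0.4, Q38 = 0.3)
  tr$nonresponse <- 0
  tr$alive_probs[] <- 1
  coh <- generate_cohort(tr, 60000, seed = 37)
  for (q in c("Q15", "Q27", "Q38")) {
    p2_expected <- 1 - pnorm(tr$tau[[q]] / sqrt(2))
    p2 <- mean(coh$survey[[paste0(q, "_MGM")]] == 2)
    expect_lt(abs(p2 - p2_expected), 0.01)
  }
  # Q26 is emitted reversed: raw category 1 corresponds to harmonised top
  p_raw1 <- mean(coh$survey$Q26_MGM == 1)
  expect_lt(abs(p_raw1 - 0.5), 0.01)
})

test_that("shifting all thresholds up moves mass into low categories", {
  tr <- default_truth()
  coh_lo <- generate_cohort(tr, 20000, seed = 38)
  tr_hi <- tr
  tr_hi$tau <- lapply(tr$tau, function(v) v + 0.8)
  coh_hi <- generate_cohort(tr_hi, 20000, seed = 38)
  for (q in c("Q15", "Q27", "Q38")) {
    col <- paste0(q, "_MGM")
    expect_gt(mean(coh_hi$survey[[col]] == 1, na.rm = TRUE),
              mean(coh_lo$survey[[col]] == 1, na.rm = TRUE))
  }
})

test_that("truth round-trips through its YAML sidecar", {
  tr <- default_truth(gamma_x = c(maternal = 0.1, paternal = 0.2),
                      gamma_y = 0.15)
  path <- tempfile(fileext = ".yml")
  write_truth(tr, path)
  back <- read_truth(path)
  expect_equal(back$beta, tr$beta)
  expect_equal(back$psi_corr, tr$psi_corr)
  expect_equal(back$lambda, tr$lambda)
  expect_equal(back$tau, tr$tau)
  expect_equal(back$alive_probs, tr$alive_probs)
  expect_equal(back$gamma_x, tr$gamma_x)
  expect_equal(back$gamma_y, tr$gamma_y)
})
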