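# Each full conditional is exercised in isolation through the sampler's
# update-mask interface: with every other block held at its initial value,
# successive sweeps yield independent draws from the targeted conditional,
# which are compared against closed-form or rejection-sampling oracles.

test_that("augmented responses are truncated normals of the right moments", {
  n <- 4000
  pb <- toy_binary_problem(x = rep(0, n), y = rep(1L, n))
  out <- run_chain(pb, toy_chain_config(1), update = "ystar",
                   init = list(tau = list(0)), retain = "ystar")
  ys <- out$ystar[1, ]
  # category 1 of a 2-category item, tau = 0, mean 0: draws <= 0 with
  # mean -sqrt(2/pi)
  expect_true(all(ys <= 0))
  expect_lt(abs(mean(ys) + sqrt(2 / pi)), 3 * sqrt((1 - 2 / pi) / n))

  # far above the threshold, truncation is inactive: top category at
  # lambda * eta = 10 has draws around 10
  pb2 <- toy_binary_problem(x = rep(0, n), y = rep(2L, n))
  out2 <- run_chain(pb2, toy_chain_config(1), update = "ystar",
                    init = list(tau = list(0), eta = matrix(10, n, 1)),
                    retain = "ystar")
  expect_lt(abs(mean(out2$ystar[1, ]) - 10), 0.1)

  # masked cells are never touched
  pb3 <- toy_binary_problem(x = rep(0, 10), y = rep(1L, 10))
  pb3$obs[3, 1] <- FALSE
  out3 <- run_chain(pb3, toy_chain_config(1), update = "ystar",
                    init = list(tau = list(0), ystar = matrix(7, 10, 1)),
                    retain = "ystar")
  expect_identical(out3$ystar[1, 3], 7)
  expect_true(all(out3$ystar[1, -3] <= 0))
})

test_that("factor scores follow the precision-weighted normal conditional", {
  # 1 factor, 1 indicator, lambda = 1, residual var 1, structural mean 0,
  # zeta = 1, y* = 2: conditional is N(1, 0.5)
  m <- 6000
  pb <- toy_continuous_problem(X = matrix(0, 1, 1), y = 2, psi = 1)
  cfg <- toy_chain_config(m)
  out <- run_chain(pb, cfg, update = "eta", retain = "eta")
  draws <- out$eta[, 1]
  expect_lt(abs(mean(draws) - 1), 4 * sqrt(0.5 / m))
  expect_lt(abs(var(draws) - 0.5), 0.05)

  # no-data limit: with all factors unobserved the conditional reverts to
  # the structural distribution N(0, Psi)
  Psi <- matrix(c(1, 0.9, 0.9, 1), 2)
  pb2 <- kinvest:::new_problem(
    Y = matrix(0, 1, 2), obs = matrix(FALSE, 1, 2),
    item_factor = 1:2, ncat = c(2L, 2L), lam_group = c(0L, 0L),
    lam_fixed = c(1, 1), tau_group = 0L * 1:2, tau_ncat = integer(),
    X = list(f1 = matrix(0, 1, 1), f2 = matrix(0, 1, 1)),
    psi_scale = Psi, psi_df = 4, continuous = TRUE)
  out2 <- run_chain(pb2, toy_chain_config(m), update = "eta",
                    init = list(psi = Psi), retain = "eta")
  emp <- cov(out2$eta)
  expect_lt(max(abs(emp - Psi)), 0.08)

  # bivariate conditional: factor 1 observed precisely, correlation 0.9
  # pulls factor 2 toward 0.9 * observed value
  pb3 <- kinvest:::new_problem(
    Y = cbind(rep(2, 1), 0), obs = cbind(TRUE, FALSE),
    item_factor = 1:2, ncat = c(2L, 2L), lam_group = c(0L, 0L),
    lam_fixed = c(30, 1),  # near-precise measurement of factor 1
    tau_group = 0L * 1:2, tau_ncat = integer(),
    X = list(f1 = matrix(0, 1, 1), f2 = matrix(0, 1, 1)),
    psi_scale = Psi, psi_df = 4, continuous = TRUE)
  pb3$Y[1, 1] <- 30 * 1.5  # y* = lambda * eta with eta ~= 1.5
  out3 <- run_chain(pb3, toy_chain_config(m), update = "eta",
                    init = list(psi = Psi), retain = "eta")
  expect_lt(abs(mean(out3$eta[, 1]) - 1.5), 0.01)
  expect_lt(abs(mean(out3$eta[, 2]) - 0.9 * 1.5), 0.05)
})

test_that("free loadings have the conjugate regression conditional", {
  set.seed(61)
  n <- 5000
  eta <- rnorm(n, 0, 1.3)
  lam_true <- 0.8
  y <- lam_true * eta + rnorm(n)
  pb <- kinvest:::new_problem(
    Y = matrix(y, n, 1), obs = matrix(TRUE, n, 1),
    item_factor = 1L, ncat = 2L, lam_group = 1L, lam_fixed = 0,
    tau_group = 0L, tau_ncat = integer(), X = list(f1 = matrix(0, n, 1)),
    continuous = TRUE)
  out <- run_chain(pb, toy_chain_config(400), update = "lambda",
                   init = list(eta = matrix(eta, n, 1)))
  ls_slope <- sum(eta * y) / sum(eta * eta)
  draws <- out$draws[, "lambda[y1]"]
  expect_lt(abs(mean(draws) - ls_slope), 0.02)

  # no-data limit: draws follow the N(0, 5) prior
  pb0 <- pb
  pb0$obs[] <- FALSE
  out0 <- run_chain(pb0, toy_chain_config(2000), update = "lambda")
  expect_lt(abs(sd(out0$draws[, "lambda[y1]"]) - sqrt(5)), 0.15)
  expect_lt(abs(mean(out0$draws[, "lambda[y1]"])), 0.15)
})

test_that("marker loadings stay exactly 1 through long runs", {
  sm <- cached_small_fit()
  pooled <- pooled_draws(sm$fit)
  marker_cols <- paste0("lambda[Q38_", c("MGM", "MGF", "PGM", "PGF"), "]")
  expect_true(all(pooled[, marker_cols] == 1))
})

test_that("threshold draws match a truncated-prior rejection oracle", {
  # construct y* so the interior threshold's bounds are exactly (-0.2, 0.3)
  n <- 40
  y <- rep(c(1L, 2L, 3L), length.out = n)
  ystar <- numeric(n)
  ystar[y == 1L] <- seq(-1, -0.2, length.out = sum(y == 1L))
  ystar[y == 2L] <- seq(0.3, 0.5, length.out = sum(y == 2L))
  ystar[y == 3L] <- seq(0.9, 1.4, length.out = sum(y == 3L))
  pb <- kinvest:::new_problem(
    Y = matrix(y, n, 1), obs = matrix(TRUE, n, 1),
    item_factor = 1L, ncat = 3L, lam_group = 0L, lam_fixed = 1,
    tau_group = 1L, tau_ncat = c(y1 = 3L), X = list(f1 = matrix(0, n, 1)))
  m <- 4000
  out <- run_chain(pb, toy_chain_config(m), update = "tau",
                   init = list(ystar = matrix(ystar, n, 1),
                               tau = list(c(-0.21, 0.85))))
  t1 <- out$draws[, "tau[y1,1]"]
  t2 <- out$draws[, "tau[y1,2]"]
  expect_true(all(t1 > -0.2 & t1 < 0.3))
  expect_true(all(t2 > 0.5 & t2 < 0.9))
  expect_true(all(t2 > t1))
  # rejection oracle for a standard normal restricted to (-0.2, 0.3)
  set.seed(71)
  oracle <- numeric(0)
  while (length(oracle) < m) {
    z <- rnorm(2 * m)
    oracle <- c(oracle, z[z > -0.2 & z < 0.3])
  }
  ks <- suppressWarnings(stats::ks.test(t1, oracle[seq_len(m)]))
  expect_gt(ks$p.value, 0.001)
})

test_that("empty categories fall back to neighbouring thresholds as bounds", {
  # category 2 of a 3-category item unobserved: tau_1 and tau_2 bound each
  # other and remain ordered
  n <- 30
  y <- rep(c(1L, 3L), length.out = n)
  ystar <- ifelse(y == 1L, -0.5, 0.6)
  pb <- kinvest:::new_problem(
    Y = matrix(y, n, 1), obs = matrix(TRUE, n, 1),
    item_factor = 1L, ncat = 3L, lam_group = 0L, lam_fixed = 1,
    tau_group = 1L, tau_ncat = c(y1 = 3L), X = list(f1 = matrix(0, n, 1)))
  out <- run_chain(pb, toy_chain_config(2000), update = "tau",
                   init = list(ystar = matrix(ystar, n, 1),
                               tau = list(c(-0.4, 0.5))))
  t1 <- out$draws[, "tau[y1,1]"]
  t2 <- out$draws[, "tau[y1,2]"]
  expect_true(all(t1 > -0.5 & t2 < 0.6 & t2 > t1))
})

test_that("structural coefficients follow the conjugate SUR conditional", {
  set.seed(81)
  n <- 3000
  X1 <- cbind(x1 = rbinom(n, 1, 0.5), x2 = rnorm(n))
  X2 <- cbind(x1 = rnorm(n))
  b1 <- c(0.5, -0.3); b2 <- 0.8
  eta <- cbind(X1 %*% b1 + rnorm(n), X2 %*% b2 + rnorm(n))
  pb <- kinvest:::new_problem(
    Y = matrix(0, n, 2), obs = matrix(FALSE, n, 2),
    item_factor = 1:2, ncat = c(2L, 2L), lam_group = c(0L, 0L),
    lam_fixed = c(1, 1), tau_group = 0L * 1:2, tau_ncat = integer(),
    X = list(f1 = X1, f2 = X2), continuous = TRUE)
  out <- run_chain(pb, toy_chain_config(500), update = "beta",
                   init = list(eta = eta))
  # with Psi = I the SUR conditional reduces to per-equation least squares
  ls1 <- coef(lm(eta[, 1] ~ X1 - 1))
  ls2 <- coef(lm(eta[, 2] ~ X2 - 1))
  post_mean <- colMeans(out$draws)
  expect_lt(abs(post_mean["beta[f1<-x1]"] - ls1[1]), 0.02)
  expect_lt(abs(post_mean["beta[f1<-x2]"] - ls1[2]), 0.02)
  expect_lt(abs(post_mean["beta[f2<-x1]"] - ls2[1]), 0.02)

  # no-data limit: prior N(0, 100^2)
  pb0 <- kinvest:::new_problem(
    Y = matrix(0, 4, 1), obs = matrix(FALSE, 4, 1),
    item_factor = 1L, ncat = 2L, lam_group = 0L, lam_fixed = 1,
    tau_group = 0L, tau_ncat = integer(), X = list(f1 = matrix(0, 4, 1)),
    continuous = TRUE)
  out0 <- run_chain(pb0, toy_chain_config(3000), update = "beta")
  expect_lt(abs(sd(out0$draws[, 1]) - 100), 5)
})

test_that("reference intercept is exactly zero in fitted models", {
  sm <- cached_small_fit()
  pooled <- pooled_draws(sm$fit)
  expect_true(all(pooled[, "alpha[MGM]"] == 0))
  # non-reference intercepts are free
  expect_gt(sd(pooled[, "alpha[PGF]"]), 0)
})

test_that("latent error covariance has the inverse-Wishart conditional", {
  set.seed(91)
  n <- 4000
  S_true <- matrix(c(1.2, 0.5, 0.5, 0.8), 2)
  R <- matrix(rnorm(n * 2), n, 2) %*% chol(S_true)
  pb <- kinvest:::new_problem(
    Y = matrix(0, n, 2), obs = matrix(FALSE, n, 2),
    item_factor = 1:2, ncat = c(2L, 2L), lam_group = c(0L, 0L),
    lam_fixed = c(1, 1), tau_group = 0L * 1:2, tau_ncat = integer(),
    X = list(f1 = matrix(0, n, 1), f2 = matrix(0, n, 1)),
    psi_df = 3, continuous = TRUE)
  out <- run_chain(pb, toy_chain_config(400), update = "psi",
                   init = list(eta = R), retain = character())
  # posterior mean of IW(I + R'R, df + n) is (I + R'R) / (df + n - dim - 1)
  S_emp <- (diag(2) + crossprod(R)) / (3 + n - 2 - 1)
  post_mean <- matrix(c(mean(out$draws[, "psi[f1,f1]"]),
                        mean(out$draws[, "psi[f2,f1]"]),
                        mean(out$draws[, "psi[f2,f1]"]),
                        mean(out$draws[, "psi[f2,f2]"])), 2)
  expect_lt(max(abs(post_mean - S_emp)), 0.05)

  # every draw symmetric positive definite (symmetry is structural: the
  # sampler stores the lower triangle once)
  v1 <- out$draws[, "psi[f1,f1]"]; v2 <- out$draws[, "psi[f2,f2]"]
  cv <- out$draws[, "psi[f2,f1]"]
  expect_true(all(v1 > 0 & v2 > 0 & v1 * v2 - cv^2 > 0))
})
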