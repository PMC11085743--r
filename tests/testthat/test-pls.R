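test_that("a response along a single predictor direction is fitted exactly", {
  set.seed(1)
  # mutually orthogonal centered columns: y lies along column 3 only
  X <- qr.Q(qr(scale(matrix(rnorm(60), 12, 5), scale = FALSE)))
  y <- X[, 3]
  m <- fit_pls1(X, y, ncomp = 1, scaling = "center")
  expect_lt(max(abs(m$residuals)), 1e-10)
})

test_that("univariate PLS reduces to ordinary least squares", {
  set.seed(2)
  x <- matrix(rnorm(12), 12, 1)
  y <- 2 * x[, 1] + rnorm(12, sd = 0.3)
  m <- fit_pls1(x, y, ncomp = 1, scaling = "center")
  ols <- stats::lm(y ~ x)
  expect_equal(unname(m$coefficients_raw), unname(coef(ols)[2]), tolerance = 1e-10)
  expect_equal(m$intercept, unname(coef(ols)[1]), tolerance = 1e-10)
})

test_that("scores are mutually orthogonal", {
  set.seed(3)
  X <- matrix(rnorm(120), 12, 10)
  y <- rnorm(12)
  m <- fit_pls1(X, y, ncomp = 4)
  G <- crossprod(m$T)
  expect_lt(max(abs(G[upper.tri(G)])), 1e-8)
  expect_equal(colSums(m$W^2), rep(1, 4), tolerance = 1e-12)
})

test_that("NIPALS agrees with the SVD-based oracle", {
  set.seed(4)
  for (i in 1:10) {
    X <- matrix(rnorm(120), 12, 10)
    y <- rnorm(12)
    m <- fit_pls1(X, y, ncomp = 3)
    o <- pls1_svd_oracle(X, y, ncomp = 3)
    expect_equal(m$coefficients, o$coefficients, tolerance = 1e-6)
    expect_equal(abs(m$W), abs(o$W), tolerance = 1e-6)
    expect_equal(m$SSa, o$SSa, tolerance = 1e-6)
  }
})

test_that("coefficients and VIP match mixOmics regression-mode PLS", {
  library(mixOmics)
  set.seed(5)
  X <- matrix(rnorm(120), 12, 10)
  y <- rnorm(12)
  m <- fit_pls1(X, y, ncomp = 2)
  mo <- mixOmics::pls(X, y, ncomp = 2, mode = "regression", scale = TRUE)
  expect_equal(unname(vip_scores(m)), unname(mixOmics::vip(mo)[, 2]),
               tolerance = 1e-8)
})

test_that("VIP satisfies its normalization identity and closed forms", {
  set.seed(6)
  # single predictor: VIP is identically 1
  x <- matrix(rnorm(12), 12, 1)
  m1 <- fit_pls1(x, 3 * x[, 1] + rnorm(12, sd = 0.1), ncomp = 1)
  expect_equal(unname(vip_scores(m1)), 1)
  # two predictors, response along predictor 1, predictor 2 orthogonal
  x1 <- rnorm(12); x1 <- x1 - mean(x1)
  x2 <- rnorm(12); x2 <- residuals(lm(x2 ~ x1))   # orthogonal to x1
  X <- cbind(x1, x2)
  m2 <- fit_pls1(X, x1, ncomp = 1, scaling = "center")
  expect_equal(unname(vip_scores(m2)), c(sqrt(2), 0), tolerance = 1e-6)
  # sum VIP^2 = P on arbitrary fits, and against the naive oracle
  for (i in 1:8) {
    X <- matrix(rnorm(12 * 9), 12, 9)
    y <- rnorm(12)
    m <- fit_pls1(X, y, ncomp = sample(1:4, 1))
    v <- vip_scores(m)
    expect_true(all(v >= 0))
    expect_equal(sum(v^2), 9, tolerance = 1e-8)
    expect_equal(unname(v), vip_oracle(m$W, m$SSa), tolerance = 1e-10)
  }
})

test_that("permuting predictor columns permutes VIP identically", {
  set.seed(7)
  X <- matrix(rnorm(120), 12, 10)
  y <- rnorm(12)
  v <- vip_scores(fit_pls1(X, y, ncomp = 2))
  perm <- sample(10)
  v2 <- vip_scores(fit_pls1(X[, perm], y, ncomp = 2))
  expect_equal(unname(v2), unname(v[perm]), tolerance = 1e-10)
})

test_that("VIP screening uses a strict threshold", {
  v <- c(P1 = sqrt(2), P2 = 0)
  expect_equal(unname(vip_screen(v)), c(TRUE, FALSE))
  expect_equal(unname(vip_screen(c(1, 1), 1)), c(FALSE, FALSE))
  expect_equal(unname(vip_screen(v, 0)), c(TRUE, FALSE))  # 0 is not > 0
})

test_that("degenerate fits raise informative errors", {
  X <- cbind(a = rnorm(12), b = rep(2, 12))
  expect_error(fit_pls1(X, rnorm(12), ncomp = 1), "b")
  expect_error(fit_pls1(matrix(rnorm(36), 12, 3), rnorm(12), ncomp = 5), "ncomp")
  expect_error(fit_pls1(matrix(rnorm(36), 12, 3), rep(1, 12), ncomp = 1),
               "covariance")
})

test_that("on noise-free data every driver's VIP beats the median non-active VIP", {
  # all actives drive all indicators, and enough batches are used for the
  # per-peak correlations to separate from the sampling noise floor
  cfg0 <- sim_config(noise_sd = 0, rt_jitter_sd = 0, seed = 8)
  beta <- matrix(0, 4, 36)
  for (m in 1:4) beta[m, cfg0$active_peaks] <- indicator_orientations()[m]
  cfg <- sim_config(n_batches = 96, noise_sd = 0, rt_jitter_sd = 0, seed = 8,
                    beta = beta)
  study <- simulate_study(cfg)
  mtx <- match_common_peaks(study$tables)
  non_active <- setdiff(1:36, cfg$active_peaks)
  for (A in 1:3) {
    vips <- pls_vip(mtx, study$panel, ncomp = A)$vip
    for (m in 1:4)
      expect_true(all(vips[m, cfg$active_peaks] >
                        stats::median(vips[m, non_active])))
  }
})

test_that("leave-one-out Q2 is high when predictors carry the response", {
  set.seed(9)
  X <- matrix(rnorm(48), 12, 4)
  y <- 2 * X[, 1] - X[, 2] + rnorm(12, sd = 0.2)
  expect_gt(pls_q2_loo(X, y, ncomp = 2), 0.5)
})
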