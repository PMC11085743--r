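# two well-separated 2-d clusters, linearly separable
separable_toy <- function(n_per = 10, seed = 1) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n_per, mean = 0, sd = 0.3), ncol = 2),
             matrix(rnorm(2 * n_per, mean = 3, sd = 0.3), ncol = 2))
  list(x = x, y = rep(c(1, 0), each = n_per))
}

test_that("analytic gradients match central finite differences", {
  set.seed(1)
  for (i in 1:5) {
    d <- sample(2:6, 1); h <- sample(2:5, 1); n <- sample(5:12, 1)
    x <- matrix(rnorm(n * d), n, d)
    y <- sample(0:1, n, replace = TRUE)
    par <- runif(d * h + 2 * h + 1, -0.5, 0.5)
    got <- specfx:::bpnn_loss_and_grad(par, x, y, h)$grad
    want <- fd_gradient(par, x, y, h)
    expect_lt(max(abs(got - want)) / max(1e-8, max(abs(want))), 1e-6)
  }
})

test_that("separable clusters are learned to perfect training accuracy", {
  toy <- separable_toy()
  m <- bpnn_train(toy$x, toy$y, epochs = 2000)
  ev <- bpnn_evaluate(m, toy$x, toy$y)
  expect_identical(ev$accuracy, 1)
  expect_equal(unname(diag(ev$confusion)), c(10L, 10L))
})

test_that("loss decreases strictly over the first epochs on separable data", {
  toy <- separable_toy()
  m <- bpnn_train(toy$x, toy$y, epochs = 50)
  expect_true(all(diff(m$loss[1:10]) < 0))
})

test_that("training is deterministic under a fixed seed", {
  toy <- separable_toy()
  m1 <- bpnn_train(toy$x, toy$y, epochs = 200, seed = 7)
  m2 <- bpnn_train(toy$x, toy$y, epochs = 200, seed = 7)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$loss, m2$loss)
  m3 <- bpnn_train(toy$x, toy$y, epochs = 200, seed = 8)
  expect_false(identical(m1$W1, m3$W1))
})

test_that("a 4-hidden-unit net solves XOR", {
  x <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  x <- x[rep(1:4, 3), ]                   # >= 2 per class
  y <- as.numeric(xor(x[, 1], x[, 2]))
  m <- bpnn_train(x, y, hidden_units = 4, epochs = 20000, seed = 1)
  expect_identical(bpnn_evaluate(m, x, y)$accuracy, 1)
})

test_that("feature assembly has the documented shape and scaling", {
  study <- quiet_study(seed = 2)
  m <- match_common_peaks(study$tables)
  g <- gra_grades(m, study$panel)
  v <- pls_vip(m, study$panel)$vip
  f <- assemble_features(g, v, study$binding, relative_content(m))
  expect_equal(dim(f), c(36L, 10L))
  expect_equal(colnames(f)[9:10], c("binding", "content"))
  expect_true(all(f >= 0 & f <= 1))
  expect_equal(unname(f[, "binding"]),
               as.numeric(1:36 %in% as.integer(study$binding)))
  # constant column degenerates to 0 with a warning
  expect_warning(
    f0 <- assemble_features(g, v, binding_set(integer()), relative_content(m)),
    "binding")
  expect_true(all(f0[, "binding"] == 0))
})

test_that("feature assembly rejects mismatched sources", {
  study <- quiet_study(seed = 2)
  m <- match_common_peaks(study$tables)
  g <- gra_grades(m, study$panel)
  v <- pls_vip(m, study$panel)$vip
  expect_error(assemble_features(g, v[, 1:10], study$binding,
                                 relative_content(m)), "peak count")
  expect_error(assemble_features(g, v, binding_set(99), relative_content(m)),
               "99")
})

test_that("training rejects degenerate label sets and bad step sizes", {
  toy <- separable_toy()
  expect_error(bpnn_train(toy$x, rep(1, 20), epochs = 10), "each class")
  expect_error(bpnn_train(toy$x, toy$y, learning_rate = -1), "learning_rate")
})

test_that("evaluation follows the rows-true / columns-predicted convention", {
  toy <- separable_toy()
  m <- bpnn_train(toy$x, toy$y, epochs = 2000)
  ev <- bpnn_evaluate(m, toy$x, toy$y)
  expect_identical(rownames(ev$confusion), c("A", "B"))
  expect_identical(names(dimnames(ev$confusion)), c("true", "predicted"))
  # degenerate all-A predictor: recall of class B is zero
  allA <- m
  allA$b2 <- 1e3
  ev2 <- bpnn_evaluate(allA, toy$x, toy$y)
  expect_identical(unname(ev2$recall["B"]), 0)
  expect_identical(sum(ev2$confusion[, "A"]), 20L)
})

test_that("an exact 0.5 output breaks the tie to inactive", {
  m <- structure(list(W1 = matrix(0, 2, 3), b1 = rep(0, 3),
                      w2 = rep(0, 3), b2 = 0, hidden_units = 3L),
                 class = "bpnn_model")
  x <- matrix(rnorm(10), 5, 2)
  expect_identical(unique(predict(m, x, type = "prob")), 0.5)
  expect_identical(unique(predict(m, x)), "B")
})

test_that("leave-one-out classification recovers nearly all planted actives", {
  # generalizing to a held-out active requires the actives to share an
  # activity signature, so this study uses a uniform effect pattern (every
  # active drives every indicator) and enough batches for the GRA/VIP
  # features to separate from the sampling-noise floor
  cfg0 <- sim_config(seed = 3)
  beta <- matrix(0, 4, 36)
  for (i in 1:4) beta[i, cfg0$active_peaks] <- indicator_orientations()[i]
  study <- simulate_study(sim_config(n_batches = 48, noise_sd = 1,
                                     rt_jitter_sd = 0, seed = 3, beta = beta))
  m <- match_common_peaks(study$tables)
  g <- gra_grades(m, study$panel)
  v <- pls_vip(m, study$panel)$vip
  f <- assemble_features(g, v, study$binding, relative_content(m))
  lab <- truth_labels(study)
  pred <- character(36)
  for (j in 1:36) {
    mod <- bpnn_train(f[-j, ], lab[-j], epochs = 4000, seed = 1)
    pred[j] <- predict(mod, f[j, , drop = FALSE])
  }
  recovered <- sum(pred[study$truth$active_peaks] == "A")
  expect_gte(recovered, 6L)
})
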