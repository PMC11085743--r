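# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive each quantity from the defining formulas with
# naive loops, sharing no code with the package internals.

# gray relational grades by naive double loop over comparisons and batches
gra_oracle <- function(ref, comps, rho = 0.5, normalization = "none") {
  norm1 <- function(v, method) {
    if (method == "mean") v / mean(v)
    else if (method == "minmax") (v - min(v)) / (max(v) - min(v))
    else v
  }
  x0 <- norm1(ref, normalization)
  n_comp <- nrow(comps)
  K <- length(ref)
  xn <- matrix(NA_real_, n_comp, K)
  for (i in seq_len(n_comp)) xn[i, ] <- norm1(comps[i, ], normalization)
  delta <- matrix(NA_real_, n_comp, K)
  for (i in seq_len(n_comp)) for (k in seq_len(K))
    delta[i, k] <- abs(x0[k] - xn[i, k])
  dmin <- min(delta); dmax <- max(delta)
  grades <- numeric(n_comp)
  for (i in seq_len(n_comp)) {
    xi <- numeric(K)
    for (k in seq_len(K))
      xi[k] <- (dmin + rho * dmax) / (delta[i, k] + rho * dmax)
    grades[i] <- mean(xi)
  }
  grades
}

# SVD-based PLS1: the component weight is the dominant left singular vector
# of the (deflated) cross-covariance X'y; scores/loadings/deflation follow
# the standard definitions
pls1_svd_oracle <- function(X, y, ncomp, scaling = "autoscale") {
  X <- as.matrix(X); y <- as.numeric(y)
  xc <- colMeans(X)
  xs <- if (scaling == "autoscale") apply(X, 2, sd) else rep(1, ncol(X))
  Xa <- sweep(sweep(X, 2, xc), 2, xs, "/")
  if (scaling == "none") Xa <- X
  ya <- y - mean(y)
  p <- ncol(X)
  W <- P <- matrix(0, p, ncomp); q <- ss <- numeric(ncomp)
  Tm <- matrix(0, nrow(X), ncomp)
  for (a in seq_len(ncomp)) {
    sv <- svd(crossprod(Xa, ya))
    w <- sv$u[, 1] * sign(sum(sv$u[, 1] * crossprod(Xa, ya)))  # fix SVD sign
    t_a <- drop(Xa %*% w)
    p_a <- drop(crossprod(Xa, t_a)) / sum(t_a^2)
    q_a <- sum(ya * t_a) / sum(t_a^2)
    Xa <- Xa - tcrossprod(t_a, p_a)
    ya <- ya - t_a * q_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a
    q[a] <- q_a; ss[a] <- q_a^2 * sum(t_a^2)
  }
  coef_scaled <- drop(W %*% solve(crossprod(P, W), q))
  list(W = W, T = Tm, q = q, SSa = ss, coefficients = coef_scaled)
}

vip_oracle <- function(W, SSa) {
  p <- nrow(W)
  vip <- numeric(p)
  for (j in seq_len(p)) {
    acc <- 0
    for (a in seq_len(ncol(W)))
      acc <- acc + SSa[a] * (W[j, a] / sqrt(sum(W[, a]^2)))^2
    vip[j] <- sqrt(p * acc / sum(SSa))
  }
  vip
}

# central finite-difference gradient of the BPNN loss
fd_gradient <- function(par, x, y, h, eps = 1e-6) {
  g <- numeric(length(par))
  for (i in seq_along(par)) {
    up <- par; up[i] <- up[i] + eps
    dn <- par; dn[i] <- dn[i] - eps
    g[i] <- (specfx:::bpnn_loss_and_grad(up, x, y, h)$loss -
             specfx:::bpnn_loss_and_grad(dn, x, y, h)$loss) / (2 * eps)
  }
  g
}

# a small deterministic study used by several tests
quiet_study <- function(seed = 1, noise = 0, jitter = 0) {
  simulate_study(sim_config(noise_sd = noise, rt_jitter_sd = jitter, seed = seed))
}

truth_labels <- function(study) {
  seq_len(study$truth$config$n_peaks) %in% study$truth$active_peaks
}
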