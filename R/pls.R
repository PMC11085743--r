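# PLS1 regression via NIPALS, with VIP (variable importance in projection)
# screening. One model per bioactivity indicator, as in per-indicator
# spectrum-effect modeling (an MTT-PLS, LDH-PLS, ATP-PLS and ROS-PLS model).
#
# The response is the continuous indicator value; VIP_j > 1 flags
# above-average contributors since mean(VIP^2) = 1 by construction.

#' Fit a single-response PLS regression by NIPALS
#'
#' Components are extracted sequentially: the weight vector of component `a`
#' is initialized from `X' y` (no random initialization — the fit is
#' deterministic), normalized to unit length, iterated to convergence, and
#' `X` and `y` are deflated by the extracted score. The response is always
#' centered; column scaling of `X` follows `scaling`.
#'
#' @param X Predictor matrix, batches x peaks (>= 3 rows).
#' @param y Response vector (one bioactivity indicator).
#' @param ncomp Number of latent components A, with
#'   `A <= min(nrow(X) - 1, ncol(X))`. Default 2.
#' @param scaling `"autoscale"` (center + unit variance, the chemometrics
#'   default), `"center"`, or `"none"`.
#' @param max_iter,tol Inner NIPALS iteration controls. Defaults 500, 1e-10.
#' @return A `pls1_model`: unit weights `W` (peaks x A), scores `T`
#'   (batches x A, mutually orthogonal), X-loadings `P`, y-loadings `q`,
#'   per-component explained response variance `SSa`, regression
#'   coefficients on both the scaled and the original scale, and the
#'   centering/scaling vectors.
#' @export
#' @examples
#' X <- matrix(rnorm(36), 12, 3)
#' y <- X[, 1] + rnorm(12, sd = 0.1)
#' m <- fit_pls1(X, y, ncomp = 2)
#' vip_scores(m)
fit_pls1 <- function(X, y, ncomp = 2L,
                     scaling = c("autoscale", "center", "none"),
                     max_iter = 500L, tol = 1e-10) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X); y <- as.numeric(y)
  n <- nrow(X); p <- ncol(X)
  if (n < 3L) stop("need at least 3 observations", call. = FALSE)
  if (length(y) != n) stop("X and y disagree in length", call. = FALSE)
  ncomp <- check_count(ncomp, "ncomp")
  if (ncomp > min(n - 1L, p))
    stop_config("ncomp", sprintf("must be <= min(n-1, p) = %d", min(n - 1L, p)))

  x_center <- colMeans(X)
  x_scale <- rep(1, p)
  if (scaling == "autoscale") {
    x_scale <- apply(X, 2L, stats::sd)
    if (any(x_scale == 0)) {
      bad <- colnames(X)[x_scale == 0]
      if (is.null(bad)) bad <- which(x_scale == 0)
      stop(sprintf("constant predictor column under autoscaling: %s",
                   paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  Xs <- if (scaling == "none") X else sweep(sweep(X, 2L, x_center), 2L, x_scale, "/")
  y_center <- mean(y)
  ys <- y - y_center

  W <- P <- matrix(0, p, ncomp)
  Tm <- matrix(0, n, ncomp)
  q <- SSa <- numeric(ncomp)
  Xa <- Xs; ya <- ys
  for (a in seq_len(ncomp)) {
    w <- crossprod(Xa, ya)
    nw <- sqrt(sum(w^2))
    if (nw < .Machine$double.eps)
      stop(sprintf("component %d: X carries no covariance with y", a),
           call. = FALSE)
    w <- w / nw
    for (it in seq_len(max_iter)) {     # PLS1 NIPALS: converges immediately,
      t_a <- drop(Xa %*% w)             # kept as a loop for the general contract
      q_a <- sum(ya * t_a) / sum(t_a^2)
      w_new <- crossprod(Xa, ya * q_a)
      w_new <- w_new / sqrt(sum(w_new^2))
      if (sqrt(sum((w_new - w)^2)) < tol) { w <- w_new; break }
      w <- w_new
    }
    t_a <- drop(Xa %*% w)
    tt <- sum(t_a^2)
    p_a <- crossprod(Xa, t_a) / tt
    q_a <- sum(ya * t_a) / tt
    Xa <- Xa - tcrossprod(t_a, p_a)
    ya <- ya - t_a * q_a
    W[, a] <- w; P[, a] <- p_a; Tm[, a] <- t_a
    q[a] <- q_a
    SSa[a] <- q_a^2 * tt                # response variance captured by comp a
  }

  # coefficients on the scaled space: B = W (P'W)^{-1} q
  coef_scaled <- drop(W %*% solve(crossprod(P, W), q))
  coef_orig <- coef_scaled / x_scale
  intercept <- y_center - sum(coef_orig * x_center)
  fitted <- drop(X %*% coef_orig) + intercept

  structure(list(W = W, T = Tm, P = P, q = q, SSa = SSa,
                 coefficients = coef_scaled, coefficients_raw = coef_orig,
                 intercept = intercept, fitted = fitted,
                 residuals = y - fitted,
                 x_center = x_center, x_scale = x_scale,
                 y_center = y_center, scaling = scaling, ncomp = ncomp,
                 peak_names = colnames(X)),
            class = "pls1_model")
}

#' @export
print.pls1_model <- function(x, ...) {
  cat(sprintf("PLS1 model: %d component(s), %d predictors (%s scaling)\n",
              x$ncomp, nrow(x$W), x$scaling))
  cat("explained y-variance per component:",
      paste(signif(x$SSa / sum(x$SSa), 3), collapse = " "), "\n")
  invisible(x)
}

#' @export
predict.pls1_model <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$coefficients_raw) + object$intercept
}

#' VIP scores of a fitted PLS1 model
#'
#' `VIP_j = sqrt( P * sum_a SSa_a w_ja^2 / sum_a SSa_a )` with unit-norm
#' weight vectors, where `SSa_a` is the response variance explained by
#' component `a` and `P` the number of predictors. Mean squared VIP is 1,
#' so `sum(VIP^2) = P` identically.
#'
#' @param model A `pls1_model`.
#' @return Numeric vector of non-negative VIP scores, one per predictor.
#' @export
vip_scores <- function(model) {
  stopifnot(inherits(model, "pls1_model"))
  ss <- sum(model$SSa)
  if (ss <= 0) stop("VIP undefined: no response variance explained", call. = FALSE)
  p <- nrow(model$W)
  vip <- sqrt(p * drop(model$W^2 %*% model$SSa) / ss)
  names(vip) <- model$peak_names
  vip
}

#' Screen peaks by VIP score
#'
#' Flags predictors whose VIP strictly exceeds the threshold; VIP > 1.0 is
#' the conventional above-average-importance rule.
#'
#' @param vip VIP vector (from [vip_scores()]) or an indicators x peaks VIP
#'   matrix.
#' @param threshold Strict lower bound. Default 1.0.
#' @return Logical vector/matrix of hits, same shape as `vip`.
#' @export
vip_screen <- function(vip, threshold = 1.0) {
  vip > threshold
}

#' Per-indicator VIP matrix for a fingerprint and bioactivity panel
#'
#' Fits one PLS1 model per indicator (four separate models, one per assay)
#' and stacks the VIP scores. The sign of the peak-indicator relationship
#' does not affect VIP, so no orientation handling is needed here.
#'
#' @param matrix A complete `common_peak_matrix`.
#' @param panel A `bioactivity_panel` for the same batches.
#' @inheritParams fit_pls1
#' @return List with `vip` (indicators x peaks matrix) and `models` (the
#'   four `pls1_model`s).
#' @export
pls_vip <- function(matrix, panel, ncomp = 2L,
                    scaling = c("autoscale", "center", "none")) {
  stopifnot(inherits(matrix, "common_peak_matrix"))
  scaling <- match.arg(scaling)
  vals <- as.matrix(as.data.frame(panel)[, .INDICATORS])
  if (nrow(vals) != length(matrix$batch_ids))
    stop("panel and matrix batch counts differ", call. = FALSE)
  models <- lapply(seq_len(4L), function(m)
    fit_pls1(matrix$areas, vals[, m], ncomp = ncomp, scaling = scaling))
  names(models) <- .INDICATORS
  vip <- do.call(rbind, lapply(models, vip_scores))
  rownames(vip) <- .INDICATORS
  list(vip = vip, models = models)
}

#' Leave-one-out Q2 of a PLS1 fit
#'
#' Utility for choosing the number of components: refits the model with each
#' batch left out and returns `Q2 = 1 - PRESS / TSS`. Provided as a
#' diagnostic, not an automatic selector.
#'
#' @inheritParams fit_pls1
#' @return Single numeric Q2 value.
#' @export
pls_q2_loo <- function(X, y, ncomp = 2L,
                       scaling = c("autoscale", "center", "none")) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X); y <- as.numeric(y)
  press <- 0
  for (i in seq_len(nrow(X))) {
    m <- fit_pls1(X[-i, , drop = FALSE], y[-i], ncomp = ncomp, scaling = scaling)
    press <- press + (y[i] - predict(m, X[i, , drop = FALSE]))^2
  }
  1 - press / sum((y - mean(y))^2)
}
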