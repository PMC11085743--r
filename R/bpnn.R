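# Backpropagation neural network, written from scratch: one hidden layer of
# logistic units, a single sigmoid output, cross-entropy loss, full-batch
# gradient descent. Classifies common peaks as active ("A") or inactive
# ("B") from the assembled screening features.

sigmoid <- function(z) 1 / (1 + exp(-z))

# flat-parameter forward/backward pass; kept separate so the analytic
# gradient can be checked against finite differences
bpnn_unpack <- function(par, d, h) {
  i <- 0L
  W1 <- matrix(par[i + seq_len(d * h)], nrow = d); i <- i + d * h
  b1 <- par[i + seq_len(h)]; i <- i + h
  w2 <- par[i + seq_len(h)]; i <- i + h
  b2 <- par[i + 1L]
  list(W1 = W1, b1 = b1, w2 = w2, b2 = b2)
}

bpnn_loss_and_grad <- function(par, x, y, h) {
  d <- ncol(x); n <- nrow(x)
  th <- bpnn_unpack(par, d, h)
  z1 <- sweep(x %*% th$W1, 2L, th$b1, "+")
  a1 <- sigmoid(z1)
  z2 <- drop(a1 %*% th$w2) + th$b2
  p <- sigmoid(z2)
  eps <- 1e-12                                 # clamp for the log
  loss <- -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
  dz2 <- (p - y) / n                           # d loss / d z2
  dw2 <- drop(crossprod(a1, dz2))
  db2 <- sum(dz2)
  dz1 <- (dz2 %o% th$w2) * a1 * (1 - a1)
  dW1 <- crossprod(x, dz1)
  db1 <- colSums(dz1)
  list(loss = loss, grad = c(as.vector(dW1), db1, dw2, db2), prob = p)
}

#' Assemble the per-peak feature table for classification
#'
#' One row per common peak, ten features in fixed column order: the four GRA
#' grades, the four VIP scores, the binding flag (0/1) and the mean relative
#' content. Features are min-max scaled to `[0, 1]` using the table's own
#' extrema (stored for reuse on new peaks); a constant column scales to 0
#' with a warning.
#'
#' @param gra A `gra_result` (or indicators x peaks grade matrix).
#' @param vip Indicators x peaks VIP matrix (e.g. `pls_vip(...)$vip`).
#' @param binding A `binding_set`.
#' @param content Per-peak relative content vector ([relative_content()]).
#' @return A `peak_features` matrix (peaks x 10) with attributes
#'   `feature_min` and `feature_max`.
#' @export
assemble_features <- function(gra, vip, binding, content) {
  grades <- if (inherits(gra, "gra_result")) gra$grades else as.matrix(gra)
  vip <- as.matrix(vip)
  P <- ncol(grades)
  if (ncol(vip) != P || length(content) != P)
    stop(sprintf("feature sources disagree on peak count (gra %d, vip %d, content %d)",
                 P, ncol(vip), length(content)), call. = FALSE)
  if (length(binding) && max(binding) > P)
    stop(sprintf("binding set names peak %d absent from the feature table",
                 max(binding)), call. = FALSE)
  feats <- cbind(t(grades), t(vip),
                 binding = as.numeric(seq_len(P) %in% as.integer(binding)),
                 content = as.numeric(content))
  colnames(feats) <- c(paste0("gra_", .INDICATORS), paste0("vip_", .INDICATORS),
                       "binding", "content")
  rownames(feats) <- if (!is.null(colnames(grades))) colnames(grades)
                     else paste0("P", seq_len(P))
  if (!all(is.finite(feats)))
    stop("non-finite feature value", call. = FALSE)
  fmin <- apply(feats, 2L, min)
  fmax <- apply(feats, 2L, max)
  rng <- fmax - fmin
  if (any(rng == 0))
    warning(sprintf("constant feature column(s) scaled to 0: %s",
                    paste(colnames(feats)[rng == 0], collapse = ", ")),
            call. = FALSE)
  scaled <- sweep(feats, 2L, fmin)
  scaled <- sweep(scaled, 2L, ifelse(rng == 0, 1, rng), "/")
  structure(scaled, feature_min = fmin, feature_max = fmax,
            class = c("peak_features", "matrix", "array"))
}

#' Train the peak classifier
#'
#' Full-batch gradient descent with backpropagation. Weights are initialized
#' from `Uniform(-0.5, 0.5)` under `seed`, so training is deterministic for
#' a fixed seed, data and configuration.
#'
#' @param features Numeric matrix (peaks x features), e.g. from
#'   [assemble_features()].
#' @param labels Class labels, `"A"` (active) / `"B"` (inactive), or a
#'   logical/0-1 vector where TRUE/1 means active. Both classes must be
#'   present with at least 2 members each.
#' @param hidden_units Hidden-layer width. Default 8.
#' @param learning_rate Gradient-descent step size. Default 0.5.
#' @param epochs Number of full-batch steps. Default 10000.
#' @param seed Seed for weight initialization. Default 1.
#' @return A `bpnn_model` with the weight matrices, the per-epoch loss
#'   history and the training configuration.
#' @export
bpnn_train <- function(features, labels, hidden_units = 8L,
                       learning_rate = 0.5, epochs = 10000L, seed = 1L) {
  x <- unclass(as.matrix(features))
  hidden_units <- check_count(hidden_units, "hidden_units")
  learning_rate <- check_positive(learning_rate, "learning_rate")
  epochs <- check_count(epochs, "epochs")
  y <- encode_labels(labels, nrow(x))
  if (sum(y) < 2L || sum(1 - y) < 2L)
    stop("need at least 2 peaks in each class", call. = FALSE)

  d <- ncol(x); h <- hidden_units
  npar <- d * h + h + h + 1L
  set.seed(seed)
  par <- stats::runif(npar, -0.5, 0.5)
  history <- numeric(epochs)
  for (e in seq_len(epochs)) {
    lg <- bpnn_loss_and_grad(par, x, y, h)
    if (!is.finite(lg$loss))
      stop("training diverged (non-finite loss); reduce learning_rate",
           call. = FALSE)
    history[e] <- lg$loss
    par <- par - learning_rate * lg$grad
  }
  th <- bpnn_unpack(par, d, h)
  structure(list(W1 = th$W1, b1 = th$b1, w2 = th$w2, b2 = th$b2,
                 hidden_units = h, learning_rate = learning_rate,
                 epochs = epochs, seed = seed, loss = history,
                 feature_names = colnames(x),
                 feature_min = attr(features, "feature_min"),
                 feature_max = attr(features, "feature_max")),
            class = "bpnn_model")
}

encode_labels <- function(labels, n) {
  if (length(labels) != n) stop("one label per peak required", call. = FALSE)
  if (is.logical(labels)) return(as.numeric(labels))
  if (is.numeric(labels)) {
    if (!all(labels %in% c(0, 1))) stop("numeric labels must be 0/1", call. = FALSE)
    return(as.numeric(labels))
  }
  labels <- as.character(labels)
  if (!all(labels %in% c("A", "B")))
    stop("labels must be 'A' (active) or 'B' (inactive)", call. = FALSE)
  as.numeric(labels == "A")
}

#' @export
print.bpnn_model <- function(x, ...) {
  cat(sprintf("BPNN peak classifier: %d-%d-1, %d epochs, final loss %.4g\n",
              nrow(x$W1), x$hidden_units, x$epochs, x$loss[x$epochs]))
  invisible(x)
}

#' Predict peak classes
#'
#' Output probabilities above 0.5 give class "A" (active); the tie at
#' exactly 0.5 breaks to "B" (inactive), the conservative choice for a
#' screen.
#'
#' @param object A `bpnn_model`.
#' @param newdata Feature matrix with the model's feature columns.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... Unused.
#' @return Character vector of classes, or numeric probabilities.
#' @export
predict.bpnn_model <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  x <- unclass(as.matrix(newdata))
  a1 <- sigmoid(sweep(x %*% object$W1, 2L, object$b1, "+"))
  p <- sigmoid(drop(a1 %*% object$w2) + object$b2)
  if (type == "prob") return(p)
  ifelse(p > 0.5, "A", "B")
}

#' Evaluate the classifier with a confusion matrix
#'
#' Rows are the true classes and columns the predicted classes (A = active
#' first). Also reports accuracy and per-class precision and recall.
#'
#' @param model A `bpnn_model`.
#' @param features Feature matrix.
#' @param labels True labels ("A"/"B", logical, or 0/1).
#' @return List with `confusion` (2 x 2), `accuracy`, `precision` and
#'   `recall` (named by class).
#' @export
bpnn_evaluate <- function(model, features, labels) {
  y <- encode_labels(labels, nrow(features))
  truth <- factor(ifelse(y == 1, "A", "B"), levels = c("A", "B"))
  pred <- factor(predict(model, features), levels = c("A", "B"))
  cm <- table(true = truth, predicted = pred)
  prec <- diag(cm) / pmax(colSums(cm), 1L)
  rec <- diag(cm) / pmax(rowSums(cm), 1L)
  list(confusion = cm, accuracy = sum(diag(cm)) / sum(cm),
       precision = prec, recall = rec)
}
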