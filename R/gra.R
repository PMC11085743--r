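# Gray relational analysis (GRA) between bioactivity indicators (reference
# series) and common-peak area series (comparison series).
#
# For a reference x0 and comparisons xi over batches k:
#   Delta_i(k) = |x0(k) - xi(k)|                 (after normalization)
#   Dmin, Dmax = global min/max of Delta over all i, k
#   xi_i(k)    = (Dmin + rho * Dmax) / (Delta_i(k) + rho * Dmax)
#   r_i        = mean_k xi_i(k)                  (relational grade, in (0, 1])
# rho is the distinguishing coefficient, conventionally 0.5.

#' Normalize a series for gray relational analysis
#'
#' @param series Numeric vector.
#' @param method `"mean"` divides by the series mean (output mean 1),
#'   `"minmax"` maps to `[0, 1]`, `"none"` is the identity.
#' @return Normalized numeric vector.
#' @export
#' @examples
#' normalize_series(c(2, 4, 6), "mean")    # 0.5 1.0 1.5
#' normalize_series(c(1, 3), "minmax")     # 0 1
normalize_series <- function(series, method = c("mean", "minmax", "none")) {
  method <- match.arg(method)
  series <- as.numeric(series)
  if (anyNA(series)) stop("series contains missing values", call. = FALSE)
  switch(method,
    mean = {
      m <- mean(series)
      if (m == 0) stop("mean normalization undefined: series mean is 0",
                       call. = FALSE)
      series / m
    },
    minmax = {
      rng <- range(series)
      if (rng[1L] == rng[2L])
        stop("min-max normalization undefined: constant series", call. = FALSE)
      (series - rng[1L]) / (rng[2L] - rng[1L])
    },
    none = series)
}

#' Gray relational grades of comparison series against one reference
#'
#' Normalizes the reference and each comparison independently, then applies
#' the relational-coefficient formula with distinguishing coefficient `rho`
#' and averages over batches.
#'
#' @param ref Reference series (length >= 2), e.g. one bioactivity indicator
#'   across batches.
#' @param comps Comparison series, peaks x batches matrix (or a single
#'   vector).
#' @param rho Distinguishing coefficient in (0, 1). Default 0.5.
#' @param normalization Passed to [normalize_series()]. Default `"mean"`.
#' @return List with `grades` (one per comparison row), `xi` (coefficient
#'   matrix, peaks x batches), `delta_min`, `delta_max`.
#' @export
#' @examples
#' relational_grade(c(1, 2, 3), rbind(c(3, 2, 1)), normalization = "none")$grades
#' # 5/9
relational_grade <- function(ref, comps, rho = 0.5,
                             normalization = c("mean", "minmax", "none")) {
  if (!is.numeric(rho) || length(rho) != 1L || rho <= 0 || rho >= 1)
    stop_config("rho", "must lie strictly between 0 and 1")
  normalization <- match.arg(normalization)
  if (is.vector(comps)) comps <- matrix(comps, nrow = 1L)
  comps <- as.matrix(comps)
  K <- length(ref)
  if (K < 2L) stop("reference series needs length >= 2", call. = FALSE)
  if (ncol(comps) != K)
    stop("reference and comparisons differ in batch length", call. = FALSE)

  x0 <- normalize_series(ref, normalization)
  xn <- t(apply(comps, 1L, normalize_series, method = normalization))
  if (ncol(xn) != K) xn <- t(xn)   # single-row apply() collapse

  delta <- abs(sweep(xn, 2L, x0))
  dmin <- min(delta); dmax <- max(delta)
  if (dmax == 0) {
    warning("all comparison series identical to the reference; grades set to 1",
            call. = FALSE)
    xi <- matrix(1, nrow = nrow(comps), ncol = K)
  } else {
    xi <- (dmin + rho * dmax) / (delta + rho * dmax)
  }
  rownames(xi) <- rownames(comps)
  list(grades = rowMeans(xi), xi = xi, delta_min = dmin, delta_max = dmax)
}

#' Gray relational analysis of a fingerprint against a bioactivity panel
#'
#' Runs [relational_grade()] once per indicator, using each indicator as the
#' reference and every common peak's area series as comparisons.
#'
#' With `orientation_handling = "protection_score"` (default), indicators
#' oriented lower-is-better (LDH, ROS) are reflected to a protection score
#' `max(series) - series` before analysis, so that for every indicator a
#' high grade reads "tracks protection"; the most-injured batch serves as
#' the model-group proxy. With `"raw"` the series enter as measured.
#'
#' @param matrix A complete `common_peak_matrix`.
#' @param panel A `bioactivity_panel` for the same batches (same order).
#' @param rho Distinguishing coefficient. Default 0.5.
#' @param normalization `"mean"` (default), `"minmax"` or `"none"`.
#' @param orientation_handling `"protection_score"` (default) or `"raw"`.
#' @return A `gra_result`: `grades` (indicators x peaks), per-indicator
#'   `xi` coefficient matrices, `delta_min`/`delta_max`, and the settings
#'   used.
#' @export
gra_grades <- function(matrix, panel, rho = 0.5,
                       normalization = c("mean", "minmax", "none"),
                       orientation_handling = c("protection_score", "raw")) {
  stopifnot(inherits(matrix, "common_peak_matrix"))
  normalization <- match.arg(normalization)
  orientation_handling <- match.arg(orientation_handling)
  vals <- as.matrix(as.data.frame(panel)[, .INDICATORS])
  if (nrow(vals) != length(matrix$batch_ids))
    stop("panel and matrix batch counts differ", call. = FALSE)
  comps <- t(matrix$areas)                       # peaks x batches

  P <- ncol(matrix$areas)
  grades <- matrix(NA_real_, nrow = 4L, ncol = P,
                   dimnames = list(.INDICATORS, colnames(matrix$areas)))
  xi <- vector("list", 4L); names(xi) <- .INDICATORS
  dmin <- dmax <- stats::setNames(numeric(4L), .INDICATORS)
  for (m in seq_len(4L)) {
    ref <- vals[, m]
    if (orientation_handling == "protection_score" && .ORIENTATION[m] < 0)
      ref <- max(ref) - ref
    res <- relational_grade(ref, comps, rho = rho, normalization = normalization)
    grades[m, ] <- res$grades
    xi[[m]] <- res$xi
    dmin[m] <- res$delta_min; dmax[m] <- res$delta_max
  }
  structure(list(grades = grades, xi = xi,
                 delta_min = dmin, delta_max = dmax,
                 rho = rho, normalization = normalization,
                 orientation_handling = orientation_handling),
            class = "gra_result")
}

#' @export
print.gra_result <- function(x, ...) {
  cat(sprintf("GRA result: %d indicators x %d peaks (rho=%g, %s normalization)\n",
              nrow(x$grades), ncol(x$grades), x$rho, x$normalization))
  print(round(x$grades, 3))
  invisible(x)
}

#' Screen peaks by gray relational grade
#'
#' Flags (indicator, peak) pairs whose relational grade strictly exceeds the
#' threshold; the conventional screening rule keeps grades greater than 0.9.
#'
#' @param result A `gra_result` (or a bare indicators x peaks grade matrix).
#' @param threshold Strict lower bound on the grade. Default 0.9.
#' @return Logical indicators x peaks hit matrix.
#' @export
gra_screen <- function(result, threshold = 0.9) {
  grades <- if (inherits(result, "gra_result")) result$grades else as.matrix(result)
  grades > threshold
}
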