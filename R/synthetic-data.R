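# Synthetic multi-batch fingerprint / bioassay generator with planted truth.
#
# The generator emulates the data regime of a multi-batch herbal-extract
# screening study: ~12 extract batches, ~36 common chromatographic peaks with
# lognormal batch-to-batch area variation, a 4-indicator cell bioassay panel
# (viability, LDH, ATP, ROS) linearly driven by a planted subset of active
# peaks, and a target-cell binding list containing the actives plus false
# positives. All randomness flows through R's default Mersenne-Twister RNG,
# seeded from `seed` (fingerprints) and `seed + 1` (assay noise), so a fixed
# seed gives bit-identical output.

default_active_peaks <- function(n_peaks, n_active = 7L) {
  if (n_active > n_peaks) stop_config("active_peaks", "more actives than peaks")
  unique(round(seq(2L, max(2L, n_peaks - 1L), length.out = n_active)))
}

default_binding_peaks <- function(n_peaks, active, n_binding = 17L) {
  extra_needed <- n_binding - length(active)
  pool <- setdiff(seq_len(n_peaks), active)
  if (extra_needed < 0L || extra_needed > length(pool))
    stop_config("binding_peaks", "cannot build default binding set of that size")
  # spread the false-positive binders evenly over the non-active peaks
  extra <- pool[unique(round(seq(1L, length(pool), length.out = extra_needed)))]
  sort(c(active, extra))
}

#' Simulation configuration for the synthetic screening study
#'
#' Defines a multi-batch study with planted ground truth: `n_peaks` common
#' chromatographic peaks across `n_batches` extract batches, a subset
#' `active_peaks` that linearly drives the four bioactivity indicators, and a
#' binding set `binding_peaks` (a superset of the actives) mimicking a
#' target-cell extraction result that contains false positives.
#'
#' Peak areas are lognormal (positive, right-skewed, as chromatographic peak
#' areas are): `log(area) ~ Normal(area_log_mean, area_log_sd)`. Indicator
#' `m` of batch `b` is `intercepts[m] + sum_j beta[m, j] * area[b, j] +
#' Normal(0, noise_sd)`. Effect signs follow indicator orientation: positive
#' on viability/ATP, negative on LDH/ROS, zero on non-active peaks.
#'
#' @param n_batches Number of extract batches (>= 3). Default 12.
#' @param n_peaks Number of common peaks. Default 36.
#' @param active_peaks Integer indices of the planted active peaks. Default:
#'   7 peaks spread evenly over the elution order.
#' @param binding_peaks Integer indices of peaks reported by the (simulated)
#'   target-cell extraction; must contain `active_peaks`. Default: the
#'   actives plus false positives, 17 peaks in all.
#' @param beta 4 x n_peaks effect matrix (rows in indicator order
#'   viability, ldh, atp, ros). Default: mechanism-specific — the actives
#'   are assigned round-robin to the four indicators (each indicator is
#'   driven by 1-2 constituents, each active drives exactly one indicator),
#'   with magnitude `beta_scale` and orientation signs; 0 elsewhere.
#' @param beta_scale Magnitude of the default per-peak effect. Default 2.
#' @param intercepts Length-4 indicator baselines. Defaults (20, 150, 20,
#'   150) keep all simulated readouts positive at the default area scale.
#' @param area_log_mean,area_log_sd Lognormal parameters of peak areas.
#'   Defaults `log(10)` and 0.4 (roughly 40% batch-to-batch CV).
#' @param noise_sd Indicator noise standard deviation. Default 3 (about 3%
#'   of a 100-scale readout).
#' @param rt_base True retention times (minutes), strictly increasing.
#'   Default: `n_peaks` values evenly spaced over 8-127 min.
#' @param rt_jitter_sd Per-batch retention-time jitter SD (minutes).
#'   Default 0.05.
#' @param seed Integer seed (< 2^31 - 2) or NULL.
#' @return A validated `sim_config` object (list).
#' @export
#' @examples
#' cfg <- sim_config(seed = 1)
#' cfg$active_peaks
sim_config <- function(n_batches = 12L, n_peaks = 36L,
                       active_peaks = NULL, binding_peaks = NULL,
                       beta = NULL, beta_scale = 2,
                       intercepts = NULL,
                       area_log_mean = log(10), area_log_sd = 0.4,
                       noise_sd = 3,
                       rt_base = NULL, rt_jitter_sd = 0.05,
                       seed = NULL) {
  n_batches <- check_count(n_batches, "n_batches", min = 3L)
  n_peaks <- check_count(n_peaks, "n_peaks", min = 1L)
  if (is.null(active_peaks)) active_peaks <- default_active_peaks(n_peaks)
  active_peaks <- sort(unique(as.integer(active_peaks)))
  if (length(active_peaks) &&
      (min(active_peaks) < 1L || max(active_peaks) > n_peaks))
    stop_config("active_peaks", "indices must lie in 1..n_peaks")
  if (is.null(binding_peaks))
    binding_peaks <- default_binding_peaks(n_peaks, active_peaks)
  binding_peaks <- sort(unique(as.integer(binding_peaks)))
  if (length(binding_peaks) &&
      (min(binding_peaks) < 1L || max(binding_peaks) > n_peaks))
    stop_config("binding_peaks", "indices must lie in 1..n_peaks")
  if (!all(active_peaks %in% binding_peaks))
    stop_config("binding_peaks", "must contain every active peak")

  check_positive(beta_scale, "beta_scale")
  if (is.null(beta)) {
    # mechanism-specific effects: the i-th active drives indicator
    # ((i-1) mod 4) + 1, so each assay responds to its own constituent
    # subset and the four models carry complementary information
    beta <- matrix(0, nrow = 4L, ncol = n_peaks,
                   dimnames = list(.INDICATORS, NULL))
    for (i in seq_along(active_peaks)) {
      m <- (i - 1L) %% 4L + 1L
      beta[m, active_peaks[i]] <- .ORIENTATION[m] * beta_scale
    }
  } else {
    beta <- as.matrix(beta)
    if (!identical(dim(beta), c(4L, n_peaks)))
      stop_config("beta", sprintf("must be 4 x %d", n_peaks))
    rownames(beta) <- .INDICATORS
    inactive <- setdiff(seq_len(n_peaks), active_peaks)
    if (any(beta[, inactive] != 0))
      stop_config("beta", "nonzero effect on a non-active peak")
    for (m in seq_len(4L))
      if (any(.ORIENTATION[m] * beta[m, active_peaks] < 0))
        stop_config("beta", sprintf(
          "row '%s' sign must match indicator orientation", .INDICATORS[m]))
  }

  if (is.null(intercepts)) intercepts <- c(20, 150, 20, 150)
  if (!is.numeric(intercepts) || length(intercepts) != 4L || anyNA(intercepts))
    stop_config("intercepts", "must be 4 finite numbers")
  intercepts <- stats::setNames(as.numeric(intercepts), .INDICATORS)

  area_log_mean <- as.numeric(area_log_mean)
  if (!is.finite(area_log_mean)) stop_config("area_log_mean", "must be finite")
  area_log_sd <- check_positive(area_log_sd, "area_log_sd")
  noise_sd <- check_nonneg(noise_sd, "noise_sd")
  if (is.null(rt_base)) rt_base <- seq(8, 127, length.out = n_peaks)
  if (!is.numeric(rt_base) || length(rt_base) != n_peaks)
    stop_config("rt_base", sprintf("must have length %d", n_peaks))
  if (is.unsorted(rt_base, strictly = TRUE))
    stop_config("rt_base", "must be strictly increasing")
  rt_jitter_sd <- check_nonneg(rt_jitter_sd, "rt_jitter_sd")
  if (!is.null(seed)) {
    seed <- check_count(seed, "seed", min = 0L)
    if (seed > 2^31 - 3) stop_config("seed", "must be below 2^31 - 2")
  }

  structure(list(
    n_batches = n_batches, n_peaks = n_peaks,
    active_peaks = active_peaks, binding_peaks = binding_peaks,
    beta = beta, intercepts = intercepts,
    area_log_mean = area_log_mean, area_log_sd = area_log_sd,
    noise_sd = noise_sd,
    rt_base = as.numeric(rt_base), rt_jitter_sd = rt_jitter_sd,
    seed = seed), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "Synthetic study: %d batches x %d peaks, %d active, %d binding, noise_sd=%g\n",
    x$n_batches, x$n_peaks, length(x$active_peaks), length(x$binding_peaks),
    x$noise_sd))
  invisible(x)
}

batch_ids <- function(config) sprintf("B%02d", seq_len(config$n_batches))

#' Simulate per-batch chromatographic peak tables
#'
#' Draws, for every batch, one peak per planted component with retention time
#' `rt_base[j] + Normal(0, rt_jitter_sd)` and a lognormal area, and returns
#' the per-batch peak tables together with the ground truth (planted actives,
#' binding set, effect matrix, and realized area/RT matrices).
#'
#' @param config A [sim_config()].
#' @return List with elements `tables` (list of `peak_table`, one per batch,
#'   each sorted by retention time) and `truth` (a `ground_truth` list with
#'   `active_peaks`, `binding_peaks`, `beta`, `areas` (batches x peaks),
#'   `rt` (batches x peaks) and `expected_indicators` (batches x 4,
#'   pre-noise)).
#' @export
#' @examples
#' sim <- simulate_fingerprints(sim_config(seed = 1))
#' length(sim$tables)
#' dim(sim$truth$areas)
simulate_fingerprints <- function(config) {
  if (!inherits(config, "sim_config")) config <- do.call(sim_config, config)
  if (!is.null(config$seed)) set.seed(config$seed)
  B <- config$n_batches; P <- config$n_peaks
  ids <- batch_ids(config)
  areas <- matrix(exp(stats::rnorm(B * P, config$area_log_mean, config$area_log_sd)),
                  nrow = B, ncol = P, dimnames = list(ids, NULL))
  rt <- matrix(rep(config$rt_base, each = B), nrow = B) +
    matrix(stats::rnorm(B * P, 0, config$rt_jitter_sd), nrow = B)
  dimnames(rt) <- list(ids, NULL)
  tables <- lapply(seq_len(B), function(b)
    peak_table(ids[b], rt = rt[b, ], area = areas[b, ]))
  names(tables) <- ids
  expected <- sweep(areas %*% t(config$beta), 2L, config$intercepts, "+")
  truth <- structure(list(
    active_peaks = config$active_peaks,
    binding_peaks = config$binding_peaks,
    beta = config$beta,
    areas = areas, rt = rt,
    expected_indicators = expected,
    config = config), class = "ground_truth")
  list(tables = tables, truth = truth)
}

#' Simulate the bioactivity panel from peak areas
#'
#' Computes each indicator as the configured linear combination of peak areas
#' plus the intercept and Gaussian noise of SD `noise_sd`. Noise is drawn
#' under seed `config$seed + 1` so fingerprints and assay noise are
#' independently reproducible.
#'
#' @param areas A `common_peak_matrix` or a plain batches x peaks matrix.
#' @param config A [sim_config()]; `ncol(areas)` must equal `n_peaks`.
#' @return A `bioactivity_panel`: data.frame with `batch_id` and columns
#'   viability, ldh, atp, ros; orientation flags in
#'   `attr(panel, "orientation")`.
#' @export
simulate_bioactivity <- function(areas, config) {
  if (inherits(areas, "common_peak_matrix")) areas <- areas$areas
  areas <- as.matrix(areas)
  if (ncol(areas) != config$n_peaks)
    stop(sprintf("dimension mismatch: areas have %d peaks, beta has %d",
                 ncol(areas), config$n_peaks), call. = FALSE)
  if (anyNA(areas)) stop("areas must be complete (no missing cells)", call. = FALSE)
  if (!is.null(config$seed)) set.seed(config$seed + 1L)
  B <- nrow(areas)
  vals <- sweep(areas %*% t(config$beta), 2L, config$intercepts, "+") +
    matrix(stats::rnorm(B * 4L, 0, config$noise_sd), nrow = B)
  ids <- rownames(areas)
  if (is.null(ids)) ids <- sprintf("B%02d", seq_len(B))
  bioactivity_panel(ids, vals)
}

#' Construct a bioactivity panel
#'
#' @param batch_id Character vector of batch identifiers.
#' @param values Matrix (batches x 4) of indicator readouts in column order
#'   viability, ldh, atp, ros.
#' @return A `bioactivity_panel` data.frame with orientation metadata.
#' @export
bioactivity_panel <- function(batch_id, values) {
  values <- as.matrix(values)
  if (ncol(values) != 4L) stop("panel needs 4 indicator columns", call. = FALSE)
  if (nrow(values) != length(batch_id)) stop("batch_id length mismatch", call. = FALSE)
  colnames(values) <- .INDICATORS
  out <- data.frame(batch_id = as.character(batch_id), values,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "orientation") <- .ORIENTATION
  class(out) <- c("bioactivity_panel", "data.frame")
  out
}

#' Return the planted binding set
#'
#' Packages `truth$binding_peaks` (the peaks a target-cell extraction would
#' report: every active plus the planted false positives) as a
#' [binding_set()].
#'
#' @param truth A `ground_truth` object from [simulate_fingerprints()].
#' @param config The matching [sim_config()] (used only for validation).
#' @return A `binding_set` of peak indices.
#' @export
simulate_binding <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "ground_truth"))
  binding_set(truth$binding_peaks)
}

#' Simulate a complete study in one call
#'
#' Runs [simulate_fingerprints()], [simulate_bioactivity()] (on the true,
#' pre-jitter area matrix) and [simulate_binding()] under one configuration.
#'
#' @param config A [sim_config()].
#' @return List with `tables`, `panel`, `binding` and `truth`.
#' @export
#' @examples
#' study <- simulate_study(sim_config(seed = 7))
#' names(study)
simulate_study <- function(config = sim_config()) {
  fp <- simulate_fingerprints(config)
  panel <- simulate_bioactivity(fp$truth$areas, config)
  list(tables = fp$tables, panel = panel,
       binding = simulate_binding(fp$truth, config), truth = fp$truth)
}

#' Write a simulated study to plain-text files
#'
#' Writes `peaks.csv` (long format: batch_id, rt_min, area), `panel.csv`,
#' `binding.csv` (one peak id per row) and `truth.json` under `dir`.
#'
#' @param study Result of [simulate_study()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  peaks <- do.call(rbind, lapply(study$tables, as.data.frame))
  paths <- c(peaks = file.path(dir, "peaks.csv"),
             panel = file.path(dir, "panel.csv"),
             binding = file.path(dir, "binding.csv"),
             truth = file.path(dir, "truth.json"))
  utils::write.csv(peaks, paths[["peaks"]], row.names = FALSE)
  utils::write.csv(as.data.frame(study$panel), paths[["panel"]], row.names = FALSE)
  utils::write.csv(data.frame(peak_id = as.integer(study$binding)),
                   paths[["binding"]], row.names = FALSE)
  truth <- study$truth
  jsonlite::write_json(list(
    active_peaks = truth$active_peaks, binding_peaks = truth$binding_peaks,
    beta = truth$beta, areas = truth$areas, rt = truth$rt), paths[["truth"]],
    digits = NA)
  invisible(paths)
}
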