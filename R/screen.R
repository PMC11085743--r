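# Orchestrates the full screening decision:
#   fingerprint -> GRA + PLS/VIP -> combined spectrum-effect hits
#   -> binding intersection -> relative-content filter -> BPNN class filter
# and records a per-peak decision trace.

#' Screening configuration
#'
#' @param gra_threshold Strict lower bound on the GRA grade. Default 0.9.
#' @param vip_threshold Strict lower bound on the VIP score. Default 1.0.
#' @param min_indicator_hits Number of indicators a method must flag for a
#'   peak to count as a hit of that method. Default 1.
#' @param combine_methods `"union"` (hit by GRA or by VIP; the default,
#'   since either method alone can miss true actives) or `"intersection"`.
#' @param content_min Minimum mean relative content; peaks below it are
#'   excluded as low-content. Default 0.005 (0.5% of total area).
#' @param require_binding Require membership in the target-cell binding set.
#'   Default TRUE.
#' @param use_bpnn Apply the BPNN class filter as the last stage (requires
#'   training labels). Default TRUE.
#' @param rt_tolerance Retention-time matching tolerance (minutes) for
#'   [match_common_peaks()]. Default 0.5.
#' @param rho,gra_normalization,orientation_handling GRA settings, see
#'   [gra_grades()].
#' @param pls_ncomp,pls_scaling PLS settings, see [fit_pls1()].
#' @param hidden_units,learning_rate,epochs,seed BPNN settings, see
#'   [bpnn_train()].
#' @return A validated `screen_config` list.
#' @export
screen_config <- function(gra_threshold = 0.9, vip_threshold = 1.0,
                          min_indicator_hits = 1L,
                          combine_methods = c("union", "intersection"),
                          content_min = 0.005,
                          require_binding = TRUE, use_bpnn = TRUE,
                          rt_tolerance = 0.5,
                          rho = 0.5, gra_normalization = "mean",
                          orientation_handling = "protection_score",
                          pls_ncomp = 2L, pls_scaling = "autoscale",
                          hidden_units = 8L, learning_rate = 0.5,
                          epochs = 10000L, seed = 1L) {
  combine_methods <- match.arg(combine_methods)
  check_nonneg(gra_threshold, "gra_threshold")
  check_nonneg(vip_threshold, "vip_threshold")
  min_indicator_hits <- check_count(min_indicator_hits, "min_indicator_hits")
  if (!is.numeric(content_min) || content_min < 0 || content_min >= 1)
    stop_config("content_min", "must lie in [0, 1)")
  structure(list(
    gra_threshold = gra_threshold, vip_threshold = vip_threshold,
    min_indicator_hits = min_indicator_hits, combine_methods = combine_methods,
    content_min = content_min, require_binding = isTRUE(require_binding),
    use_bpnn = isTRUE(use_bpnn), rt_tolerance = rt_tolerance,
    rho = rho, gra_normalization = gra_normalization,
    orientation_handling = orientation_handling,
    pls_ncomp = pls_ncomp, pls_scaling = pls_scaling,
    hidden_units = hidden_units, learning_rate = learning_rate,
    epochs = epochs, seed = seed), class = "screen_config")
}

#' Combine GRA and VIP hits into spectrum-effect hits
#'
#' A peak is a GRA (resp. VIP) hit when at least `min_indicator_hits` of the
#' four indicator models flag it. Under `"union"` either method suffices;
#' under `"intersection"` both are required.
#'
#' @param gra_hits,vip_hits Logical indicators x peaks hit matrices
#'   ([gra_screen()], [vip_screen()]).
#' @param min_indicator_hits Minimum flagging indicators per method.
#'   Default 1.
#' @param combine_methods `"union"` (default) or `"intersection"`.
#' @return Sorted integer vector of hit peak ids.
#' @export
spectrum_effect_hits <- function(gra_hits, vip_hits, min_indicator_hits = 1L,
                                 combine_methods = c("union", "intersection")) {
  combine_methods <- match.arg(combine_methods)
  gra_hits <- as.matrix(gra_hits); vip_hits <- as.matrix(vip_hits)
  if (ncol(gra_hits) != ncol(vip_hits))
    stop("hit matrices disagree on peak count", call. = FALSE)
  g <- colSums(gra_hits) >= min_indicator_hits
  v <- colSums(vip_hits) >= min_indicator_hits
  hit <- if (combine_methods == "union") g | v else g & v
  which(hit)
}

fnv1a <- function(s) {
  # 32-bit FNV-1a over the UTF-8 bytes, for config provenance stamps;
  # arithmetic on doubles (exact below 2^53), xor on 16-bit halves
  h <- 2166136261
  for (b in as.integer(charToRaw(enc2utf8(s)))) {
    lo <- bitwXor(as.integer(h %% 65536), b)
    h <- (h %/% 65536) * 65536 + lo
    h <- (h * 16777619) %% 2^32
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

config_hash <- function(config) {
  fnv1a(as.character(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                      digits = NA)))
}

#' Run the full screening pipeline
#'
#' Stages, in order: common-peak matching (skipped when `tables` is already
#' a `common_peak_matrix`), GRA and PLS/VIP per indicator, combination into
#' spectrum-effect hits, intersection with the binding set, relative-content
#' filter, and finally the BPNN class filter. Every peak receives a decision
#' trace recording which rules fired.
#'
#' @param tables List of `peak_table`s, or a ready `common_peak_matrix`.
#' @param panel A `bioactivity_panel` for the same batches.
#' @param binding A `binding_set` (required when
#'   `config$require_binding`); `NULL` is treated as an empty set for the
#'   feature table.
#' @param labels Training labels for the BPNN stage ("A"/"B", logical or
#'   0/1 per peak): ground truth in a synthetic study, literature-verified
#'   assignments in a real one. Required when `config$use_bpnn`.
#' @param config A [screen_config()].
#' @return A `candidate_report`: `candidates` (final peak ids), `trace`
#'   (per-peak data.frame), the `gra`/`vip` matrices, the fitted BPNN (if
#'   used), the configuration and provenance metadata.
#' @export
#' @examples
#' study <- simulate_study(sim_config(noise_sd = 0, rt_jitter_sd = 0, seed = 1))
#' rep <- run_screen(study$tables, study$panel, study$binding,
#'                   labels = seq_len(36) %in% study$truth$active_peaks)
#' rep$candidates
run_screen <- function(tables, panel, binding = NULL, labels = NULL,
                       config = screen_config()) {
  stopifnot(inherits(config, "screen_config"))
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  matrix <- if (inherits(tables, "common_peak_matrix")) tables else
    stage("fingerprint", match_common_peaks(tables, config$rt_tolerance))
  P <- length(matrix$peak_ids)

  gra <- stage("gra", gra_grades(matrix, panel, rho = config$rho,
                                 normalization = config$gra_normalization,
                                 orientation_handling = config$orientation_handling))
  pls <- stage("pls", pls_vip(matrix, panel, ncomp = config$pls_ncomp,
                              scaling = config$pls_scaling))
  gra_hits <- gra_screen(gra, config$gra_threshold)
  vip_hits <- vip_screen(pls$vip, config$vip_threshold)
  spectrum <- spectrum_effect_hits(gra_hits, vip_hits,
                                   config$min_indicator_hits,
                                   config$combine_methods)

  if (is.null(binding)) {
    if (config$require_binding)
      stop("stage 'binding' failed: require_binding is TRUE but no binding set given",
           call. = FALSE)
    binding <- binding_set(integer())
  }
  bound <- seq_len(P) %in% as.integer(binding)
  after_binding <- if (config$require_binding)
    intersect_hits(spectrum, binding) else spectrum

  content <- stage("content", relative_content(matrix))
  content_ok <- content >= config$content_min
  after_content <- after_binding[content_ok[after_binding]]

  bpnn <- NULL
  bpnn_class <- rep(NA_character_, P)
  bpnn_prob <- rep(NA_real_, P)
  if (config$use_bpnn) {
    if (is.null(labels))
      stop("stage 'bpnn' failed: use_bpnn is TRUE but no training labels given",
           call. = FALSE)
    feats <- stage("bpnn", assemble_features(gra, pls$vip, binding, content))
    bpnn <- stage("bpnn", bpnn_train(feats, labels,
                                     hidden_units = config$hidden_units,
                                     learning_rate = config$learning_rate,
                                     epochs = config$epochs, seed = config$seed))
    bpnn_prob <- predict(bpnn, feats, type = "prob")
    bpnn_class <- ifelse(bpnn_prob > 0.5, "A", "B")
    candidates <- after_content[bpnn_class[after_content] == "A"]
  } else {
    candidates <- after_content
  }

  rules <- vapply(seq_len(P), function(j) {
    r <- character()
    if (j %in% spectrum) r <- c(r, "spectrum-hit") else r <- c(r, "no-spectrum-hit")
    if (config$require_binding)
      r <- c(r, if (bound[j]) "bound" else "not-bound")
    if (!content_ok[j]) r <- c(r, "content-filtered")
    if (config$use_bpnn) r <- c(r, paste0("bpnn-", bpnn_class[j]))
    paste(r, collapse = ";")
  }, character(1L))

  trace <- data.frame(
    peak = seq_len(P), consensus_rt = matrix$consensus_rt,
    t(gra$grades), t(pls$vip),
    gra_indicator_hits = colSums(gra_hits),
    vip_indicator_hits = colSums(vip_hits),
    spectrum_hit = seq_len(P) %in% spectrum,
    binding = bound,
    content = as.numeric(content), content_ok = content_ok,
    bpnn_class = bpnn_class, bpnn_prob = bpnn_prob,
    candidate = seq_len(P) %in% candidates,
    rules = rules,
    stringsAsFactors = FALSE, row.names = NULL)
  names(trace)[3:10] <- c(paste0("gra_", .INDICATORS), paste0("vip_", .INDICATORS))

  structure(list(candidates = as.integer(candidates), trace = trace,
                 gra = gra$grades, vip = pls$vip, bpnn = bpnn,
                 config = config,
                 metadata = list(package_version = as.character(utils::packageVersion("specfx")),
                                 config_hash = config_hash(config),
                                 seed = config$seed,
                                 n_batches = length(matrix$batch_ids),
                                 n_peaks = P)),
            class = "candidate_report")
}

#' @export
print.candidate_report <- function(x, ...) {
  cat(sprintf("Screening report: %d of %d peaks nominated: %s\n",
              length(x$candidates), x$metadata$n_peaks,
              if (length(x$candidates)) paste(x$candidates, collapse = ", ")
              else "(none)"))
  invisible(x)
}

#' Run the pipeline from files
#'
#' Thin wrapper over [run_screen()]: reads peak tables (directory or long
#' CSV), the bioactivity panel CSV (columns batch_id, viability, ldh, atp,
#' ros), an optional binding CSV (column peak_id) and an optional labels CSV
#' (columns peak_id, label).
#'
#' @param peaks Path to peak tables (directory of CSVs or one long CSV).
#' @param panel Path to the panel CSV.
#' @param binding Optional path to the binding CSV.
#' @param labels Optional path to the labels CSV.
#' @param config A [screen_config()].
#' @return A `candidate_report`.
#' @export
run_screen_files <- function(peaks, panel, binding = NULL, labels = NULL,
                             config = screen_config()) {
  tables <- read_peak_tables(peaks)
  pdf <- utils::read.csv(panel, stringsAsFactors = FALSE)
  pan <- bioactivity_panel(pdf$batch_id, as.matrix(pdf[, .INDICATORS]))
  ord <- vapply(tables, function(t) t$batch_id[1L], character(1L))
  pan <- pan[match(ord, pan$batch_id), , drop = FALSE]
  matrix <- match_common_peaks(tables, config$rt_tolerance)
  bind <- if (!is.null(binding)) load_binding_set(binding, matrix) else NULL
  labs <- NULL
  if (!is.null(labels)) {
    ldf <- utils::read.csv(labels, stringsAsFactors = FALSE)
    labs <- rep("B", length(matrix$peak_ids))
    labs[ldf$peak_id[ldf$label %in% c("A", "1", "TRUE", "active")]] <- "A"
  }
  run_screen(matrix, pan, bind, labs, config)
}

#' Write / read a screening report
#'
#' `write_report` writes `report.json` (machine-readable: candidates, trace,
#' configuration, metadata, in deterministic field order) plus
#' `trace.csv` and a short `summary.md` under `dir`. `read_report` restores
#' the JSON into a `candidate_report` (models are not serialized).
#'
#' @param report A `candidate_report`.
#' @param dir Output directory (created if absent).
#' @param path Path to a written `report.json`.
#' @return `write_report` invisibly returns the file paths; `read_report`
#'   the restored report.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "candidate_report"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(json = file.path(dir, "report.json"),
             csv = file.path(dir, "trace.csv"),
             md = file.path(dir, "summary.md"))
  jsonlite::write_json(list(candidates = report$candidates,
                            trace = report$trace,
                            config = unclass(report$config),
                            metadata = report$metadata),
                       paths[["json"]], auto_unbox = TRUE, digits = NA,
                       na = "null")
  utils::write.csv(report$trace, paths[["csv"]], row.names = FALSE)
  md <- c("# Screening summary", "",
          sprintf("- batches: %d, common peaks: %d", report$metadata$n_batches,
                  report$metadata$n_peaks),
          sprintf("- config hash: %s, seed: %s", report$metadata$config_hash,
                  report$metadata$seed),
          sprintf("- nominated peaks: %s",
                  if (length(report$candidates))
                    paste(report$candidates, collapse = ", ") else "(none)"))
  writeLines(md, paths[["md"]])
  invisible(paths)
}

#' @rdname write_report
#' @export
read_report <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  trace <- as.data.frame(obj$trace, stringsAsFactors = FALSE)
  structure(list(candidates = as.integer(obj$candidates), trace = trace,
                 gra = NULL, vip = NULL, bpnn = NULL,
                 config = do.call(screen_config, obj$config[
                   names(obj$config) %in% names(formals(screen_config))]),
                 metadata = obj$metadata),
            class = "candidate_report")
}
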