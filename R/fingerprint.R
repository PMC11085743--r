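# Fingerprint construction: per-batch peak tables -> common-peak matrix.
#
# Peaks are matched across batches purely by retention time (the matching
# tolerance is a parameter, not a constant of nature): greedy clustering
# seeded from the batch with the most peaks, refined by consensus means.

#' Construct a per-batch peak table
#'
#' @param batch_id Single batch identifier.
#' @param rt Retention times in minutes.
#' @param area Peak areas (strictly positive), same length as `rt`.
#' @return A `peak_table` data.frame with columns batch_id, rt_min, area,
#'   sorted by retention time.
#' @export
#' @examples
#' peak_table("B01", rt = c(20, 10), area = c(3, 5))
peak_table <- function(batch_id, rt, area) {
  stopifnot(length(batch_id) == 1L, length(rt) == length(area))
  rt <- as.numeric(rt); area <- as.numeric(area)
  if (anyNA(rt) || anyNA(area))
    stop("peak table contains missing values", call. = FALSE)
  if (length(area) && any(area <= 0))
    stop(sprintf("non-positive peak area in batch '%s'", batch_id), call. = FALSE)
  ord <- order(rt)
  out <- data.frame(batch_id = rep(as.character(batch_id), length(rt)),
                    rt_min = rt[ord], area = area[ord],
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("peak_table", "data.frame")
  out
}

#' Read a single-batch peak table from CSV
#'
#' Expects columns `batch_id`, `rt_min`, `area`. Rows failing to parse or
#' carrying non-positive areas raise an error naming the offending line.
#'
#' @param path CSV file path. An empty file (header only or zero bytes)
#'   yields an empty table.
#' @param batch_id Batch id to assign when the file is empty; otherwise
#'   taken from the file (which must contain exactly one batch).
#' @return A `peak_table`.
#' @export
read_peak_table <- function(path, batch_id = basename(path)) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path), call. = FALSE)
  raw <- tryCatch(
    utils::read.csv(path, stringsAsFactors = FALSE, colClasses = NA),
    error = function(e) stop(sprintf("cannot parse '%s': %s", path,
                                     conditionMessage(e)), call. = FALSE))
  if (nrow(raw) == 0L) return(peak_table(batch_id, numeric(), numeric()))
  need <- c("batch_id", "rt_min", "area")
  if (!all(need %in% names(raw)))
    stop(sprintf("'%s' must have columns %s", path,
                 paste(need, collapse = ", ")), call. = FALSE)
  rt <- suppressWarnings(as.numeric(raw$rt_min))
  area <- suppressWarnings(as.numeric(raw$area))
  bad <- which(is.na(rt) | is.na(area))
  if (length(bad))  # +1 for the header line
    stop(sprintf("malformed row at line %d of '%s'", bad[1L] + 1L, path),
         call. = FALSE)
  if (length(unique(raw$batch_id)) > 1L)
    stop(sprintf("'%s' contains multiple batch ids; use read_peak_tables()",
                 path), call. = FALSE)
  neg <- which(area <= 0)
  if (length(neg))
    stop(sprintf("non-positive area at line %d of '%s'", neg[1L] + 1L, path),
         call. = FALSE)
  peak_table(raw$batch_id[1L], rt, area)
}

#' Read peak tables for several batches
#'
#' Accepts either a directory of per-batch CSVs or one long-format CSV whose
#' `batch_id` column distinguishes batches.
#'
#' @param path Directory or CSV file.
#' @return Named list of `peak_table`s, ordered by batch id.
#' @export
read_peak_tables <- function(path) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.csv$", full.names = TRUE))
    if (!length(files)) stop(sprintf("no CSV files in '%s'", path), call. = FALSE)
    tabs <- lapply(files, read_peak_table)
  } else {
    raw <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (nrow(raw) == 0L) stop(sprintf("'%s' is empty", path), call. = FALSE)
    tabs <- lapply(split(raw, raw$batch_id), function(d)
      peak_table(d$batch_id[1L], d$rt_min, d$area))
  }
  names(tabs) <- vapply(tabs, function(t) t$batch_id[1L], character(1L))
  tabs[order(names(tabs))]
}

#' Match peaks across batches into a common-peak matrix
#'
#' Clusters peaks by retention time. Clusters are seeded from the batch with
#' the most peaks; peaks of every other batch are then assigned greedily (in
#' elution order) to the nearest cluster whose consensus RT lies within
#' `rt_tolerance` and which has no member from that batch yet — nearest-RT
#' wins, distance ties go to the earlier-eluting cluster. Unassignable peaks
#' found new clusters. Consensus RTs are refreshed (member mean) after every
#' batch. Clusters represented in every batch become the common peaks,
#' numbered 1..P in elution order.
#'
#' @param tables List of `peak_table`s (>= 1).
#' @param rt_tolerance Maximum |RT - consensus RT| for membership, minutes.
#'   Default 0.5.
#' @param require_all_batches If TRUE (default) keep only clusters present in
#'   every batch; otherwise keep all clusters (missing cells are NA and the
#'   result is a partial matrix, flagged in the object).
#' @return A `common_peak_matrix`: list with `batch_ids`, `peak_ids`,
#'   `consensus_rt` (strictly increasing) and `areas` (batches x peaks).
#' @export
#' @examples
#' t1 <- peak_table("B1", c(10.0, 20.0), c(1, 2))
#' t2 <- peak_table("B2", c(10.1, 20.2), c(3, 4))
#' match_common_peaks(list(t1, t2), rt_tolerance = 0.3)
match_common_peaks <- function(tables, rt_tolerance = 0.5,
                               require_all_batches = TRUE) {
  stopifnot(length(tables) >= 1L)
  if (rt_tolerance < 0) stop_config("rt_tolerance", "must be >= 0")
  for (t in tables) if (!inherits(t, "peak_table"))
    stop("all inputs must be peak_table objects", call. = FALSE)
  ids <- unname(vapply(tables, function(t)
    if (nrow(t)) t$batch_id[1L] else NA_character_, character(1L)))
  if (anyNA(ids)) stop("empty peak table has no batch id", call. = FALSE)
  if (anyDuplicated(ids)) stop("duplicate batch ids", call. = FALSE)
  B <- length(tables)

  seed_b <- which.max(vapply(tables, nrow, integer(1L)))
  # clusters: parallel lists of member RTs/areas/batch indices
  rts <- as.list(tables[[seed_b]]$rt_min)
  areas <- as.list(tables[[seed_b]]$area)
  members <- as.list(rep(seed_b, length(rts)))
  consensus <- unlist(rts, use.names = FALSE)
  if (!length(consensus)) consensus <- numeric()

  for (b in setdiff(seq_len(B), seed_b)) {
    tab <- tables[[b]]
    taken <- rep(FALSE, length(consensus))
    for (i in seq_len(nrow(tab))) {       # elution order
      rt_i <- tab$rt_min[i]
      if (length(consensus)) {
        d <- abs(consensus - rt_i)
        d[taken] <- Inf
        j <- which.min(d)                 # which.min takes the first (earlier RT) on ties
        hit <- is.finite(d[j]) && d[j] <= rt_tolerance
      } else hit <- FALSE
      if (hit) {
        rts[[j]] <- c(rts[[j]], rt_i)
        areas[[j]] <- c(areas[[j]], tab$area[i])
        members[[j]] <- c(members[[j]], b)
        taken[j] <- TRUE
      } else {                            # found a new cluster
        rts <- c(rts, rt_i); areas <- c(areas, tab$area[i])
        members <- c(members, b)
        taken <- c(taken, TRUE)
        consensus <- c(consensus, rt_i)
      }
    }
    consensus <- vapply(rts, mean, numeric(1L))
  }

  # post-refinement tolerance check: members must sit within tolerance of the
  # final consensus; clusters violating it (possible only when clusters
  # overlap at the tolerance scale) are dropped with a warning
  ok <- vapply(seq_along(rts), function(j)
    all(abs(rts[[j]] - consensus[j]) <= rt_tolerance + 1e-12), logical(1L))
  if (!all(ok))
    warning(sprintf("%d overlapping cluster(s) exceeded rt_tolerance and were dropped",
                    sum(!ok)), call. = FALSE)
  keep <- ok
  if (require_all_batches)
    keep <- keep & vapply(members, function(m) length(unique(m)) == B, logical(1L))
  ord <- order(consensus[keep])
  idx <- which(keep)[ord]
  P <- length(idx)

  A <- matrix(NA_real_, nrow = B, ncol = P, dimnames = list(ids, NULL))
  for (k in seq_len(P)) {
    j <- idx[k]
    A[members[[j]], k] <- areas[[j]]
  }
  common_peak_matrix(batch_ids = ids, consensus_rt = consensus[idx], areas = A,
                     complete = require_all_batches)
}

#' Construct a common-peak matrix
#'
#' @param batch_ids Character vector of batch ids.
#' @param consensus_rt Strictly increasing consensus retention times.
#' @param areas Batches x peaks area matrix (positive; no NA when
#'   `complete`).
#' @param complete Whether every cell must be present. Default TRUE.
#' @return A `common_peak_matrix` object.
#' @export
common_peak_matrix <- function(batch_ids, consensus_rt, areas, complete = TRUE) {
  areas <- as.matrix(areas)
  P <- length(consensus_rt)
  stopifnot(nrow(areas) == length(batch_ids), ncol(areas) == P)
  if (P > 1L && is.unsorted(consensus_rt, strictly = TRUE))
    stop("consensus retention times must be strictly increasing", call. = FALSE)
  if (complete && anyNA(areas))
    stop("common-peak matrix has missing cells", call. = FALSE)
  if (any(areas[!is.na(areas)] <= 0))
    stop("peak areas must be positive", call. = FALSE)
  dimnames(areas) <- list(as.character(batch_ids),
                          if (P) paste0("P", seq_len(P)) else NULL)
  structure(list(batch_ids = as.character(batch_ids),
                 peak_ids = seq_len(P),
                 consensus_rt = as.numeric(consensus_rt),
                 areas = areas, complete = complete),
            class = "common_peak_matrix")
}

#' @export
print.common_peak_matrix <- function(x, ...) {
  cat(sprintf("Common-peak matrix: %d batches x %d peaks (RT %.2f-%.2f min)\n",
              length(x$batch_ids), length(x$peak_ids),
              if (length(x$consensus_rt)) min(x$consensus_rt) else NA,
              if (length(x$consensus_rt)) max(x$consensus_rt) else NA))
  invisible(x)
}

#' @export
dim.common_peak_matrix <- function(x) dim(x$areas)

#' Mean relative content per common peak
#'
#' For each batch, peak areas are divided by the batch's total area; the
#' per-peak mean of these shares across batches is returned. Entries sum
#' to 1.
#'
#' @param matrix A complete `common_peak_matrix`.
#' @return Numeric vector, one share per peak.
#' @export
#' @examples
#' m <- common_peak_matrix("B1", c(1, 2), matrix(c(1, 3), 1))
#' relative_content(m)  # 0.25 0.75
relative_content <- function(matrix) {
  stopifnot(inherits(matrix, "common_peak_matrix"))
  A <- matrix$areas
  if (anyNA(A)) stop("relative content needs a complete matrix", call. = FALSE)
  shares <- A / rowSums(A)
  stats::setNames(colMeans(shares), colnames(A))
}

#' Write / read a common-peak matrix
#'
#' The matrix is stored as a wide CSV (batch rows x peak columns, first
#' column `batch_id`) with a JSON sidecar (`<path>.meta.json`) holding the
#' consensus retention times.
#'
#' @param matrix A `common_peak_matrix`.
#' @param path CSV path.
#' @return `write_common_peaks` invisibly returns `path`;
#'   `read_common_peaks` returns the `common_peak_matrix`.
#' @export
write_common_peaks <- function(matrix, path) {
  df <- data.frame(batch_id = matrix$batch_ids, matrix$areas,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(consensus_rt = matrix$consensus_rt),
                       paste0(path, ".meta.json"), digits = NA)
  invisible(path)
}

#' @rdname write_common_peaks
#' @export
read_common_peaks <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  meta <- jsonlite::read_json(paste0(path, ".meta.json"), simplifyVector = TRUE)
  A <- as.matrix(df[, -1L, drop = FALSE])
  common_peak_matrix(df$batch_id, meta$consensus_rt, A)
}

#' @export
as.data.frame.peak_table <- function(x, ...) {
  class(x) <- "data.frame"
  x
}
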