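# Target-cell binding set: the peaks a cell-extraction experiment reports as
# cell-associated. Binding indicates physical association, not activity; the
# screen therefore intersects it with spectrum-effect hits.

#' Construct a binding set
#'
#' @param peak_ids Integer common-peak indices (deduplicated, sorted).
#' @param names Optional component names, same length as `peak_ids`.
#' @return A `binding_set` (sorted integer vector; names attached when
#'   given).
#' @export
#' @examples
#' binding_set(c(4, 2, 2))
binding_set <- function(peak_ids, names = NULL) {
  ids <- sort(unique(as.integer(peak_ids)))
  if (length(ids) && min(ids) < 1L)
    stop("peak ids must be positive integers", call. = FALSE)
  if (!is.null(names)) {
    nm <- as.character(names)[match(ids, as.integer(peak_ids))]
    names(ids) <- nm
  }
  structure(ids, class = "binding_set")
}

#' @export
print.binding_set <- function(x, ...) {
  cat(sprintf("Binding set: %d peak(s): %s\n", length(x),
              paste(unclass(x), collapse = ", ")))
  invisible(x)
}

#' Load a binding set from CSV and validate it against a fingerprint
#'
#' The file must have a `peak_id` column (an optional `name` column carries
#' component names). Every id is checked against the common-peak matrix;
#' unknown ids raise an error listing them. An empty file yields an empty
#' set with a warning.
#'
#' @param path CSV path.
#' @param matrix The `common_peak_matrix` whose peak ids are valid.
#' @return A `binding_set`.
#' @export
load_binding_set <- function(path, matrix) {
  stopifnot(inherits(matrix, "common_peak_matrix"))
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning(sprintf("binding file '%s' is empty", path), call. = FALSE)
    return(binding_set(integer()))
  }
  if (!"peak_id" %in% names(df))
    stop(sprintf("'%s' must have a 'peak_id' column", path), call. = FALSE)
  ids <- as.integer(df$peak_id)
  unknown <- setdiff(ids, matrix$peak_ids)
  if (length(unknown))
    stop(sprintf("binding set names unknown peak id(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  binding_set(ids, names = df[["name"]])
}

#' Intersect spectrum-effect hits with the binding set
#'
#' A peak must both bind the target cells and be a spectrum-effect hit:
#' bound peaks without spectrum support are dropped, as are spectrum hits
#' that never bound.
#'
#' @param spectrum_hits Integer peak ids flagged by GRA/VIP screening.
#' @param binding A `binding_set`.
#' @return Sorted integer vector of peak ids in both sets.
#' @export
#' @examples
#' intersect_hits(c(1, 2, 3), binding_set(c(2, 3, 4)))  # 2 3
intersect_hits <- function(spectrum_hits, binding) {
  sort(intersect(as.integer(spectrum_hits), as.integer(binding)))
}
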