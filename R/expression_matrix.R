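#' Expression matrix container
#'
#' A light wrapper around a numeric matrix that tracks whether rows are
#' probes or genes and whether the values are raw intensities or
#' normalized log2 values. Row and column ids live in the dimnames and
#' must be unique.
#'
#' @param values numeric matrix; rows are probes or genes, columns are
#'   samples. Must have unique, non-missing dimnames.
#' @param level `"probe"` or `"gene"`.
#' @param stage `"raw"` (linear intensities) or `"normalized"` (log2).
#' @return an object of class `expr_matrix`.
#' @export
expr_matrix <- function(values, level = c("probe", "gene"),
                        stage = c("raw", "normalized")) {
  level <- match.arg(level)
  stage <- match.arg(stage)
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("`values` must be a numeric matrix", call. = FALSE)
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("`values` must carry row and column ids in its dimnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(values))) {
    stop("duplicate row ids in expression matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicate column (sample) ids in expression matrix", call. = FALSE)
  }
  if (any(!is.finite(values))) {
    stop("expression values must all be finite", call. = FALSE)
  }
  structure(
    list(values = values, level = level, stage = stage),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf(
    "<expr_matrix> %d %ss x %d samples, stage=%s\n",
    nrow(x$values), x$level, ncol(x$values), x$stage
  ))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Sample metadata validator
#'
#' Checks a metadata table for the two-factor study layout: one row per
#' sample with a tissue label (2 levels expected downstream) and a
#' disease-state label (3 levels expected downstream).
#'
#' @param metadata data.frame with columns `sample_id`, `tissue`, `state`.
#' @param sample_ids optional character vector that `sample_id` must
#'   match (same set, order ignored).
#' @return the metadata with `tissue` and `state` as factors, rows
#'   ordered to `sample_ids` when given.
#' @export
validate_metadata <- function(metadata, sample_ids = NULL) {
  required <- c("sample_id", "tissue", "state")
  missing <- setdiff(required, names(metadata))
  if (length(missing) > 0) {
    stop("metadata lacks column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(metadata$sample_id)) {
    stop("duplicate sample ids in metadata", call. = FALSE)
  }
  if (!is.null(sample_ids)) {
    if (!setequal(metadata$sample_id, sample_ids)) {
      stop("metadata sample ids do not match the expression matrix",
           call. = FALSE)
    }
    metadata <- metadata[match(sample_ids, metadata$sample_id), , drop = FALSE]
  }
  metadata$tissue <- factor(metadata$tissue)
  metadata$state <- factor(metadata$state)
  rownames(metadata) <- NULL
  metadata
}
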