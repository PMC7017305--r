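#' Normalize raw probe intensities
#'
#' The canonical normalization is: threshold intensities to 1, take log2,
#' and baseline every probe to the median of all samples (subtract the
#' per-row median). An optional per-sample percentile shift (e.g. 0.75
#' for a 75th-percentile shift, the usual default of microarray suites)
#' can be applied between the log2 and baselining steps; it is off by
#' default so the three explicit steps are the canonical path. The
#' percentile uses the nearest-rank definition.
#'
#' @param raw raw-stage [expr_matrix()].
#' @param percentile_shift optional fraction in (0, 1]; each column is
#'   shifted so its nearest-rank percentile equals 0.
#' @return a normalized-stage [expr_matrix()] on the log2 scale; every
#'   row has across-sample median 0.
#' @export
normalize_matrix <- function(raw, percentile_shift = NULL) {
  stopifnot(inherits(raw, "expr_matrix"))
  if (raw$stage != "raw") {
    stop("`normalize_matrix()` expects a raw-stage matrix", call. = FALSE)
  }
  v <- log2(pmax(raw$values, 1))
  if (!is.null(percentile_shift)) {
    if (percentile_shift <= 0 || percentile_shift > 1) {
      stop("`percentile_shift` must lie in (0, 1]", call. = FALSE)
    }
    idx <- ceiling(percentile_shift * nrow(v))  # nearest-rank
    shifts <- apply(v, 2, function(col) sort(col)[idx])
    v <- sweep(v, 2, shifts)
  }
  v <- sweep(v, 1, apply(v, 1, stats::median))
  expr_matrix(v, level = raw$level, stage = "normalized")
}

#' Restrict a probe-level matrix to an a-priori gene panel
#'
#' Keeps exactly the probes whose mapped gene belongs to the panel, in
#' stable row order. Probes without a mapping are dropped with a message.
#'
#' @param matrix probe-level [expr_matrix()].
#' @param panel character vector of panel gene ids.
#' @param probe_map data.frame with columns `probe_id`, `gene_id`
#'   (many probes to one gene; each probe mapped at most once).
#' @return the filtered [expr_matrix()].
#' @export
filter_panel <- function(matrix, panel, probe_map) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (matrix$level != "probe") {
    stop("`filter_panel()` expects a probe-level matrix", call. = FALSE)
  }
  if (length(panel) == 0) stop("empty gene panel", call. = FALSE)
  if (anyDuplicated(probe_map$probe_id)) {
    stop("a probe is mapped more than once in the probe map", call. = FALSE)
  }
  gene_of <- stats::setNames(probe_map$gene_id, probe_map$probe_id)
  probes <- rownames(matrix$values)
  unmapped <- probes[!(probes %in% names(gene_of))]
  if (length(unmapped) > 0) {
    message(length(unmapped), " unmapped probe(s) dropped")
  }
  keep <- probes[probes %in% names(gene_of) & gene_of[probes] %in% panel]
  if (length(keep) == 0) {
    unmatched <- setdiff(panel, gene_of[probes])
    stop("no probe maps to the panel; unmatched panel genes: ",
         paste(utils::head(unmatched, 20), collapse = ", "), call. = FALSE)
  }
  expr_matrix(matrix$values[keep, , drop = FALSE],
              level = "probe", stage = matrix$stage)
}

#' Collapse probes to genes by the mean
#'
#' Replaces the probe rows of each gene with their per-sample arithmetic
#' mean, yielding a gene-level matrix for the downstream statistics.
#'
#' @param matrix normalized probe-level [expr_matrix()].
#' @param probe_map data.frame with columns `probe_id`, `gene_id`.
#' @param drop_unmapped if `FALSE` (default) a probe absent from the map
#'   is an error; if `TRUE` such probes are dropped with a message.
#' @return a gene-level [expr_matrix()]; gene rows ordered by first
#'   appearance of their probes.
#' @export
collapse_probes <- function(matrix, probe_map, drop_unmapped = FALSE) {
  stopifnot(inherits(matrix, "expr_matrix"))
  if (matrix$level != "probe") {
    stop("`collapse_probes()` expects a probe-level matrix", call. = FALSE)
  }
  gene_of <- stats::setNames(probe_map$gene_id, probe_map$probe_id)
  probes <- rownames(matrix$values)
  missing <- probes[!(probes %in% names(gene_of))]
  if (length(missing) > 0) {
    if (!drop_unmapped) {
      stop("probe(s) absent from the probe map: ",
           paste(utils::head(missing, 10), collapse = ", "), call. = FALSE)
    }
    message(length(missing), " unmapped probe(s) dropped before collapsing")
    probes <- setdiff(probes, missing)
  }
  genes <- gene_of[probes]
  gene_order <- unique(genes)
  v <- matrix$values[probes, , drop = FALSE]
  collapsed <- rowsum(v, group = genes, reorder = FALSE) /
    as.vector(table(factor(genes, levels = unique(genes))))
  collapsed <- collapsed[gene_order, , drop = FALSE]
  expr_matrix(collapsed, level = "gene", stage = matrix$stage)
}
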