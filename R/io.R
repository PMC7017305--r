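# Readers and writers for the pipeline's plain-text formats. All tables
# are TSV with a header row and stable column order; floating point is
# written with 12 significant digits.

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.12g", x))
}

#' Write a data.frame as TSV
#'
#' @param df data.frame; numeric columns are written with 12 significant
#'   digits.
#' @param path output file.
#' @export
write_tsv_table <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a TSV table
#' @param path input file.
#' @return data.frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Write an expression matrix as TSV (rows = ids, columns = samples)
#' @param matrix an [expr_matrix()].
#' @param path output file.
#' @export
write_expression_tsv <- function(matrix, path) {
  stopifnot(inherits(matrix, "expr_matrix"))
  id_col <- if (matrix$level == "probe") "probe_id" else "gene_id"
  df <- data.frame(rownames(matrix$values), matrix$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  names(df)[1] <- id_col
  write_tsv_table(df, path)
}

#' Read an expression matrix from TSV
#'
#' The first column holds row ids (probes or genes), the remaining
#' columns one sample each. Duplicate row or sample ids are rejected.
#'
#' @param path input file.
#' @param level `"probe"` or `"gene"`.
#' @param stage `"raw"` or `"normalized"`.
#' @return an [expr_matrix()].
#' @export
read_expression_tsv <- function(path, level = "probe", stage = "raw") {
  df <- read_tsv_table(path)
  if (ncol(df) < 2) stop("expression TSV needs an id column and >= 1 sample",
                         call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(names(df)[-1])) {
    stop("duplicated sample id in ", path, call. = FALSE)
  }
  v <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(v) <- "double"
  rownames(v) <- ids
  expr_matrix(v, level = level, stage = stage)
}

#' Read a gene panel (one gene id per line)
#' @param path input file.
#' @return character vector of unique gene ids.
#' @export
read_panel <- function(path) {
  x <- trimws(readLines(path))
  x <- x[x != ""]
  if (length(x) == 0) stop("empty panel file: ", path, call. = FALSE)
  unique(x)
}

#' Write / read a probe-to-gene map (TSV: probe_id, gene_id)
#' @param probe_map data.frame with columns `probe_id`, `gene_id`.
#' @param path file path.
#' @export
write_probe_map_tsv <- function(probe_map, path) {
  write_tsv_table(probe_map[, c("probe_id", "gene_id")], path)
}

#' @rdname write_probe_map_tsv
#' @export
read_probe_map_tsv <- function(path) {
  df <- read_tsv_table(path)
  if (!all(c("probe_id", "gene_id") %in% names(df))) {
    stop("probe map needs columns probe_id, gene_id", call. = FALSE)
  }
  if (anyDuplicated(df$probe_id)) {
    stop("probe mapped more than once in ", path, call. = FALSE)
  }
  df
}

#' Write an annotation set in GMT format
#'
#' One term per line: term id, description, then the member genes, all
#' tab-separated.
#'
#' @param annotations an [annotation_set()].
#' @param path output file.
#' @param descriptions optional named character vector of term
#'   descriptions (defaults to `"na"`).
#' @export
write_gmt <- function(annotations, path, descriptions = NULL) {
  stopifnot(inherits(annotations, "annotation_set"))
  lines <- vapply(names(annotations$sets), function(term) {
    desc <- if (!is.null(descriptions) && term %in% names(descriptions)) {
      descriptions[[term]]
    } else "na"
    paste(c(term, desc, annotations$sets[[term]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' @param path input file.
#' @param universe optional universe; defaults to the union of all
#'   members.
#' @return an [annotation_set()].
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readLines(path)
  sets <- list()
  for (i in seq_along(lines)) {
    if (trimws(lines[i]) == "") next
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("malformed GMT line ", i, " in ", path,
           " (need term, description, >=1 member)", call. = FALSE)
    }
    sets[[fields[1]]] <- fields[-(1:2)]
  }
  if (length(sets) == 0) stop("no gene sets in ", path, call. = FALSE)
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  annotation_set(sets, universe)
}

#' Write / read a scored edge list (TSV: node_a, node_b, score)
#' @param interactome an [interactome()].
#' @param path file path.
#' @export
write_edge_list_tsv <- function(interactome, path) {
  write_tsv_table(interactome[, c("node_a", "node_b", "score")], path)
}

#' @rdname write_edge_list_tsv
#' @export
read_edge_list_tsv <- function(path) {
  df <- read_tsv_table(path)
  if (!all(c("node_a", "node_b", "score") %in% names(df))) {
    stop("edge list needs columns node_a, node_b, score", call. = FALSE)
  }
  loops <- which(df$node_a == df$node_b)
  if (length(loops) > 0) {
    stop("self-loop at line ", loops[1] + 1L, " of ", path, call. = FALSE)
  }
  key <- paste(pmin(df$node_a, df$node_b), pmax(df$node_a, df$node_b))
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop("duplicate edge at line ", dup[1] + 1L, " of ", path, call. = FALSE)
  }
  interactome(df)
}

#' Write a network in GraphML and SIF-style edge-list form
#'
#' @param network an `igraph` graph.
#' @param graphml_path output GraphML file (skipped if `NULL`).
#' @param sif_path output tab-separated `node_a  interaction  node_b`
#'   file (skipped if `NULL`).
#' @export
write_network <- function(network, graphml_path = NULL, sif_path = NULL) {
  if (!is.null(graphml_path)) {
    g <- network
    # GraphML carries numeric/string attributes; coerce the rest
    for (at in igraph::vertex_attr_names(g)) {
      v <- igraph::vertex_attr(g, at)
      if (is.logical(v)) g <- igraph::set_vertex_attr(g, at, value = as.integer(v))
    }
    if ("missing_seeds" %in% igraph::graph_attr_names(g)) {
      g <- igraph::delete_graph_attr(g, "missing_seeds")
    }
    igraph::write_graph(g, graphml_path, format = "graphml")
  }
  if (!is.null(sif_path)) {
    el <- igraph::as_edgelist(network, names = TRUE)
    writeLines(paste(el[, 1], "pp", el[, 2], sep = "\t"), sif_path)
  }
  invisible(network)
}
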