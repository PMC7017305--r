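#' Scored interactome edge table
#'
#' An undirected, scored protein-protein interaction table. Self-loops
#' and duplicate unordered pairs are rejected; scores must be finite.
#'
#' @param edges data.frame with columns `node_a`, `node_b`, `score`.
#' @return an object of class `interactome` (the validated data.frame).
#' @export
interactome <- function(edges) {
  required <- c("node_a", "node_b", "score")
  if (!all(required %in% names(edges))) {
    stop("interactome needs columns node_a, node_b, score", call. = FALSE)
  }
  if (nrow(edges) == 0) stop("empty interactome", call. = FALSE)
  if (any(edges$node_a == edges$node_b)) {
    stop("self-loop(s) at row(s): ",
         paste(utils::head(which(edges$node_a == edges$node_b), 10),
               collapse = ", "), call. = FALSE)
  }
  key <- paste(pmin(edges$node_a, edges$node_b),
               pmax(edges$node_a, edges$node_b))
  if (anyDuplicated(key)) {
    stop("duplicate unordered edge(s) at row(s): ",
         paste(utils::head(which(duplicated(key)), 10), collapse = ", "),
         call. = FALSE)
  }
  if (any(!is.finite(edges$score))) {
    stop("edge scores must be finite", call. = FALSE)
  }
  rownames(edges) <- NULL
  class(edges) <- c("interactome", "data.frame")
  edges
}

#' Keep the top-scoring fraction of interactome edges
#'
#' Retains the `ceiling(top_fraction * m)` edges with the largest
#' absolute score, ties broken by stable input order (`mode = "count"`,
#' the default). `mode = "value"` instead thresholds at the nearest-rank
#' upper quantile of |score|, keeping every edge at or above it. The node
#' set shrinks to the endpoints of the retained edges.
#'
#' @param interactome an [interactome()].
#' @param top_fraction fraction in (0, 1] (default 0.15).
#' @param mode `"count"` or `"value"`.
#' @return the filtered [interactome()], rows in input order.
#' @export
filter_interactome <- function(interactome, top_fraction = 0.15,
                               mode = c("count", "value")) {
  mode <- match.arg(mode)
  stopifnot(inherits(interactome, "interactome"))
  if (top_fraction <= 0 || top_fraction > 1) {
    stop("`top_fraction` must lie in (0, 1]", call. = FALSE)
  }
  m <- nrow(interactome)
  a <- abs(interactome$score)
  if (mode == "count") {
    keep_n <- ceiling(top_fraction * m)
    ord <- order(-a)  # stable: ties stay in input order
    keep <- sort(ord[seq_len(keep_n)])
  } else {
    thr <- sort(a, decreasing = TRUE)[ceiling(top_fraction * m)]
    keep <- which(a >= thr)
  }
  out <- interactome[keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("interactome", "data.frame")
  out
}

#' Build a first-order PPI network from DEG seeds
#'
#' The network's node set is the seeds present in the interactome plus
#' all their direct interaction partners; the edge set is every
#' interactome edge with both endpoints in that node set (the induced
#' subgraph). Duplicate seed entries are averaged by their log2
#' fold-change mean. Seeds absent from the interactome are recorded in
#' the `missing_seeds` attribute.
#'
#' @param seeds data.frame with columns `gene_id`, `log2_fc` (or a
#'   character vector of gene ids, taken with log2_fc = NA).
#' @param interactome an [interactome()].
#' @return an `igraph` graph with vertex attributes `seed` (logical) and
#'   `log2_fc`, edge attribute `score`, and graph attribute
#'   `missing_seeds`.
#' @export
build_first_order_network <- function(seeds, interactome) {
  stopifnot(inherits(interactome, "interactome"))
  if (is.character(seeds)) {
    seeds <- data.frame(gene_id = seeds, log2_fc = NA_real_,
                        stringsAsFactors = FALSE)
  }
  if (nrow(seeds) == 0) stop("empty seed list", call. = FALSE)
  # duplicates filtered using the log2FC mean
  lfc <- tapply(seeds$log2_fc, seeds$gene_id, mean)
  seed_ids <- names(lfc)

  g_full <- igraph::graph_from_data_frame(
    interactome[, c("node_a", "node_b", "score")], directed = FALSE)
  present <- intersect(seed_ids, igraph::V(g_full)$name)
  missing <- setdiff(seed_ids, present)
  if (length(present) == 0) {
    stop("no seed maps into the interactome (", length(missing),
         " seed(s) unmatched)", call. = FALSE)
  }
  nbrs <- igraph::V(g_full)$name[unlist(igraph::adjacent_vertices(g_full, present))]
  nodes <- union(present, unique(nbrs))
  g <- igraph::induced_subgraph(g_full, nodes)
  igraph::V(g)$seed <- igraph::V(g)$name %in% present
  igraph::V(g)$log2_fc <- unname(lfc[match(igraph::V(g)$name, seed_ids)])
  g <- igraph::set_graph_attr(g, "missing_seeds", missing)
  g
}

#' Betweenness centrality
#'
#' Unnormalized, unweighted betweenness on the undirected network:
#' for node v, the sum over unordered pairs (s, t), s != v != t, of the
#' fraction of shortest s-t paths passing through v. Disconnected pairs
#' contribute zero. Edge scores are ignored (they only drive filtering).
#'
#' @param network an `igraph` graph.
#' @return named numeric vector, node -> betweenness.
#' @export
node_betweenness <- function(network) {
  if (igraph::vcount(network) == 0) stop("empty network", call. = FALSE)
  igraph::betweenness(network, directed = FALSE, weights = NA,
                      normalized = FALSE)
}

#' Classify hub-bottleneck and nonhub-bottleneck nodes
#'
#' The degree cutoff is `mean + 2 * SD` of the network's degree
#' distribution (population SD by default: the node set is the whole
#' population). A node is a `hub_bottleneck` when its degree is at or
#' above the cutoff. A node is a `nonhub_bottleneck` when its degree is
#' below the cutoff, its betweenness is positive and lies in the top 50%
#' of the betweenness distribution (descending rank <= ceiling(N/2)), and
#' it is directly connected to at least two hub-bottlenecks. Everything
#' else is `other`.
#'
#' @param network an `igraph` graph (typically from
#'   [build_first_order_network()]).
#' @param sd_sample use the sample SD (denominator N-1) instead of the
#'   population SD for the degree cutoff.
#' @return data.frame with one row per node: `node_id`, `degree`,
#'   `betweenness`, `class`, `degree_cutoff`, `log2_fc` (NA for nodes
#'   without an expression value), `seed`.
#' @export
classify_topology <- function(network, sd_sample = FALSE) {
  n <- igraph::vcount(network)
  if (n == 0) stop("empty network", call. = FALSE)
  deg <- igraph::degree(network)
  btw <- node_betweenness(network)
  if (n == 1) {
    warning("single-node network: no topology classes assignable")
    cutoff <- NA_real_
    cls <- "other"
  } else {
    sdv <- stats::sd(deg)
    if (!sd_sample) sdv <- sdv * sqrt((n - 1) / n)
    cutoff <- mean(deg) + 2 * sdv
    is_hub <- deg >= cutoff
    hub_nbrs <- vapply(seq_len(n), function(v) {
      sum(is_hub[igraph::neighbors(network, v)])
    }, numeric(1))
    top_half <- rank(-btw, ties.method = "min") <= ceiling(n / 2)
    is_nonhub <- !is_hub & btw > 0 & top_half & hub_nbrs >= 2
    cls <- ifelse(is_hub, "hub_bottleneck",
                  ifelse(is_nonhub, "nonhub_bottleneck", "other"))
  }
  lfc <- if ("log2_fc" %in% igraph::vertex_attr_names(network)) {
    igraph::V(network)$log2_fc
  } else NA_real_
  seed <- if ("seed" %in% igraph::vertex_attr_names(network)) {
    igraph::V(network)$seed
  } else NA
  data.frame(node_id = igraph::V(network)$name, degree = unname(deg),
             betweenness = unname(btw), class = cls,
             degree_cutoff = cutoff, log2_fc = lfc, seed = seed,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Compare topology classifications between two conditions
#'
#' For each topology class, reports the nodes shared between, or specific
#' to, two classification outputs (e.g. the two disease subtypes), with
#' each node's per-condition log2 fold change and a concordance flag
#' (FALSE marks an opposite expression trend).
#'
#' @param records_a,records_b outputs of [classify_topology()].
#' @param classes classes to compare.
#' @return named list (one element per class) of data.frames with
#'   columns `node_id`, `in_a`, `in_b`, `log2_fc_a`, `log2_fc_b`,
#'   `concordant`.
#' @export
compare_clusters <- function(records_a, records_b,
                             classes = c("hub_bottleneck", "nonhub_bottleneck")) {
  out <- lapply(classes, function(cl) {
    a <- records_a[records_a$class == cl, ]
    b <- records_b[records_b$class == cl, ]
    nodes <- union(a$node_id, b$node_id)
    if (length(nodes) == 0) {
      return(data.frame(node_id = character(), in_a = logical(),
                        in_b = logical(), log2_fc_a = numeric(),
                        log2_fc_b = numeric(), concordant = logical(),
                        stringsAsFactors = FALSE))
    }
    lfc_a <- records_a$log2_fc[match(nodes, records_a$node_id)]
    lfc_b <- records_b$log2_fc[match(nodes, records_b$node_id)]
    concord <- ifelse(is.na(lfc_a) | is.na(lfc_b), NA,
                      sign(lfc_a) == sign(lfc_b))
    data.frame(node_id = nodes, in_a = nodes %in% a$node_id,
               in_b = nodes %in% b$node_id,
               log2_fc_a = lfc_a, log2_fc_b = lfc_b,
               concordant = concord, stringsAsFactors = FALSE)
  })
  names(out) <- classes
  out
}
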