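#' Annotation set container
#'
#' Named gene sets (e.g. GO cellular-component terms) over a gene
#' universe. Every member must belong to the universe and term ids must
#' be unique.
#'
#' @param sets named list of character vectors.
#' @param universe character vector of gene ids.
#' @return an object of class `annotation_set`.
#' @export
annotation_set <- function(sets, universe) {
  if (length(universe) == 0) stop("empty universe", call. = FALSE)
  if (anyDuplicated(universe)) stop("duplicate genes in universe", call. = FALSE)
  nm <- names(sets)
  if (is.null(nm) || anyDuplicated(nm) || any(nm == "")) {
    stop("term ids must be unique and non-empty", call. = FALSE)
  }
  sets <- lapply(sets, unique)
  stray <- setdiff(unlist(sets, use.names = FALSE), universe)
  if (length(stray) > 0) {
    stop("term member(s) outside the universe: ",
         paste(utils::head(stray, 10), collapse = ", "), call. = FALSE)
  }
  structure(list(sets = sets, universe = universe), class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d terms over %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

# Upper tail P(X >= k) of the hypergeometric: k successes drawn in a list
# of size n from a universe of N genes containing K term members.
hypergeom_tail <- function(k, K, n, N) {
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Gene-set overrepresentation by Fisher's exact test
#'
#' One-sided (greater) overrepresentation of a gene list against each
#' annotation term: `p = P(overlap >= k)` under the hypergeometric null,
#' with Bonferroni correction over the tested terms. Terms empty in the
#' universe are skipped and excluded from the correction. List genes
#' outside the universe are dropped with a warning. If per-gene log2 fold
#' changes are supplied, each term gets a direction summary: `up`/`down`
#' when more than half of the overlapping genes share that sign, `mixed`
#' otherwise.
#'
#' @param deg_list character vector of genes (the DEG list).
#' @param annotations an [annotation_set()]; its universe is the
#'   reference (by default the filtered array gene list).
#' @param deg_directions optional named numeric vector of log2 fold
#'   changes for the list genes.
#' @return data.frame sorted by p: `term_id`, `k`, `K`, `n`, `N`,
#'   `fold_enrichment`, `p`, `p_bonferroni`, `direction`.
#' @export
fisher_overrepresentation <- function(deg_list, annotations,
                                      deg_directions = NULL) {
  stopifnot(inherits(annotations, "annotation_set"))
  universe <- annotations$universe
  if (length(deg_list) == 0) stop("empty gene list", call. = FALSE)
  deg_list <- unique(deg_list)
  outside <- setdiff(deg_list, universe)
  if (length(outside) > 0) {
    warning(length(outside), " list gene(s) outside the universe dropped")
    deg_list <- intersect(deg_list, universe)
  }
  if (length(deg_list) == 0) stop("no list gene maps to the universe", call. = FALSE)

  N <- length(universe)
  n <- length(deg_list)
  keep <- vapply(annotations$sets, function(s) length(intersect(s, universe)) > 0,
                 logical(1))
  sets <- annotations$sets[keep]
  m <- length(sets)
  if (m == 0) stop("no annotation term overlaps the universe", call. = FALSE)

  rows <- lapply(names(sets), function(term) {
    members <- intersect(sets[[term]], universe)
    K <- length(members)
    overlap <- intersect(deg_list, members)
    k <- length(overlap)
    p <- hypergeom_tail(k, K, n, N)
    direction <- NA_character_
    if (!is.null(deg_directions) && k > 0) {
      s <- sign(deg_directions[overlap])
      s <- s[!is.na(s)]
      direction <- if (length(s) > 0 && mean(s > 0) > 0.5) "up"
        else if (length(s) > 0 && mean(s < 0) > 0.5) "down"
        else "mixed"
    }
    data.frame(term_id = term, k = k, K = K, n = n, N = N,
               fold_enrichment = (k / n) / (K / N),
               p = p, direction = direction,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_bonferroni <- pmin(1, res$p * m)
  res <- res[order(res$p, res$term_id), ]
  rownames(res) <- NULL
  res[, c("term_id", "k", "K", "n", "N", "fold_enrichment",
          "p", "p_bonferroni", "direction")]
}
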