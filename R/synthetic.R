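#' Planted differential-expression effect
#'
#' Describes a known shift, on the log2 scale, applied to one gene's cell
#' means in the tissue-by-state factorial design. The shift pattern must
#' be consistent with the declared kind: a tissue main effect varies only
#' across tissues, a state main effect only across states, and an
#' interaction leaves a nonzero residual after removing both main
#' effects.
#'
#' @param gene_id integer gene index (1-based, < n_genes of the design).
#' @param effect_kind one of `"tissue_main"`, `"state_main"`,
#'   `"interaction"`.
#' @param cell_shift_log2 numeric matrix of log2 shifts with tissues as
#'   rows and states as columns (dimnames required).
#' @return an object of class `planted_effect`.
#' @export
planted_effect <- function(gene_id,
                           effect_kind = c("tissue_main", "state_main", "interaction"),
                           cell_shift_log2) {
  effect_kind <- match.arg(effect_kind)
  m <- cell_shift_log2
  if (!is.matrix(m) || is.null(rownames(m)) || is.null(colnames(m))) {
    stop("`cell_shift_log2` must be a matrix with tissue rownames and state colnames",
         call. = FALSE)
  }
  if (all(abs(m) < 1e-12)) {
    stop("a planted effect needs at least one nonzero cell shift", call. = FALSE)
  }
  tol <- 1e-9
  row_var <- max(abs(sweep(m, 1, rowMeans(m))))   # within-tissue variation
  col_var <- max(abs(sweep(m, 2, colMeans(m))))   # within-state variation
  resid <- m - outer(rowMeans(m), colMeans(m), "+") + mean(m)
  switch(effect_kind,
    tissue_main = if (row_var > tol)
      stop("tissue_main shifts must depend only on tissue", call. = FALSE),
    state_main = if (col_var > tol)
      stop("state_main shifts must depend only on state", call. = FALSE),
    interaction = if (max(abs(resid)) < tol)
      stop("interaction shifts must leave a nonzero non-additive residual",
           call. = FALSE)
  )
  structure(
    list(gene_id = as.integer(gene_id), effect_kind = effect_kind,
         cell_shift_log2 = m),
    class = "planted_effect"
  )
}

#' Factorial simulation design
#'
#' Specifies a two-factor (tissue x disease state) expression simulation
#' with planted effects. The default group sizes reproduce the study
#' layout: 18/13/10 SALS1/SALS2/CTRL motor-cortex samples and 17/13/10
#' spinal-cord samples.
#'
#' @param n_genes number of genes.
#' @param probes_per_gene scalar or length-`n_genes` integer vector.
#' @param group_sizes data.frame with columns `tissue`, `state`, `n`
#'   covering the full factorial grid.
#' @param baseline_log2_mean baseline log2 intensity (default 7, a
#'   mid-range microarray signal).
#' @param noise_sd_log2 per-probe Gaussian noise SD on the log2 scale
#'   (default 0.5, typical microarray residual spread).
#' @param planted_effects list of [planted_effect()] objects.
#' @param seed integer seed; all randomness flows from it.
#' @return an object of class `design_spec`.
#' @export
design_spec <- function(n_genes,
                        probes_per_gene = 2L,
                        group_sizes = default_group_sizes(),
                        baseline_log2_mean = 7,
                        noise_sd_log2 = 0.5,
                        planted_effects = list(),
                        seed = 1L) {
  stopifnot(n_genes >= 1)
  if (length(probes_per_gene) == 1L) {
    probes_per_gene <- rep(as.integer(probes_per_gene), n_genes)
  }
  if (length(probes_per_gene) != n_genes || any(probes_per_gene < 1)) {
    stop("`probes_per_gene` must be a positive scalar or one positive count per gene",
         call. = FALSE)
  }
  if (!all(c("tissue", "state", "n") %in% names(group_sizes))) {
    stop("`group_sizes` needs columns tissue, state, n", call. = FALSE)
  }
  tissues <- unique(as.character(group_sizes$tissue))
  states <- unique(as.character(group_sizes$state))
  full <- expand.grid(tissue = tissues, state = states, stringsAsFactors = FALSE)
  key <- paste(group_sizes$tissue, group_sizes$state)
  if (anyDuplicated(key) || !all(paste(full$tissue, full$state) %in% key)) {
    stop("`group_sizes` must cover the full factorial grid exactly once",
         call. = FALSE)
  }
  if (any(group_sizes$n < 1)) {
    stop("every factorial cell needs at least one sample", call. = FALSE)
  }
  if (!is.numeric(noise_sd_log2) || noise_sd_log2 <= 0) {
    stop("`noise_sd_log2` must be positive", call. = FALSE)
  }
  for (eff in planted_effects) {
    if (!inherits(eff, "planted_effect")) {
      stop("`planted_effects` must be a list of planted_effect objects",
           call. = FALSE)
    }
    if (eff$gene_id < 1 || eff$gene_id > n_genes) {
      stop("planted gene id ", eff$gene_id, " outside 1..n_genes", call. = FALSE)
    }
    if (!setequal(rownames(eff$cell_shift_log2), tissues) ||
        !setequal(colnames(eff$cell_shift_log2), states)) {
      stop("planted effect for gene ", eff$gene_id,
           " does not match the design's tissue/state levels", call. = FALSE)
    }
  }
  structure(
    list(n_genes = as.integer(n_genes),
         probes_per_gene = probes_per_gene,
         group_sizes = group_sizes,
         baseline_log2_mean = baseline_log2_mean,
         noise_sd_log2 = noise_sd_log2,
         planted_effects = planted_effects,
         seed = as.integer(seed)),
    class = "design_spec"
  )
}

#' Study group sizes
#'
#' The unbalanced 2x3 factorial layout of the study cohort: 18/13/10
#' SALS1/SALS2/CTRL motor-cortex samples and 17/13/10 spinal-cord samples
#' (41 + 40 arrays).
#'
#' @return data.frame with columns `tissue`, `state`, `n`.
#' @export
default_group_sizes <- function() {
  data.frame(
    tissue = rep(c("motor_cortex", "spinal_cord"), each = 3),
    state = rep(c("SALS1", "SALS2", "CTRL"), 2),
    n = c(18L, 13L, 10L, 17L, 13L, 10L),
    stringsAsFactors = FALSE
  )
}

# Sum a gene's planted shifts into one tissue-x-state matrix (zeros if none).
total_shift_matrix <- function(spec, gene_id, tissues, states) {
  m <- matrix(0, length(tissues), length(states),
              dimnames = list(tissues, states))
  for (eff in spec$planted_effects) {
    if (eff$gene_id == gene_id) {
      m <- m + eff$cell_shift_log2[tissues, states, drop = FALSE]
    }
  }
  m
}

#' Simulate a factorial expression dataset with known truth
#'
#' Draws probe-level linear intensities `2^(cell mean + noise)` under the
#' design, with each gene's probes sharing the gene's cell means plus
#' independent Gaussian log2 noise, so collapsing probes by their mean is
#' the correct estimator. Identical seeds give bit-identical output.
#'
#' @param spec a [design_spec()].
#' @return list of class `synthetic_expression` with elements
#'   `expression` (raw-stage [expr_matrix()]), `metadata` (sample_id,
#'   tissue, state), `probe_map` (probe_id, gene_id) and `truth` (per-gene
#'   DE flags and expected log2 fold change for each study contrast).
#' @export
simulate_expression <- function(spec) {
  stopifnot(inherits(spec, "design_spec"))
  gs <- spec$group_sizes
  tissues <- unique(as.character(gs$tissue))
  states <- unique(as.character(gs$state))

  meta <- do.call(rbind, lapply(seq_len(nrow(gs)), function(i) {
    data.frame(
      sample_id = sprintf("%s_%s_%02d", gs$tissue[i], gs$state[i],
                          seq_len(gs$n[i])),
      tissue = gs$tissue[i], state = gs$state[i],
      stringsAsFactors = FALSE
    )
  }))

  gene_ids <- sprintf("G%04d", seq_len(spec$n_genes))
  probe_gene <- rep(seq_len(spec$n_genes), spec$probes_per_gene)
  probe_ids <- sprintf("P%05d", seq_along(probe_gene))
  probe_map <- data.frame(probe_id = probe_ids,
                          gene_id = gene_ids[probe_gene],
                          stringsAsFactors = FALSE)

  shift <- lapply(seq_len(spec$n_genes), function(g) {
    total_shift_matrix(spec, g, tissues, states)
  })

  n_samples <- nrow(meta)
  cell_idx <- cbind(match(meta$tissue, tissues), match(meta$state, states))
  values <- withr::with_seed(spec$seed, {
    log2_mean <- vapply(seq_along(probe_gene), function(p) {
      spec$baseline_log2_mean + shift[[probe_gene[p]]][cell_idx]
    }, numeric(n_samples))
    noise <- matrix(stats::rnorm(length(log2_mean), 0, spec$noise_sd_log2),
                    nrow = n_samples)
    t(2^(log2_mean + noise))
  })
  dimnames(values) <- list(probe_ids, meta$sample_id)

  truth <- truth_table(spec, gene_ids, shift)

  structure(
    list(expression = expr_matrix(values, level = "probe", stage = "raw"),
         metadata = meta, probe_map = probe_map, truth = truth),
    class = "synthetic_expression"
  )
}

# Derive per-gene DE flags and expected contrast log2FCs from the planted
# shift matrices: flags follow the additive decomposition of the summed
# shifts, so unplanted genes are all-false by construction.
truth_table <- function(spec, gene_ids, shift) {
  tol <- 1e-12
  contrasts <- study_contrasts()
  flags <- t(vapply(shift, function(m) {
    rm_ <- rowMeans(m); cm <- colMeans(m)
    resid <- m - outer(rm_, cm, "+") + mean(m)
    c(tissue = diff(range(rm_)) > tol,
      state = diff(range(cm)) > tol,
      interaction = max(abs(resid)) > tol)
  }, logical(3)))
  truth <- data.frame(
    gene_id = gene_ids,
    is_tissue_de = flags[, "tissue"],
    is_state_de = flags[, "state"],
    is_interaction_de = flags[, "interaction"],
    stringsAsFactors = FALSE
  )
  for (i in seq_len(nrow(contrasts))) {
    cc <- contrasts[i, ]
    truth[[paste0("lfc_", cc$contrast_id)]] <- vapply(shift, function(m) {
      m[cc$tissue_a, cc$state_a] - m[cc$tissue_b, cc$state_b]
    }, numeric(1))
  }
  truth
}

#' Simulate a scored scale-free interactome
#'
#' Grows a connected undirected graph by preferential attachment, then
#' adds extra attachments to any planted hub until its degree reaches the
#' hub cutoff (mean + 2 SD of the degree distribution), and draws an
#' i.i.d. tissue-specific score for every edge.
#'
#' @param n_nodes number of nodes (> `edges_per_new_node`).
#' @param edges_per_new_node edges attached by each arriving node (>= 1).
#' @param planted_hubs character vector of node names (or integer
#'   indices) forced to be hub-bottlenecks.
#' @param node_names optional node names (default `N0001`, ...).
#' @param score_fun function of one integer `m` returning `m` edge
#'   scores; default standard normal.
#' @param seed integer seed.
#' @return an [interactome()] edge table.
#' @export
simulate_interactome <- function(n_nodes, edges_per_new_node = 2L,
                                 planted_hubs = character(),
                                 node_names = NULL,
                                 score_fun = function(m) stats::rnorm(m),
                                 seed = 1L) {
  if (n_nodes <= edges_per_new_node || edges_per_new_node < 1) {
    stop("need n_nodes > edges_per_new_node >= 1", call. = FALSE)
  }
  if (is.null(node_names)) node_names <- sprintf("N%04d", seq_len(n_nodes))
  stopifnot(length(node_names) == n_nodes, !anyDuplicated(node_names))
  if (is.numeric(planted_hubs)) {
    if (any(planted_hubs < 1 | planted_hubs > n_nodes)) {
      stop("planted hub index out of range", call. = FALSE)
    }
    planted_hubs <- node_names[planted_hubs]
  }
  if (!all(planted_hubs %in% node_names)) {
    stop("planted hub name not among node names", call. = FALSE)
  }

  withr::with_seed(seed, {
    g <- igraph::sample_pa(n_nodes, m = edges_per_new_node, directed = FALSE)
    igraph::V(g)$name <- node_names
    # raise each planted hub above the mean + 2 SD degree cutoff; the
    # cutoff is recomputed after every added edge since it moves too
    repeat {
      deg <- igraph::degree(g)
      cutoff <- mean(deg) + 2 * stats::sd(deg) * sqrt((length(deg) - 1) / length(deg))
      low <- planted_hubs[deg[planted_hubs] < cutoff]
      if (length(low) == 0) break
      h <- low[[1]]
      nbrs <- names(igraph::neighbors(g, h))
      cand <- setdiff(node_names, c(nbrs, h))
      if (length(cand) == 0) break  # hub saturated; cannot raise further
      g <- igraph::add_edges(g, c(h, sample(cand, 1)))
    }
    el <- igraph::as_edgelist(g, names = TRUE)
    interactome(data.frame(node_a = el[, 1], node_b = el[, 2],
                           score = score_fun(nrow(el)),
                           stringsAsFactors = FALSE))
  })
}

#' Simulate an annotation set with one planted term
#'
#' Builds `n_terms` gene sets over a universe; background terms are
#' uniform random subsets, and the optional planted term keeps exactly
#' the members given.
#'
#' @param universe character vector of gene ids.
#' @param n_terms total number of terms (planted one included).
#' @param planted_term optional `list(term_id = , genes = )`; members must
#'   lie in the universe.
#' @param term_size_range integer range for background term sizes,
#'   truncated at the universe size.
#' @param seed integer seed.
#' @return an [annotation_set()].
#' @export
simulate_annotations <- function(universe, n_terms, planted_term = NULL,
                                 term_size_range = c(5L, 50L), seed = 1L) {
  stopifnot(n_terms >= 1, length(universe) >= 1)
  sets <- list()
  if (!is.null(planted_term)) {
    if (!all(planted_term$genes %in% universe)) {
      stop("planted term member outside the universe", call. = FALSE)
    }
    sets[[planted_term$term_id]] <- planted_term$genes
  }
  n_bg <- n_terms - length(sets)
  lo <- min(term_size_range[1], length(universe))
  hi <- min(term_size_range[2], length(universe))
  withr::with_seed(seed, {
    for (i in seq_len(n_bg)) {
      size <- if (lo == hi) lo else sample(lo:hi, 1)
      sets[[sprintf("T%03d", i)]] <- sort(sample(universe, size))
    }
  })
  annotation_set(sets, universe)
}
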