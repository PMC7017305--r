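#' Bundle a complete synthetic study
#'
#' Generates everything the pipeline consumes, with known planted
#' structure: a factorial expression dataset whose first `n_planted`
#' genes carry a disease-state shift of `effect_log2` (alternating sign)
#' in both SALS subtypes against control; a gene panel equal to the
#' simulated universe; an annotation set whose planted term contains
#' `planted_term_fraction` of the planted genes; and a scale-free scored
#' interactome over the gene namespace with `n_planted_hubs` of the
#' planted genes forced above the hub degree cutoff.
#'
#' @param n_genes number of genes.
#' @param n_planted number of genes with a planted state effect.
#' @param effect_log2 |log2 fold change| of the planted state effect
#'   (default 2, i.e. 4-fold).
#' @param probes_per_gene probes per gene.
#' @param noise_sd_log2 log2 noise SD.
#' @param group_sizes factorial layout (default: the study's Table-1
#'   sizes).
#' @param n_terms annotation terms (planted one included).
#' @param planted_term_fraction fraction of planted genes in the planted
#'   term.
#' @param interactome_nodes interactome size (<= `n_genes`; nodes share
#'   the gene namespace).
#' @param edges_per_new_node preferential-attachment parameter.
#' @param n_planted_hubs planted hubs, chosen among the planted genes.
#' @param seed master seed; stage seeds are derived from it.
#' @return list of class `synthetic_study`: `data` (the
#'   [simulate_expression()] bundle), `panel`, `annotations`,
#'   `interactome`, and `planted` (gene ids, term id, hub ids).
#' @export
synthetic_study <- function(n_genes = 300, n_planted = 30, effect_log2 = 2,
                            probes_per_gene = 2, noise_sd_log2 = 0.5,
                            group_sizes = default_group_sizes(),
                            n_terms = 20, planted_term_fraction = 0.8,
                            interactome_nodes = 250, edges_per_new_node = 2,
                            n_planted_hubs = 3, seed = 1L) {
  stopifnot(n_planted <= n_genes, interactome_nodes <= n_genes,
            n_planted_hubs <= n_planted)
  tissues <- unique(as.character(group_sizes$tissue))
  states <- unique(as.character(group_sizes$state))
  effects <- lapply(seq_len(n_planted), function(i) {
    shift <- matrix(0, length(tissues), length(states),
                    dimnames = list(tissues, states))
    s <- if (i %% 2 == 0) -effect_log2 else effect_log2
    shift[, c("SALS1", "SALS2")] <- s
    planted_effect(i, "state_main", shift)
  })
  spec <- design_spec(
    n_genes = n_genes, probes_per_gene = probes_per_gene,
    group_sizes = group_sizes, noise_sd_log2 = noise_sd_log2,
    planted_effects = effects, seed = seed
  )
  data <- simulate_expression(spec)
  gene_ids <- data$truth$gene_id
  planted_genes <- gene_ids[seq_len(n_planted)]

  n_term_members <- round(planted_term_fraction * n_planted)
  planted_term <- if (n_term_members >= 1) {
    list(term_id = "PLANTED", genes = planted_genes[seq_len(n_term_members)])
  } else NULL
  annotations <- simulate_annotations(
    universe = gene_ids, n_terms = n_terms, planted_term = planted_term,
    seed = seed + 1L
  )

  hub_ids <- planted_genes[seq_len(n_planted_hubs)]
  inter <- simulate_interactome(
    n_nodes = interactome_nodes, edges_per_new_node = edges_per_new_node,
    planted_hubs = hub_ids, node_names = gene_ids[seq_len(interactome_nodes)],
    seed = seed + 2L
  )

  structure(
    list(data = data, panel = gene_ids, annotations = annotations,
         interactome = inter,
         planted = list(genes = planted_genes,
                        term_id = if (is.null(planted_term)) NA_character_
                                  else planted_term$term_id,
                        hubs = hub_ids)),
    class = "synthetic_study"
  )
}

#' Pipeline configuration
#'
#' One flat configuration drives the whole run. Exactly one of `inputs`
#' (paths to real data files) or `synthetic` (arguments for
#' [synthetic_study()]) must be given.
#'
#' @param inputs optional named list of paths: `expression`, `metadata`,
#'   `probe_map`, `panel`, `gmt`, `edge_list`.
#' @param synthetic optional named list of [synthetic_study()] arguments.
#' @param alpha adjusted-p threshold.
#' @param fc_cut linear fold-change threshold.
#' @param top_fraction interactome edge-filter fraction.
#' @param ss_type ANOVA sums-of-squares type.
#' @param gating DEG gating rule.
#' @param sd_sample use sample SD for the hub cutoff.
#' @param percentile_shift optional per-sample percentile shift for
#'   normalization.
#' @param network_contrasts contrast ids to build networks for (default:
#'   the four disease-state contrasts).
#' @param seed master seed.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(inputs = NULL, synthetic = NULL,
                            alpha = 0.05, fc_cut = 2.0, top_fraction = 0.15,
                            ss_type = "III", gating = "effect",
                            sd_sample = FALSE, percentile_shift = NULL,
                            network_contrasts = NULL, seed = 1L) {
  if (is.null(inputs) == is.null(synthetic)) {
    stop("exactly one of `inputs` or `synthetic` must be given", call. = FALSE)
  }
  if (!is.null(inputs)) {
    required <- c("expression", "metadata", "probe_map", "panel")
    missing <- setdiff(required, names(inputs))
    if (length(missing) > 0) {
      stop("config `inputs` lacks field(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
  }
  stopifnot(alpha > 0, alpha < 1, fc_cut >= 1,
            top_fraction > 0, top_fraction <= 1)
  if (is.null(network_contrasts)) {
    sc <- study_contrasts()
    network_contrasts <- sc$contrast_id[sc$type == "state"]
  }
  structure(
    list(inputs = inputs, synthetic = synthetic, alpha = alpha,
         fc_cut = fc_cut, top_fraction = top_fraction, ss_type = ss_type,
         gating = gating, sd_sample = sd_sample,
         percentile_shift = percentile_shift,
         network_contrasts = network_contrasts, seed = as.integer(seed)),
    class = "pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#' @param path YAML file with the fields of [pipeline_config()].
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  do.call(pipeline_config, yaml::read_yaml(path))
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data acquisition (synthetic or from files),
#' normalization, panel filtering, probe collapsing, per-gene two-way
#' ANOVA with BH correction, fold-change screening over the study
#' contrasts, DEG selection, Venn partitioning, gene-set
#' overrepresentation per contrast, and first-order network construction
#' with hub/nonhub-bottleneck classification per configured contrast,
#' plus a cross-subtype comparison of topology classes. All result
#' tables and a run manifest are written under `out_dir`; a failing
#' stage aborts with the stage named and leaves a `FAILED` marker.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return invisibly, a list with all in-memory results.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()
  stage <- "init"
  on_fail <- function(e) {
    writeLines(paste("stage:", stage, "-", conditionMessage(e)),
               file.path(out_dir, "FAILED"))
    stop("pipeline failed at stage `", stage, "`: ", conditionMessage(e),
         call. = FALSE)
  }
  res <- tryCatch({
    stage <- "acquire"
    if (!is.null(config$synthetic)) {
      args <- config$synthetic
      if (is.null(args$seed)) args$seed <- config$seed
      study <- do.call(synthetic_study, args)
      raw <- study$data$expression
      metadata <- study$data$metadata
      probe_map <- study$data$probe_map
      panel <- study$panel
      annotations <- study$annotations
      inter <- study$interactome
      write_tsv_table(study$data$truth, file.path(out_dir, "truth.tsv"))
    } else {
      study <- NULL
      raw <- read_expression_tsv(config$inputs$expression)
      metadata <- read_tsv_table(config$inputs$metadata)
      probe_map <- read_probe_map_tsv(config$inputs$probe_map)
      panel <- read_panel(config$inputs$panel)
      annotations <- if (!is.null(config$inputs$gmt)) {
        read_gmt(config$inputs$gmt)
      } else NULL
      inter <- if (!is.null(config$inputs$edge_list)) {
        read_edge_list_tsv(config$inputs$edge_list)
      } else NULL
    }
    counts$samples <- ncol(raw$values)
    counts$probes_raw <- nrow(raw$values)

    stage <- "normalize"
    norm <- normalize_matrix(raw, percentile_shift = config$percentile_shift)
    write_expression_tsv(norm, file.path(out_dir, "normalized_matrix.tsv"))

    stage <- "panel_filter"
    filtered <- filter_panel(norm, panel, probe_map)
    counts$probes_panel <- nrow(filtered$values)

    stage <- "collapse"
    genes <- collapse_probes(filtered, probe_map)
    counts$genes <- nrow(genes$values)

    stage <- "anova"
    anova <- two_way_anova(genes, metadata, ss_type = config$ss_type)
    write_tsv_table(anova, file.path(out_dir, "anova.tsv"))

    stage <- "fold_changes"
    pw <- pairwise_fold_changes(genes, metadata)

    stage <- "select_degs"
    sel <- select_degs(anova, pw, alpha = config$alpha,
                       fc_cut = config$fc_cut, gating = config$gating)
    write_tsv_table(sel$records, file.path(out_dir, "pairwise.tsv"))
    for (cid in names(sel$degs)) {
      d <- sel$records[sel$records$contrast_id == cid &
                         sel$records$passes_threshold, ]
      write_tsv_table(d[, c("gene_id", "log2_fc", "direction")],
                      file.path(out_dir, paste0("degs_", cid, ".tsv")))
    }
    counts$degs <- vapply(sel$degs, length, integer(1))
    if (all(counts$degs == 0)) {
      warning("no DEG passed the thresholds in any contrast")
    }

    stage <- "venn"
    effect_sets <- list(
      state = anova$gene_id[anova$q_state < config$alpha],
      tissue = anova$gene_id[anova$q_tissue < config$alpha],
      interaction = anova$gene_id[anova$q_interaction < config$alpha]
    )
    venn_effects <- venn_partition(effect_sets)
    write_tsv_table(venn_effects$regions, file.path(out_dir, "venn_effects.tsv"))
    state_ids <- study_contrasts()$contrast_id[study_contrasts()$type == "state"]
    venn_degs <- venn_partition(sel$degs[state_ids])
    write_tsv_table(venn_degs$regions, file.path(out_dir, "venn_degs.tsv"))

    stage <- "enrichment"
    enrich <- list()
    if (!is.null(annotations)) {
      for (cid in names(sel$degs)) {
        deg <- sel$degs[[cid]]
        if (length(deg) == 0) next
        lfc <- sel$records$log2_fc[sel$records$contrast_id == cid]
        names(lfc) <- sel$records$gene_id[sel$records$contrast_id == cid]
        enrich[[cid]] <- fisher_overrepresentation(deg, annotations,
                                                   deg_directions = lfc)
        write_tsv_table(enrich[[cid]],
                        file.path(out_dir, paste0("enrichment_", cid, ".tsv")))
      }
    }

    stage <- "network"
    networks <- list()
    topology <- list()
    if (!is.null(inter)) {
      inter_f <- filter_interactome(inter, top_fraction = config$top_fraction)
      counts$edges_kept <- nrow(inter_f)
      for (cid in config$network_contrasts) {
        deg <- sel$degs[[cid]]
        if (is.null(deg) || length(deg) == 0) next
        recs <- sel$records[sel$records$contrast_id == cid &
                              sel$records$passes_threshold, ]
        seeds <- data.frame(gene_id = recs$gene_id, log2_fc = recs$log2_fc,
                            stringsAsFactors = FALSE)
        net <- tryCatch(build_first_order_network(seeds, inter_f),
                        error = function(e) NULL)
        if (is.null(net)) next  # no seed maps into the filtered interactome
        networks[[cid]] <- net
        topology[[cid]] <- classify_topology(net, sd_sample = config$sd_sample)
        write_tsv_table(topology[[cid]],
                        file.path(out_dir, paste0("topology_", cid, ".tsv")))
        write_network(net,
                      graphml_path = file.path(out_dir, paste0("network_", cid, ".graphml")),
                      sif_path = file.path(out_dir, paste0("network_", cid, ".sif")))
      }
    }
    counts$networks <- length(networks)

    stage <- "compare"
    comparisons <- list()
    pairs <- list(
      cortex = c("cortex_SALS1_vs_cortex_CTRL", "cortex_SALS2_vs_cortex_CTRL"),
      spinal = c("spinal_SALS1_vs_spinal_CTRL", "spinal_SALS2_vs_spinal_CTRL")
    )
    for (nm in names(pairs)) {
      pr <- pairs[[nm]]
      if (all(pr %in% names(topology))) {
        cmp <- compare_clusters(topology[[pr[1]]], topology[[pr[2]]])
        comparisons[[nm]] <- cmp
        for (cl in names(cmp)) {
          write_tsv_table(cmp[[cl]],
                          file.path(out_dir, paste0("compare_", nm, "_", cl, ".tsv")))
        }
      }
    }

    stage <- "manifest"
    manifest <- list(
      package_version = as.character(utils::packageVersion("splicenet")),
      seed = config$seed,
      config = config[setdiff(names(config), "synthetic")],
      synthetic = !is.null(config$synthetic),
      counts = counts,
      timestamp = format(Sys.time(), tz = "UTC")
    )
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA,
                         null = "null", force = TRUE)

    list(study = study, normalized = norm, genes = genes, anova = anova,
         selection = sel, venn_effects = venn_effects, venn_degs = venn_degs,
         enrichment = enrich, networks = networks, topology = topology,
         comparisons = comparisons, counts = counts)
  }, error = on_fail)
  invisible(res)
}
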