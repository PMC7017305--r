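#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study emulating the cohort layout
# (41 motor-cortex + 40 spinal-cord arrays, SALS1/SALS2/CTRL 18/13/10 and
# 17/13/10) with planted structure: 30 of 300 panel genes carry a 4-fold
# disease-state shift, one annotation term holds 80% of them, and three
# of them are forced hubs of the scored interactome.
# Writes the pipeline's input files under results/data/.

library(splicenet)

out <- "results/data"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

study <- synthetic_study(n_genes = 300, n_planted = 30, effect_log2 = 2,
                         n_terms = 20, planted_term_fraction = 0.8,
                         interactome_nodes = 250, n_planted_hubs = 3,
                         seed = 20260928)

write_expression_tsv(study$data$expression, file.path(out, "expression.tsv"))
write_tsv_table(study$data$metadata, file.path(out, "metadata.tsv"))
write_probe_map_tsv(study$data$probe_map, file.path(out, "probe_map.tsv"))
writeLines(study$panel, file.path(out, "panel.txt"))
write_gmt(study$annotations, file.path(out, "annotations.gmt"))
write_edge_list_tsv(study$interactome, file.path(out, "interactome.tsv"))
write_tsv_table(study$data$truth, file.path(out, "truth.tsv"))

cat(sprintf("simulated %d probes x %d samples (%d genes, %d planted DEGs)\n",
            nrow(study$data$expression$values),
            ncol(study$data$expression$values),
            length(study$panel), length(study$planted$genes)))
cat(sprintf("interactome: %d edges over %d nodes; planted hubs: %s\n",
            nrow(study$interactome),
            length(unique(c(study$interactome$node_a, study$interactome$node_b))),
            paste(study$planted$hubs, collapse = ", ")))
cat(sprintf("planted term '%s' with %d members\n", study$planted$term_id,
            length(study$annotations$sets[[study$planted$term_id]])))
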