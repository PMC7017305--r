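#!/usr/bin/env Rscript
# Stage 3: per-gene two-way ANOVA (tissue x state, Type-III) with BH
# correction, fold-change screening over the seven study contrasts, DEG
# selection (q < 0.05, |FC| > 2), and Venn partitions of the effect and
# DEG sets.

library(splicenet)

genes <- read_expression_tsv("results/gene_matrix.tsv", level = "gene",
                             stage = "normalized")
metadata <- read_tsv_table("results/data/metadata.tsv")

anova <- two_way_anova(genes, metadata)
pw <- pairwise_fold_changes(genes, metadata)
sel <- select_degs(anova, pw, alpha = 0.05, fc_cut = 2)

write_tsv_table(anova, "results/anova.tsv")
write_tsv_table(sel$records, "results/pairwise.tsv")
for (cid in names(sel$degs)) {
  d <- sel$records[sel$records$contrast_id == cid & sel$records$passes_threshold, ]
  write_tsv_table(d[, c("gene_id", "log2_fc", "direction")],
                  file.path("results", paste0("degs_", cid, ".tsv")))
}

cat("significant genes per effect at q < 0.05:\n")
cat(sprintf("  state %d, tissue %d, interaction %d\n",
            sum(anova$q_state < 0.05), sum(anova$q_tissue < 0.05),
            sum(anova$q_interaction < 0.05)))
cat("DEGs per contrast (q < 0.05, |FC| > 2):\n")
for (cid in names(sel$degs)) {
  cat(sprintf("  %-30s %d\n", cid, length(sel$degs[[cid]])))
}

venn_eff <- venn_partition(list(
  state = anova$gene_id[anova$q_state < 0.05],
  tissue = anova$gene_id[anova$q_tissue < 0.05],
  interaction = anova$gene_id[anova$q_interaction < 0.05]
))
write_tsv_table(venn_eff$regions, "results/venn_effects.tsv")
state_ids <- study_contrasts()$contrast_id[study_contrasts()$type == "state"]
venn_deg <- venn_partition(sel$degs[state_ids])
write_tsv_table(venn_deg$regions, "results/venn_degs.tsv")
cat("effect-set Venn regions:\n")
print(venn_eff$regions, row.names = FALSE)
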