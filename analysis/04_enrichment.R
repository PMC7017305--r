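#!/usr/bin/env Rscript
# Stage 4: one-sided Fisher's exact overrepresentation of each contrast's
# DEG list against the annotation sets, Bonferroni-corrected, with a
# direction summary per term.

library(splicenet)

annotations <- read_gmt("results/data/annotations.gmt",
                        universe = read_panel("results/data/panel.txt"))
records <- read_tsv_table("results/pairwise.tsv")

for (cid in unique(records$contrast_id)) {
  rec <- records[records$contrast_id == cid, ]
  deg <- rec$gene_id[rec$passes_threshold == "TRUE" | rec$passes_threshold == TRUE]
  if (length(deg) == 0) next
  lfc <- setNames(rec$log2_fc, rec$gene_id)
  enr <- fisher_overrepresentation(deg, annotations, deg_directions = lfc)
  write_tsv_table(enr, file.path("results", paste0("enrichment_", cid, ".tsv")))
  top <- enr[1, ]
  cat(sprintf("%s: %d DEGs; top term %s (k=%d/K=%d, p=%.3g, Bonferroni=%.3g, %s)\n",
              cid, length(deg), top$term_id, top$k, top$K, top$p,
              top$p_bonferroni, top$direction))
}
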