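#!/usr/bin/env Rscript
# Stage 6: gene-level enrichment of the generated gene sets in aDMRs and in
# expression-correlating aDMRs (2x2 tables, sample odds ratios, Fisher's
# exact tests). Writes results/enrichment.tsv.

library(agedmr)

state <- readRDS("scratch/primary_regions.rds")
links <- readRDS("scratch/links.rds")
sets <- list(enriched = read_gene_set("results/sim/geneset_enriched.txt"),
             background = read_gene_set("results/sim/geneset_background.txt"))

rows <- list()
for (set_name in names(sets)) {
  for (feat in c("admr", "expr_admr")) {
    e <- gene_set_enrichment(state$regions, sets[[set_name]], feature = feat,
                             links = links)
    rows[[paste(set_name, feat)]] <-
      data.frame(set = set_name, feature = feat,
                 a = e$table[1, 1], b = e$table[1, 2],
                 c = e$table[2, 1], d = e$table[2, 2],
                 odds_ratio = e$odds_ratio, p = e$p_value)
    cat(sprintf("%-11s %-10s OR = %5.2f, p = %.3g\n",
                set_name, feat, e$odds_ratio, e$p_value))
  }
}
data.table::fwrite(do.call(rbind, rows), "results/enrichment.tsv", sep = "\t")
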