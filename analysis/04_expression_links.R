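#!/usr/bin/env Rscript
# Stage 4: link candidate regions to local gene expression through the
# maximally correlating member site; flag expression-correlating aDMRs
# (|Pearson r| >= 0.3). Writes results/expression_links.tsv.

library(agedmr)

sim <- "results/sim"
state <- readRDS("scratch/primary_regions.rds")
ds <- filter_probes(read_methylome(file.path(sim, "beta.tsv"),
                                   file.path(sim, "annotation.tsv"),
                                   file.path(sim, "subjects.tsv")))
sm <- smooth_beta(ds, window_bp = 500)
expr <- read_expression(file.path(sim, "expression.tsv"))
al <- align_subjects(sm, expr)
links <- link_regions_to_expression(state$regions, al$dataset, al$expr,
                                    min_abs_r = 0.3)
data.table::fwrite(links, "results/expression_links.tsv", sep = "\t")
saveRDS(links, "scratch/links.rds")

sm_counts <- summarize_links(links, state$regions)
cat(sprintf("%d aDMRs, %d expression-correlating (genes: %d)\n",
            sm_counts$n_dmrs, sm_counts$n_expression_correlating,
            sm_counts$n_genes_expression_correlating))

truth <- jsonlite::read_json(file.path(sim, "ground_truth.json"),
                             simplifyVector = TRUE)$coupled
flagged <- vapply(truth$gene, function(g)
  any(links$gene == g & links$is_expression_correlating), logical(1L))
cat(sprintf("coupled genes recovered: %d/%d\n", sum(flagged), nrow(truth)))
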