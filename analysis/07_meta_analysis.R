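#!/usr/bin/env Rscript
# Stage 7: site-by-site fixed-effect meta-analysis of the primary and
# replication cohorts, then region definition on the meta-summarized sites.
# Writes results/meta_sitestats.tsv and results/meta_regions.tsv.

library(agedmr)

st_a <- data.table::fread("results/sitestats_primary.tsv", data.table = FALSE)
st_b <- data.table::fread("results/sitestats_replication.tsv",
                          data.table = FALSE)
ms <- meta_combine_sites(st_a, st_b)
regions <- meta_define_regions(ms, site_alpha = 0.05, max_gap_bp = 1000)
regions <- call_dmrs(regions, q_threshold = 0.05, effect_threshold = 0.03)

data.table::fwrite(ms, "results/meta_sitestats.tsv", sep = "\t")
data.table::fwrite(as.data.frame(regions), "results/meta_regions.tsv",
                   sep = "\t")

truth <- jsonlite::read_json("results/sim/ground_truth.json",
                             simplifyVector = TRUE)$regions
dmrs <- regions[regions$is_dmr, ]
hit <- vapply(seq_len(nrow(truth)), function(k)
  any(dmrs$chrom == truth$chrom[k] & dmrs$start <= truth$end[k] &
      dmrs$end >= truth$start[k]), logical(1L))
cat(sprintf("meta: %d shared sites, %d regions, %d aDMRs; %d/%d implanted recovered\n",
            nrow(ms), nrow(regions), nrow(dmrs), sum(hit), nrow(truth)))
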