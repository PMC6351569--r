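#!/usr/bin/env Rscript
# Stage 5: CpG island/shore/shelf/sea classification of analyzed sites,
# distribution of aDMR-associated sites across contexts, and the
# hypermethylation gradient. Writes results/context_distribution.tsv and
# results/gradient.tsv.

library(agedmr)

state <- readRDS("scratch/primary_regions.rds")
islands <- read_islands("results/sim/islands.bed")
st <- state$stats
regions <- state$regions

context <- classify_context(st$pos, st$chrom, islands)
in_dmr <- regions$is_dmr[attr(regions, "site_cr")] %in% TRUE

ct <- context_distribution_test(context, in_dmr)
per <- do.call(rbind, lapply(names(ct$per_context), function(cx) {
  e <- ct$per_context[[cx]]
  data.frame(context = cx, a = e$table[1, 1], b = e$table[1, 2],
             c = e$table[2, 1], d = e$table[2, 2],
             odds_ratio = e$odds_ratio, p = e$p_value)
}))
data.table::fwrite(per, "results/context_distribution.tsv", sep = "\t")

grad <- hypermethylation_gradient(context[in_dmr], st$direction[in_dmr])
data.table::fwrite(data.frame(context = names(grad$fractions),
                              hyper_fraction = as.vector(grad$fractions),
                              n = as.vector(rowSums(grad$counts))),
                   "results/gradient.tsv", sep = "\t")

cat(sprintf("context goodness-of-fit: chi2 = %.1f (df %d), p = %.3g\n",
            ct$chi2, ct$df, ct$p))
cat(sprintf("hypermethylation gradient: chi2 = %.1f (df %d), p = %.3g\n",
            grad$chi2, grad$df, grad$p))
print(round(100 * grad$fractions, 1))
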