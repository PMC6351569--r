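#!/usr/bin/env Rscript
# Stage 1: generate the synthetic two-cohort methylome study.
#
# Primary cohort: 20 younger + 19 older subjects, 20,000 clustered CpG sites
# on 4 chromosomes, beta concentration 100 (array-like noise). Thirty
# five-site regions carry a true group difference (20 at +10%, 10 at -10%
# methylation); ten of their genes are expression-coupled at Pearson r = -0.9;
# the "enriched" gene set draws half its 40 genes from implanted-region genes.
# A replication cohort shares the site skeleton and true means but has
# independent subjects. Everything is written under results/sim/.

library(agedmr)

seed <- 1L
out <- "results/sim"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

specs <- c(replicate(20, dmr_spec(5, 0.10), simplify = FALSE),
           replicate(10, dmr_spec(5, -0.10), simplify = FALSE))
cfg <- sim_config(n_sites = 20000, n_chromosomes = 4, dmr_specs = specs,
                  n_coupled_genes = 10, target_r = -0.9,
                  n_genes_in_set = 40, geneset_dmr_fraction = 0.5,
                  seed = seed)
study <- simulate_study(cfg, dir = out)

# replication cohort: same loci and true means, fresh subjects
set.seed(seed + 4L)
conc <- cfg$concentration
redraw <- function(mu, n) {
  x <- rbeta(length(mu) * n, rep(mu * conc, n), rep((1 - mu) * conc, n))
  matrix(pmin(pmax(x, 1e-6), 1 - 1e-6), nrow = length(mu))
}
rep_ds <- study$dataset
rep_ds$beta <- cbind(redraw(study$truth$mu_young, 20L),
                     redraw(study$truth$mu_old, 19L))
dimnames(rep_ds$beta) <- dimnames(study$dataset$beta)
write_methylome(rep_ds,
                file.path(out, "replication_beta.tsv"),
                file.path(out, "replication_annotation.tsv"),
                file.path(out, "replication_subjects.tsv"))

cat(sprintf("simulated %d sites x %d subjects, %d implanted regions\n",
            nrow(study$dataset$beta), ncol(study$dataset$beta),
            nrow(study$truth$regions)))
cat("written to", out, "\n")
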