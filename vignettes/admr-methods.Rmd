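---
title: "Region-based detection of age-associated differential DNA methylation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Region-based detection of age-associated differential DNA methylation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(agedmr)
```

## The analysis

`agedmr` implements a region-level two-group comparison of array-style DNA
methylation between younger and older subjects. The unit of measurement is
the beta value, the fraction of methylated signal at a CpG site, in [0, 1].
The procedure is:

1. **Probe filtering.** Sites flagged for poor hybridization, SNP overlap in
   the probe or target, multi-mapping, and all sex-chromosome sites are
   removed (`filter_probes()`).
2. **Smoothing.** Per subject, each site's beta value is replaced by the
   unweighted mean over sites on the same chromosome within a centered
   500-bp window, endpoints inclusive (`smooth_beta()`). The window is a
   design choice over an under-specified convention: we read "500-bp sliding
   window" as ±250 bp around the site; the width is a parameter.
3. **Site tests.** Smoothed beta values are logit2-transformed to M-values
   (`beta_to_m()`, guard `epsilon = 1e-6`) for approximate normality, and
   each site is tested with a two-tailed two-sample t-test, Welch by default
   because the group sizes (20 vs 19 in the design the generator emulates)
   and variances need not match; a pooled-variance option exists. Effect
   sizes (`delta_beta` = mean(older) − mean(younger)) and their sampling
   variances are computed on the smoothed beta scale, where "percent
   methylation" lives.
4. **Candidate regions (CRs).** Sites significant at `site_alpha = 0.05`
   are merged greedily left-to-right into maximal runs in which consecutive
   sites are ≤ 1000 bp apart and all effects share a sign; every other site
   is its own isolated CR. Every analyzed site belongs to exactly one CR —
   a partition property the tests assert.
5. **Region p-values.** Within each CR, site p-values are combined with
   Fisher's method, −2Σlog p ~ χ²(2m). Smoothing makes neighbouring
   p-values dependent, so the combined value is *not* treated as a valid
   p-value; it is a ranking statistic whose calibration comes from the next
   step. This is stated prominently because it is the one place the
   analysis would be unsound without the permutation stage.
6. **Permutation calibration.** Subject labels are permuted B times
   (default 500; the bundled analyses use 200); each permutation re-runs
   the site tests and region building from scratch and contributes its
   regions' Fisher-combined values to a pooled null. The permuted p-value
   of an observed region is the fraction of pooled values less than or
   equal to its own (ties count). Permutations are sampled uniformly with
   replacement over the label-permutation space — the identity labeling may
   recur — because the procedure specifies random permutations, not
   distinct ones; an exhaustive mode enumerates every distinct group
   assignment for small cohorts and is checked against brute-force
   enumeration in the tests.
7. **FDR and aDMR calls.** Benjamini–Hochberg is applied jointly across all
   CRs, merged and isolated alike. A permuted p of exactly 0 is a one-sided
   bound (< 1/Σm_b); it enters BH as 0.5/Σm_b so q-values stay defined —
   a documented convention, configurable in principle and visible in the
   stored `p_perm` column, which keeps the raw 0. A CR is an aDMR when
   q < 0.05 *and* |region effect| > 0.03 (3% methylation), both strict.
   The region effect is the inverse-variance (fixed-effect) weighted mean
   of member `delta_beta`; a zero-variance member triggers an unweighted
   fallback with a warning.
8. **Expression linkage.** Each region annotated to an expressed gene is
   represented by the member site whose Pearson correlation with that
   gene's expression is maximal in absolute value, sign retained.
   Expression-correlating aDMRs require |r| ≥ 0.3 and an aDMR call.
   Correlation uses all aligned subjects (no group split) and the smoothed
   beta values the pipeline carries; both are choices where the source
   procedure is silent, and raw-beta correlation is available by running
   the linkage on an unsmoothed dataset.
9. **Context and gene-set enrichment.** Sites are classified island /
   shore / shelf / sea (2-kb rings outside island edges; north = lower
   coordinate side; nearest island wins overlapping flanks, ties resolve
   deterministically to the lower-coordinate island's south flank). The
   aDMR-site context distribution is tested by chi-square goodness-of-fit
   against the all-site distribution, with per-context 2×2 sample odds
   ratios and two-sided Fisher's exact p. Gene-set enrichment is
   gene-level: the universe is all genes with ≥ 1 analyzed region, a gene
   "carries" a feature if ≥ 1 of its regions has it, and the reported OR is
   the cross-product (sample) OR — the convention in enrichment tables —
   rather than the conditional-MLE OR that `fisher.test` estimates; the
   exact-test p does come from the hypergeometric (Fisher) test.
   Chi-square tests use no continuity correction.
10. **Meta-analysis.** Two cohorts are combined site-by-site with a
    fixed-effect model: inverse-variance weighted effect, variance 1/Σw,
    z = effect/√variance, two-sided normal p. We derive the combined
    p-value from the fixed-effect z rather than adding a separate Stouffer
    step, so effect and p come from one coherent model. Regions are then
    rebuilt from the meta p-values under the unchanged merging rules.
    Meta-region q-values default to BH on the Fisher-combined values;
    a joint within-cohort label permutation (`meta_permutation_null()`) is
    available but off by default because the meta stage's calibration cost
    is B full two-cohort re-analyses.

## The synthetic generator

No array data ships with the package; every empirical claim is made on
synthetic studies with known ground truth (`sim_config()`,
`simulate_study()`).

* **Noise model.** Per-site beta values are drawn from a beta distribution
  parameterized by (mean, concentration). Concentration 100 gives SD ≈ 0.03
  at mean 0.5, a realistic scale for HM450-class arrays after
  normalization; there is no published variance model for these arrays, so
  the concentration is the single noise knob and is deliberately exposed.
* **Spatial structure.** Sites come in clusters (geometric sizes, mean 4;
  exponential intra-cluster gaps, mean 200 bp) separated by exponential
  inter-cluster gaps (mean 5000 bp), so the 1000-bp merging rule is
  genuinely exercised: clusters merge, distinct clusters do not.
* **Ground truth.** Implanted regions shift the older-group mean by a
  signed `delta_beta`; all true means stay within [0.05, 0.95] before
  noise, and configurations that cannot honour that margin are rejected.
  Each cluster carries one synthetic gene; a configurable fraction of
  clusters is covered by a CpG island interval, so context classification
  is testable end-to-end. Expression for coupled genes is a linear blend of
  the site's standardized methylation and Gaussian noise at a target
  Pearson r; gene sets draw a configured fraction of members from
  implanted-region genes.
* **What it does not emulate.** Probe-level two-channel intensities, batch
  effects, cell-composition mixtures, the bimodal genome-wide beta
  distribution, and long-range comethylation beyond the cluster scale.
  Passing tests therefore demonstrate the correctness and calibration of
  the procedure under exchangeable beta-distributed noise, not performance
  on raw array data.

## Problem sizes and numerical choices

The bundled analyses and validation suites run at 20,000 sites, 20 + 19
subjects and B = 200 permutations, with 50-replicate null-calibration and
20-replicate recovery studies; these sizes give stable Monte-Carlo estimates
(the null pool holds ~4 million permuted region values per dataset) while
keeping a full run in minutes on one core. Degenerate inputs are handled
explicitly: zero within-group variance gives p = 1 (equal means) or the
machine minimum with a warning (unequal means); p-values are clipped into
(0, 1]; Fisher's method receives machine-minimum in place of 0 with a
warning; zero-variance members fall back to unweighted region means; and
zero-variance expression or methylation vectors are skipped in linkage, not
silently scored. Missing beta entries are rejected outright rather than
imputed. Site sorting is stable, so ties at one position keep input order.

## Known limitations

* The permutation null pools regions across permutations; with few subjects
  the number of distinct label assignments bounds the resolution of p*.
* Fisher-combined values on smoothed data are anticonservative as p-values;
  they are only ever used as ranks (see above).
* Gene assignment is taken from the annotation as given; no nearest-gene
  computation is performed.
* Covariate adjustment (continuous age, pH, post-mortem interval) is out of
  scope; the design is strictly two-group.
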