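Package: agedmr
Title: Region-Based Detection of Age-Associated Differential DNA Methylation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects age-associated differentially methylated regions (aDMRs)
    from array-style beta-value matrices: sliding-window smoothing, M-value
    two-group t-tests, greedy merging of concordant significant sites into
    candidate regions, Fisher's method for region p-values, label-permutation
    calibration, Benjamini-Hochberg false discovery rate control, and
    inverse-variance region effect sizes. Also links regions to local gene
    expression through the maximally correlating member site, classifies sites
    into CpG island/shore/shelf/sea contexts, tests context and gene-set
    enrichment with odds ratios and Fisher's exact tests, and combines two
    datasets site-by-site with a fixed-effect meta-analysis. A synthetic
    methylome generator with known ground truth (implanted regions, known
    methylation-expression coupling, known gene-set enrichment) supports
    end-to-end validation without array downloads.
License: MIT
Encoding: UTF-8
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    metafor,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
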