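test_that("context classification follows island / shore / shelf / sea distances", {
  isl <- data.frame(chrom = "chr1", start = 10000L, end = 11000L)
  got <- classify_context(c(10500L, 12500L, 14500L, 16000L, 9500L, 6500L, 4000L),
                          "chr1", isl)
  expect_equal(got, c("island", "shore_south", "shelf_south", "sea",
                      "shore_north", "shelf_north", "sea"))
  # boundary distances are inclusive; 2001 bp is a shelf
  expect_equal(classify_context(c(13000L, 13001L, 15000L, 15001L), "chr1", isl),
               c("shore_south", "shelf_south", "shelf_south", "sea"))
  # a chromosome without islands is all sea
  expect_equal(classify_context(10500L, "chr9", isl), "sea")
})

test_that("the nearest island wins when flanks of two islands overlap", {
  isl <- data.frame(chrom = "chr1", start = c(10000L, 16000L),
                    end = c(11000L, 17000L))
  # 12000 is 1000 past island 1 (shore) and 4000 before island 2 (shelf)
  expect_equal(classify_context(12000L, "chr1", isl), "shore_south")
  expect_equal(classify_context(15500L, "chr1", isl), "shore_north")
  # every position gets exactly one of the six labels
  pos <- seq(1L, 25000L, by = 37L)
  labs <- classify_context(pos, "chr1", isl)
  expect_true(all(labs %in% c("island", "shore_north", "shore_south",
                              "shelf_north", "shelf_south", "sea")))
})

test_that("context distribution test is null on proportional sampling and matches the 2x2 arithmetic", {
  ctx <- rep(c("island", "sea"), each = 100)
  prop_feature <- rep(rep(c(TRUE, FALSE), c(20, 80)), 2)
  null_res <- suppressMessages(context_distribution_test(ctx, prop_feature))
  expect_lt(null_res$chi2, 1e-10)
  expect_equal(null_res$per_context$island$odds_ratio, 1)

  # 10 of 100 island sites vs 30 of 100 sea sites carry the feature
  feat <- c(rep(c(TRUE, FALSE), c(10, 90)), rep(c(TRUE, FALSE), c(30, 70)))
  res <- suppressMessages(context_distribution_test(ctx, feat))
  isl <- res$per_context$island
  expect_equal(unname(isl$table[1, ]), c(10, 90))
  expect_equal(isl$odds_ratio, 10 * 70 / (90 * 30))
  expect_equal(isl$p_value,
               oracle_fisher_exact(10, 90, 30, 70), tolerance = 1e-10)
  expect_error(context_distribution_test(ctx, rep(FALSE, 200)), "no feature")
})

test_that("hypermethylation fractions and homogeneity test match the contingency oracle", {
  ctx <- rep(c("island", "sea"), each = 40)
  dir <- c(rep(c("hyper", "hypo"), c(30, 10)), rep(c("hyper", "hypo"), c(10, 30)))
  res <- hypermethylation_gradient(ctx, dir)
  expect_equal(unname(res$fractions), c(0.75, 0.25))
  want <- stats::chisq.test(table(ctx, dir), correct = FALSE)
  expect_equal(res$chi2, unname(want$statistic), tolerance = 1e-12)
  expect_equal(res$p, want$p.value, tolerance = 1e-12)
  # frozen oracle values for this table
  expect_equal(res$chi2, 20.0, tolerance = 1e-12)
  expect_equal(res$p, 7.744216e-06, tolerance = 1e-6)
  # equal fractions on equal counts -> chi2 = 0
  flat <- suppressWarnings(
    hypermethylation_gradient(rep(c("island", "sea"), each = 4),
                              rep(c("hyper", "hypo"), 4)))
  expect_equal(flat$chi2, 0)
  # unrepresented contexts are dropped from the test
  expect_message(suppressWarnings(
    hypermethylation_gradient(c("island", "island"), c("hyper", "hypo"))),
    "dropped")
})

test_that("gene-set enrichment reproduces the cross-product OR and the exact test", {
  # 100 set genes (30 carriers), 900 background genes (100 carriers)
  regions_genes <- c(sprintf("S%03d", 1:100), sprintf("B%03d", 1:900))
  carriers <- c(sprintf("S%03d", 1:30), sprintf("B%03d", 1:100))
  st <- make_stats(pos = seq_len(1000) * 10000L,
                   p = ifelse(regions_genes %in% carriers, 0.001, 0.9),
                   delta = 0.1, gene = regions_genes)
  rg <- build_candidate_regions(st)
  rg$is_dmr <- !rg$is_isolated
  set <- structure(list(name = "toy", genes = sprintf("S%03d", 1:100)),
                   class = "gene_set")
  res <- gene_set_enrichment(rg, set, feature = "admr")
  expect_equal(unname(as.vector(t(res$table))), c(30, 70, 100, 800))
  expect_equal(res$odds_ratio, 30 * 800 / (70 * 100))
  expect_equal(res$p_value, oracle_fisher_exact(30, 70, 100, 800),
               tolerance = 1e-10)
})

test_that("exact-test p agrees with the hypergeometric oracle across random tables", {
  set.seed(14)
  for (i in 1:20) {
    tb <- matrix(rpois(4, 15) + 1L, 2)
    got <- stats::fisher.test(tb)$p.value
    want <- oracle_fisher_exact(tb[1, 1], tb[1, 2], tb[2, 1], tb[2, 2])
    expect_equal(got, want, tolerance = 1e-10)
    # symmetry under swapping both rows and both columns
    expect_equal(got, stats::fisher.test(tb[2:1, 2:1])$p.value,
                 tolerance = 1e-12)
  }
})

test_that("degenerate gene-set tables are refused or flagged", {
  st <- make_stats(pos = seq_len(10) * 10000L, p = rep(0.9, 10),
                   delta = 0.1, gene = sprintf("G%02d", 1:10))
  rg <- build_candidate_regions(st)
  rg$is_dmr <- FALSE
  set <- structure(list(name = "s", genes = sprintf("G%02d", 1:4)),
                   class = "gene_set")
  res <- gene_set_enrichment(rg, set)  # no gene carries the feature
  expect_true(res$degenerate)
  all_set <- structure(list(name = "u", genes = sprintf("G%02d", 1:10)),
                       class = "gene_set")
  expect_error(gene_set_enrichment(rg, all_set), "set equals universe")
  empty <- structure(list(name = "e", genes = "ABSENT"), class = "gene_set")
  expect_error(suppressMessages(gene_set_enrichment(rg, empty)), "no genes")
})

test_that("background-rate gene sets give odds ratios near 1 on average", {
  ors <- numeric(30)
  for (i in seq_len(30)) {
    cfg <- sim_config(n_sites = 2000, n_chromosomes = 2,
                      dmr_specs = replicate(40, dmr_spec(4, 0.15),
                                            simplify = FALSE),
                      n_genes_in_set = 50, geneset_dmr_fraction = 0,
                      seed = 3000 + i)
    gm <- generate_methylome(cfg)
    # enriched set built at the realized background overlap rate
    cfg$geneset_dmr_fraction <-
      length(gm$truth$dmr_genes) / length(gm$truth$genes)
    sets <- generate_gene_sets(gm$truth, cfg, seed = 4000 + i)
    universe <- gm$truth$genes
    carrier <- universe %in% gm$truth$dmr_genes
    set_genes <- sets$enriched$genes
    a <- sum(set_genes %in% universe[carrier])
    b <- sum(set_genes %in% universe[!carrier])
    c_ <- sum(carrier) - a
    d <- sum(!carrier) - b
    ors[i] <- (a * d) / (b * c_)
  }
  expect_lt(abs(mean(ors) - 1), 0.2)
})
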