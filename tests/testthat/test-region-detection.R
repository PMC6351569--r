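test_that("gap, concordance and significance rules partition sites into regions", {
  st <- make_stats(pos = c(100L, 600L, 2000L, 2500L, 5000L),
                   p = c(0.01, 0.02, 0.03, 0.04, 0.5),
                   delta = c(0.1, 0.1, 0.1, -0.1, 0.1))
  rg <- build_candidate_regions(st)
  expect_equal(nrow(rg), 4L)
  expect_equal(rg$n_sites, c(2L, 1L, 1L, 1L))
  expect_equal(rg$start, c(100L, 2000L, 2500L, 5000L))
  expect_equal(rg$end, c(600L, 2000L, 2500L, 5000L))
  expect_equal(rg$direction, c("hyper", "hyper", "hypo", "none"))
  expect_equal(rg$is_isolated, c(FALSE, FALSE, FALSE, TRUE))
})

test_that("without significant sites every region is an isolated singleton", {
  st <- make_stats(pos = c(100L, 200L, 300L), p = c(0.5, 0.9, 0.06),
                   delta = c(0.1, 0.1, 0.1))
  rg <- build_candidate_regions(st)
  expect_equal(nrow(rg), 3L)
  expect_true(all(rg$is_isolated))
  expect_equal(rg$p_fisher, st$p)
})

test_that("region assignment partitions every site exactly once, matching the naive merger", {
  set.seed(6)
  for (rep in 1:5) {
    n <- 400
    st <- make_stats(pos = sort(sample.int(2e5, n)),
                     p = runif(n)^2,
                     delta = rnorm(n, 0, 0.05),
                     chrom = sort(sample(c("chr1", "chr2", "chr3"), n,
                                         replace = TRUE)))
    st <- st[order(st$chrom, st$pos), ]
    rg <- build_candidate_regions(st)
    cr <- attr(rg, "site_cr")
    expect_equal(sum(rg$n_sites), n)
    expect_equal(tabulate(cr), rg$n_sites)
    expect_equal(cr, oracle_assign_crs(st$chrom, st$pos, st$p, st$delta_beta))
    # row shuffling (chromosome processing order) does not change the partition
    sh <- st[sample(n), ]
    rg2 <- build_candidate_regions(sh)
    expect_equal(rg2$start, rg$start)
    expect_equal(rg2$n_sites, rg$n_sites)
  }
})

test_that("Fisher's method matches the closed-form chi-square survival oracle", {
  expect_equal(fisher_combine(0.2), 0.2)
  expect_equal(fisher_combine(c(1, 1)), 1)
  expect_equal(fisher_combine(c(0.05, 0.05)),
               chisq_sf_even(-2 * 2 * log(0.05), 2), tolerance = 1e-12)
  expect_equal(fisher_combine(c(0.05, 0.05)), 0.01747, tolerance = 1e-3)
  set.seed(12)
  for (m in c(2, 3, 5, 8)) {
    p <- runif(m)
    expect_equal(fisher_combine(p), oracle_fisher(p), tolerance = 1e-10)
  }
  expect_warning(out <- fisher_combine(c(0, 0.5)), "clipped")
  expect_gt(out, 0)
  expect_error(fisher_combine(numeric(0)), "empty")
})

test_that("permuted p-values implement the pooled-count formula", {
  # two permutations with region p-values {0.05, 0.2} and {0.3}; an observed
  # region at p = 0.1 is beaten by one of three pooled values
  null <- structure(list(pooled = c(0.05, 0.2, 0.3), m_b = c(2L, 1L), B = 2L),
                    class = "permutation_null")
  rg <- build_candidate_regions(
    make_stats(pos = c(100L, 9000L), p = c(0.1, 0.01), delta = c(0.1, 0.1)))
  rg$p_fisher <- c(0.1, 0.04)
  out <- calibrate_and_fdr(rg, null)
  expect_equal(out$p_perm, c(1 / 3, 0))
  # ties count toward the numerator
  rg$p_fisher <- c(0.2, 0.3)
  expect_equal(calibrate_and_fdr(rg, null)$p_perm, c(2 / 3, 1))
  # p_perm = 0 enters BH as 0.5/total, so q stays positive and finite
  rg$p_fisher <- c(0.01, 0.5)
  out0 <- calibrate_and_fdr(rg, null)
  expect_equal(out0$p_perm[1], 0)
  expect_equal(out0$q_value[1], 2 * 0.5 / 3)
  expect_error(calibrate_and_fdr(rg, structure(list(pooled = numeric(0)),
                                               class = "permutation_null")),
               "empty")
})

test_that("sampled permutation null is reproducible under a fixed seed", {
  cfg <- sim_config(n_sites = 300, n_chromosomes = 2, seed = 5,
                    geneset_dmr_fraction = 0)
  ds <- smooth_beta(generate_methylome(cfg)$dataset)
  a <- permutation_null(ds, B = 5, seed = 99)
  b <- permutation_null(ds, B = 5, seed = 99)
  expect_identical(a$pooled, b$pooled)
  expect_identical(a$m_b, b$m_b)
  expect_error(permutation_null(ds, B = 0), "B must be")
})

test_that("exhaustive permutation equals brute-force enumeration on a small cohort", {
  cfg <- sim_config(n_sites = 25, n_chromosomes = 1,
                    n_subjects_young = 3, n_subjects_old = 3,
                    dmr_specs = list(dmr_spec(3, 0.2)),
                    geneset_dmr_fraction = 0, seed = 17)
  ds <- smooth_beta(generate_methylome(cfg)$dataset)
  got <- permutation_null(ds, exhaustive = TRUE)
  want <- oracle_permutation_pool(ds)
  expect_equal(got$B, choose(6, 3))
  expect_equal(got$m_b, want$m_b)
  expect_equal(sort(got$pooled), sort(want$pooled), tolerance = 1e-12)
})

test_that("BH q-values follow the step-up procedure", {
  rg <- build_candidate_regions(
    make_stats(pos = c(1L, 9000L, 20000L, 31000L) * 10L,
               p = c(0.5, 0.6, 0.7, 0.8), delta = rep(0.1, 4)))
  null <- structure(list(pooled = seq(0.001, 1, length.out = 100),
                         m_b = 100L, B = 1L), class = "permutation_null")
  rg$p_fisher <- c(0.0105, 0.0205, 0.0305, 0.0405)  # p_perm = .01,.02,.03,.04
  out <- calibrate_and_fdr(rg, null)
  expect_equal(out$p_perm, c(0.01, 0.02, 0.03, 0.04))
  expect_equal(out$q_value, rep(0.04, 4))
  expect_equal(out$q_value, oracle_bh(out$p_perm))
  # all p_perm = 1 -> all q = 1; single region -> q = p_perm
  rg$p_fisher <- rep(1, 4)
  expect_true(all(calibrate_and_fdr(rg, null)$q_value == 1))
  one <- rg[1, ]; attr(one, "site_cr") <- 1L
  one$p_fisher <- 0.0305
  expect_equal(calibrate_and_fdr(one, null)$q_value,
               calibrate_and_fdr(one, null)$p_perm)
  # q is monotone nondecreasing in p_perm
  set.seed(3)
  p <- runif(50)
  q <- oracle_bh(p)
  expect_true(all(diff(q[order(p)]) >= -1e-15))
})

test_that("region effect sizes are inverse-variance weighted means", {
  expect_equal(region_effect_size(0.05, 0.01), 0.05)
  expect_equal(region_effect_size(c(0.10, 0.20), c(0.01, 0.04)), 0.12)
  expect_equal(region_effect_size(c(0.1, 0.3), c(0.02, 0.02)), 0.2)
  expect_warning(e <- region_effect_size(c(0.1, 0.3), c(0, 0.02)),
                 "unweighted")
  expect_equal(e, 0.2)
  # the vectorized path in build_candidate_regions agrees
  st <- make_stats(pos = c(100L, 300L), p = c(0.01, 0.01),
                   delta = c(0.10, 0.20))
  st$variance <- c(0.01, 0.04)
  rg <- build_candidate_regions(st)
  expect_equal(rg$effect_size, 0.12)
})

test_that("DMR calls require both the q and the effect threshold", {
  rg <- build_candidate_regions(
    make_stats(pos = c(1L, 9000L, 18000L) * 10L, p = rep(0.01, 3),
               delta = rep(0.1, 3)))
  rg$q_value <- c(0.01, 0.01, 0.06)
  rg$effect_size <- c(0.05, 0.02, 0.10)
  out <- suppressMessages(call_dmrs(rg))
  expect_equal(out$is_dmr, c(TRUE, FALSE, FALSE))
  # raising the effect threshold never adds DMRs
  hi <- suppressMessages(call_dmrs(rg, effect_threshold = 0.08))
  expect_true(all(!hi$is_dmr | out$is_dmr))
  # boundary values are excluded (strict inequalities)
  rg$q_value <- c(0.05, 0.01, 0.01); rg$effect_size <- c(0.1, 0.03, -0.031)
  expect_equal(suppressMessages(call_dmrs(rg))$is_dmr, c(FALSE, FALSE, TRUE))
})
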