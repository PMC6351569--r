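#' Combine p-values with Fisher's method
#'
#' X = -2 * sum(log p) is referred to a chi-square distribution with 2m
#' degrees of freedom (m = number of p-values). A single p-value is returned
#' unchanged. Zeros are clipped to the machine minimum with a warning.
#'
#' @param p_values Numeric vector of p-values in (0, 1\].
#' @return The combined p-value.
#' @export
fisher_combine <- function(p_values) {
  if (!length(p_values)) stop("empty p-value list")
  if (any(p_values <= 0)) {
    warning("p-value(s) <= 0 clipped to machine minimum")
    p_values <- pmax(p_values, .Machine$double.xmin)
  }
  if (length(p_values) == 1L) return(p_values)
  stats::pchisq(-2 * sum(log(p_values)), df = 2 * length(p_values),
                lower.tail = FALSE)
}

# Partition sorted sites into candidate-region ids. A new region starts at a
# chromosome change, at or after any non-significant site, when the gap to
# the previous site exceeds max_gap_bp, or when direction flips. Sites with
# delta exactly 0 (or p >= alpha) never merge.
assign_cr_ids <- function(chrom, pos, p, delta, site_alpha = 0.05,
                          max_gap_bp = 1000) {
  n <- length(p)
  sig <- p < site_alpha & delta != 0
  dirn <- sign(delta)
  if (n == 1L) return(list(cr = 1L, significant = sig))
  prev <- seq_len(n - 1L)
  brk <- c(TRUE,
           chrom[-1L] != chrom[prev] |
           !sig[-1L] | !sig[prev] |
           (pos[-1L] - pos[prev]) > max_gap_bp |
           dirn[-1L] != dirn[prev])
  list(cr = cumsum(brk), significant = sig)
}

# Fisher-combine per region: -2*sum(log p) ~ chisq(2m). Vectorized over all
# regions via rowsum; single-member regions keep their own p exactly.
fisher_by_cr <- function(p, cr) {
  m <- tabulate(cr)
  X <- -2 * rowsum(log(pmax(p, .Machine$double.xmin)), cr, reorder = TRUE)[, 1L]
  pf <- stats::pchisq(X, df = 2 * m, lower.tail = FALSE)
  pf[m == 1L] <- p[cr %in% which(m == 1L)]
  list(p_fisher = unname(pf), m = m)
}

#' Merge site statistics into candidate regions
#'
#' Significant sites (p < `site_alpha`) are greedily merged left to right into
#' maximal runs in which consecutive sites are at most `max_gap_bp` apart and
#' all directions agree; every other site becomes a singleton isolated region.
#' Every site belongs to exactly one region. Each region gets a combined
#' p-value by Fisher's method and an inverse-variance weighted effect size.
#'
#' @param stats A `site_stats` data.frame (sorted by chromosome, position).
#' @param site_alpha Per-site significance threshold for merging; default 0.05.
#' @param max_gap_bp Maximum gap between consecutive member sites; default 1000.
#' @return data.frame of class `candidate_regions`: `cr_id`, `chrom`, `start`,
#'   `end`, `n_sites`, `direction`, `p_fisher`, `effect_size`, `is_isolated`,
#'   and NA placeholders for `p_perm`, `q_value`, `is_dmr`. The site-to-region
#'   map is attached as attribute `site_cr` (integer per row of `stats`).
#' @export
build_candidate_regions <- function(stats, site_alpha = 0.05, max_gap_bp = 1000) {
  if (is.unsorted(order(stats$chrom, stats$pos)))
    stats <- stats[order(stats$chrom, stats$pos), , drop = FALSE]
  a <- assign_cr_ids(stats$chrom, stats$pos, stats$p, stats$delta_beta,
                     site_alpha, max_gap_bp)
  cr <- a$cr
  fb <- fisher_by_cr(stats$p, cr)
  first <- which(!duplicated(cr))
  last <- c(first[-1L] - 1L, length(cr))
  eff <- region_effects(stats$delta_beta, stats$variance, cr)
  out <- data.frame(
    cr_id = sprintf("cr%06d", seq_along(first)),
    chrom = stats$chrom[first],
    start = stats$pos[first],
    end = stats$pos[last],
    n_sites = fb$m,
    direction = ifelse(!a$significant[first], "none",
                       ifelse(stats$delta_beta[first] > 0, "hyper", "hypo")),
    p_fisher = fb$p_fisher,
    p_perm = NA_real_,
    q_value = NA_real_,
    effect_size = eff,
    is_isolated = !a$significant[first],
    is_dmr = NA,
    stringsAsFactors = FALSE)
  attr(out, "site_cr") <- cr
  attr(out, "site_id") <- stats$site_id
  if (!is.null(stats$gene)) attr(out, "site_gene") <- stats$gene
  class(out) <- c("candidate_regions", "data.frame")
  out
}

# Inverse-variance weighted mean delta per region; regions containing a
# zero-variance member fall back to the unweighted mean (with one warning).
region_effects <- function(delta, variance, cr) {
  w <- 1 / variance
  bad <- !is.finite(w)
  if (any(bad)) {
    warning("zero sampling variance at ", sum(bad),
            " site(s); affected regions use the unweighted mean effect")
    bad_cr <- unique(cr[bad])
    w[cr %in% bad_cr] <- 1
  }
  as.vector(rowsum(w * delta, cr, reorder = TRUE) /
            rowsum(w, cr, reorder = TRUE))
}

#' Inverse-variance (fixed-effect) region effect size
#'
#' @param delta_beta Member-site effect sizes.
#' @param variance Member-site sampling variances (same length).
#' @return sum(w * d) / sum(w) with w = 1/variance; falls back to the
#'   unweighted mean (with a warning) if any variance is zero.
#' @export
region_effect_size <- function(delta_beta, variance) {
  stopifnot(length(delta_beta) == length(variance))
  if (any(variance == 0)) {
    warning("zero variance member; using unweighted mean")
    return(mean(delta_beta))
  }
  w <- 1 / variance
  sum(w * delta_beta) / sum(w)
}

#' Permutation null distribution of region p-values
#'
#' Subject group labels are permuted B times; in each permutation the site
#' tests are re-run on the (already smoothed) dataset, candidate regions are
#' rebuilt from scratch, and each permuted region receives a Fisher-combined
#' p-value. The pooled multiset of permuted region p-values, with the number
#' of regions per permutation, forms the null against which observed region
#' p-values are calibrated. Permutations are sampled uniformly with
#' replacement over the label-permutation space (the identity labeling may
#' recur); with `exhaustive = TRUE` every distinct group assignment is used
#' exactly once instead.
#'
#' @param dataset A smoothed [methylome] object.
#' @param B Number of permutations (ignored when `exhaustive`); default 500.
#' @param seed Integer seed for label shuffling.
#' @param site_alpha,max_gap_bp Region-building parameters, as in
#'   [build_candidate_regions()].
#' @param var_equal Passed to the site tests.
#' @param epsilon M-transform guard.
#' @param exhaustive Enumerate all distinct assignments of subjects to the
#'   two group sizes (only feasible for small cohorts).
#' @return list of class `permutation_null`: `pooled` (all permuted region
#'   p-values), `m_b` (regions per permutation), `B`, `seed`.
#' @export
permutation_null <- function(dataset, B = 500, seed = NULL,
                             site_alpha = 0.05, max_gap_bp = 1000,
                             var_equal = FALSE, epsilon = 1e-6,
                             exhaustive = FALSE) {
  if (!exhaustive && B < 1) stop("B must be >= 1")
  is_old <- dataset$subjects$group == "older"
  n <- length(is_old); n_old <- sum(is_old)
  M <- beta_to_m(dataset$beta, epsilon)
  chrom <- dataset$sites$chrom
  pos <- dataset$sites$pos
  if (!is.null(seed)) set.seed(seed)
  if (exhaustive) {
    if (choose(n, n_old) > 20000)
      stop("exhaustive enumeration infeasible for ", n, " subjects")
    assigns <- utils::combn(n, n_old, simplify = FALSE)
  } else {
    assigns <- replicate(B, sample.int(n, n_old), simplify = FALSE)
  }
  pooled <- vector("list", length(assigns))
  m_b <- integer(length(assigns))
  for (b in seq_along(assigns)) {
    perm_old <- logical(n); perm_old[assigns[[b]]] <- TRUE
    tm <- row_t_test(M, perm_old, var_equal = var_equal)
    delta <- tm$m1 - tm$m0  # M-scale difference; same sign as the t statistic
    a <- assign_cr_ids(chrom, pos, tm$p, delta, site_alpha, max_gap_bp)
    fb <- fisher_by_cr(tm$p, a$cr)
    pooled[[b]] <- fb$p_fisher
    m_b[b] <- length(fb$p_fisher)
  }
  structure(list(pooled = unlist(pooled), m_b = m_b,
                 B = length(assigns), seed = seed),
            class = "permutation_null")
}

#' Calibrate region p-values against the permutation null and control FDR
#'
#' The permuted p-value of region i is the fraction of pooled permuted region
#' p-values less than or equal to its Fisher-combined p-value (ties count).
#' Benjamini-Hochberg q-values are then computed jointly over all regions,
#' merged and isolated alike. A permuted p of exactly 0 is a one-sided bound
#' (< 1/total pooled); it enters BH as 0.5/total so q-values stay defined.
#'
#' @param regions A `candidate_regions` data.frame with `p_fisher` set.
#' @param null A `permutation_null` object.
#' @return `regions` with `p_perm` and `q_value` filled in.
#' @export
calibrate_and_fdr <- function(regions, null) {
  if (!length(null$pooled)) stop("empty permutation null pool")
  total <- length(null$pooled)
  sorted <- sort(null$pooled)
  p_perm <- findInterval(regions$p_fisher, sorted) / total
  regions$p_perm <- p_perm
  regions$q_value <- stats::p.adjust(pmax(p_perm, 0.5 / total), method = "BH")
  regions
}

#' Call differentially methylated regions
#'
#' A region is a DMR when its q-value is below `q_threshold` AND the absolute
#' region effect size exceeds `effect_threshold` (both strict).
#'
#' @param regions A `candidate_regions` data.frame with `q_value` and
#'   `effect_size` set.
#' @param q_threshold q-value cutoff; default 0.05.
#' @param effect_threshold absolute beta-scale effect cutoff; default 0.03
#'   (3 percent methylation).
#' @return `regions` with `is_dmr` set; a summary line (count, hyper/hypo
#'   split) is emitted as a message.
#' @export
call_dmrs <- function(regions, q_threshold = 0.05, effect_threshold = 0.03) {
  regions$is_dmr <- regions$q_value < q_threshold &
    abs(regions$effect_size) > effect_threshold
  n_hyper <- sum(regions$is_dmr & regions$effect_size > 0)
  n_hypo <- sum(regions$is_dmr & regions$effect_size < 0)
  message(sprintf("called %d DMRs among %d regions (%d hyper, %d hypo)",
                  sum(regions$is_dmr), nrow(regions), n_hyper, n_hypo))
  regions
}
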