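#' Fixed-effect meta-analysis of per-site effects from two datasets
#'
#' For each site present in both datasets, effect sizes are combined with
#' inverse-variance weights: effect = sum(w * d) / sum(w), variance =
#' 1 / sum(w), w = 1/variance. The combined p-value follows from the
#' fixed-effect z statistic (two-sided normal). Sites absent from either
#' dataset, or with zero variance in either, are dropped with a message.
#'
#' @param stats_a,stats_b `site_stats` data.frames from [site_test()] run on
#'   the two datasets (matched by `site_id`).
#' @return data.frame of class `meta_site_stats`: `site_id`, `chrom`, `pos`,
#'   `effect_meta`, `variance_meta`, `z_meta`, `p` (named `p` so region
#'   building applies unchanged), `delta_beta` (= `effect_meta`), `variance`
#'   (= `variance_meta`), `direction`, plus `gene` if annotated.
#' @export
meta_combine_sites <- function(stats_a, stats_b) {
  shared <- intersect(stats_a$site_id, stats_b$site_id)
  n_drop <- (nrow(stats_a) - length(shared)) + (nrow(stats_b) - length(shared))
  if (!length(shared)) stop("no shared sites between the two datasets")
  if (n_drop) message(n_drop, " site record(s) absent from one dataset dropped")
  a <- stats_a[match(shared, stats_a$site_id), , drop = FALSE]
  b <- stats_b[match(shared, stats_b$site_id), , drop = FALSE]
  ok <- a$variance > 0 & b$variance > 0
  if (any(!ok)) {
    warning(sum(!ok), " site(s) with zero sampling variance skipped")
    a <- a[ok, , drop = FALSE]; b <- b[ok, , drop = FALSE]
  }
  wa <- 1 / a$variance; wb <- 1 / b$variance
  eff <- (wa * a$delta_beta + wb * b$delta_beta) / (wa + wb)
  v <- 1 / (wa + wb)
  z <- eff / sqrt(v)
  p <- pmax(2 * stats::pnorm(-abs(z)), .Machine$double.xmin)
  out <- data.frame(site_id = a$site_id, chrom = a$chrom, pos = a$pos,
                    effect_meta = eff, variance_meta = v, z_meta = z,
                    p = p, delta_beta = eff, variance = v,
                    direction = ifelse(eff > 0, "hyper",
                                       ifelse(eff < 0, "hypo", NA)),
                    stringsAsFactors = FALSE)
  if (!is.null(a$gene)) out$gene <- a$gene
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("meta_site_stats", "site_stats", "data.frame")
  out
}

#' Define candidate regions from meta-analyzed site statistics
#'
#' Applies the single-dataset region procedure to the fixed-effect summaries:
#' sites significant at `site_alpha` on the meta p-value are merged under the
#' same gap and direction-concordance rules, region p-values come from
#' Fisher's method, and region effect sizes are inverse-variance means of the
#' meta effects. q-values are Benjamini-Hochberg over the Fisher-combined
#' p-values unless a permutation null (e.g. from
#' [meta_permutation_null()]) is supplied, in which case the permutation
#' calibration of the single-dataset pipeline is used.
#'
#' @param meta_stats Output of [meta_combine_sites()].
#' @param site_alpha,max_gap_bp As in [build_candidate_regions()].
#' @param null Optional `permutation_null` for calibration.
#' @return A `candidate_regions` data.frame (with `q_value` set; `p_perm` set
#'   only when `null` is supplied).
#' @export
meta_define_regions <- function(meta_stats, site_alpha = 0.05,
                                max_gap_bp = 1000, null = NULL) {
  regions <- build_candidate_regions(meta_stats, site_alpha = site_alpha,
                                     max_gap_bp = max_gap_bp)
  if (is.null(null)) {
    regions$q_value <- stats::p.adjust(regions$p_fisher, method = "BH")
  } else {
    regions <- calibrate_and_fdr(regions, null)
  }
  regions
}

#' Permutation null for meta-defined regions
#'
#' Permutes group labels independently within each dataset, recomputes both
#' sets of site statistics, meta-combines them and rebuilds regions, pooling
#' the permuted Fisher-combined region p-values.
#'
#' @param dataset_a,dataset_b Smoothed [methylome] objects of the two studies.
#' @param B Number of joint permutations.
#' @param seed Integer seed.
#' @param site_alpha,max_gap_bp,var_equal,epsilon As elsewhere.
#' @return A `permutation_null`.
#' @export
meta_permutation_null <- function(dataset_a, dataset_b, B = 500, seed = NULL,
                                  site_alpha = 0.05, max_gap_bp = 1000,
                                  var_equal = FALSE, epsilon = 1e-6) {
  if (B < 1) stop("B must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  perm_stats <- function(ds) {
    g <- sample(ds$subjects$group)
    ds$subjects$group <- g
    site_test(ds, var_equal = var_equal, epsilon = epsilon)
  }
  pooled <- vector("list", B); m_b <- integer(B)
  for (b in seq_len(B)) {
    ms <- meta_combine_sites(perm_stats(dataset_a), perm_stats(dataset_b))
    a <- assign_cr_ids(ms$chrom, ms$pos, ms$p, ms$delta_beta,
                       site_alpha, max_gap_bp)
    fb <- fisher_by_cr(ms$p, a$cr)
    pooled[[b]] <- fb$p_fisher
    m_b[b] <- length(fb$p_fisher)
  }
  structure(list(pooled = unlist(pooled), m_b = m_b, B = B, seed = seed),
            class = "permutation_null")
}
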