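#' Percentage to the reporting precision
#'
#' Ratio arithmetic used by the summary tables: 100 * numerator / denominator
#' rounded to one decimal. `NA` for a zero denominator (never 0/0 = 0).
#'
#' @param numerator,denominator Non-negative counts.
#' @export
pct <- function(numerator, denominator) {
  ifelse(denominator > 0, round(100 * numerator / denominator, 1), NA_real_)
}

#' Summarize the called DMR landscape
#'
#' Reports the funnel the analysis produces: how many analyzed sites fall
#' inside called aDMRs, what fraction of aDMRs (and of aDMR-associated sites)
#' is hypermethylated, and the per-context hypermethylation fractions when
#' context labels are supplied. Percentages are given to one decimal; raw
#' counts are kept alongside.
#'
#' @param regions A `candidate_regions` data.frame with `is_dmr` set.
#' @param stats The `site_stats` the regions were built from.
#' @param context Optional per-site context labels (same order as `stats`).
#' @return list of counts and percentages.
#' @export
summarize_dmr_landscape <- function(regions, stats, context = NULL) {
  site_cr <- attr(regions, "site_cr")
  in_dmr <- regions$is_dmr[site_cr] %in% TRUE
  n_dmr <- sum(regions$is_dmr, na.rm = TRUE)
  out <- list(
    n_sites = nrow(stats),
    n_regions = nrow(regions),
    n_dmrs = n_dmr,
    n_dmr_sites = sum(in_dmr),
    pct_sites_in_dmrs = pct(sum(in_dmr), nrow(stats)),
    n_dmrs_hyper = sum(regions$is_dmr & regions$effect_size > 0, na.rm = TRUE),
    pct_dmrs_hyper = pct(sum(regions$is_dmr & regions$effect_size > 0,
                             na.rm = TRUE), n_dmr),
    n_dmr_sites_hyper = sum(in_dmr & stats$delta_beta > 0),
    pct_dmr_sites_hyper = pct(sum(in_dmr & stats$delta_beta > 0), sum(in_dmr)))
  if (!is.null(context) && any(in_dmr)) {
    tab <- table(factor(context[in_dmr], levels = CPG_CONTEXTS),
                 factor(stats$direction[in_dmr], levels = c("hyper", "hypo")))
    out$context_hyper_pct <- pct(tab[, "hyper"], rowSums(tab))
  }
  out
}

#' Run the full aDMR analysis end to end
#'
#' filter -> smooth -> per-site tests -> candidate regions -> permutation
#' null -> FDR -> DMR calls -> expression links -> context and gene-set
#' enrichment. All stage outputs are written as TSV under `out_dir`, together
#' with a machine-readable `summary.json` recording the funnel (sites ->
#' regions -> aDMRs -> expression-correlating aDMRs), the seed and the
#' resolved parameters. Deterministic under a fixed seed.
#'
#' @param dataset A [methylome] object, or `NULL` to read from `beta_path`/
#'   `annotation_path`/`subjects_path`.
#' @param beta_path,annotation_path,subjects_path Input TSVs (used when
#'   `dataset` is NULL).
#' @param islands Optional island data.frame or BED path.
#' @param expr Optional expression matrix or TSV path.
#' @param gene_sets Optional named list of `gene_set` objects or file paths.
#' @param out_dir Output directory; `NULL` to skip writing.
#' @param filter Apply [filter_probes()] first; default TRUE.
#' @param site_alpha,max_gap_bp,window_bp,B,q_threshold,effect_threshold,min_abs_r
#'   Pipeline parameters (defaults 0.05, 1000 bp, 500 bp, 500 permutations,
#'   0.05, 0.03, 0.3).
#' @param var_equal Pooled-variance t-test instead of Welch.
#' @param seed Integer seed controlling the permutation null.
#' @return list with `stats`, `regions`, `null`, `links`, `context`,
#'   `context_test`, `gradient`, `enrichment`, `summary` (invisible).
#' @export
run_pipeline <- function(dataset = NULL,
                         beta_path = NULL, annotation_path = NULL,
                         subjects_path = NULL,
                         islands = NULL, expr = NULL, gene_sets = NULL,
                         out_dir = NULL, filter = TRUE,
                         site_alpha = 0.05, max_gap_bp = 1000,
                         window_bp = 500, B = 500,
                         q_threshold = 0.05, effect_threshold = 0.03,
                         min_abs_r = 0.3, var_equal = FALSE, seed = 1) {
  stopifnot(site_alpha > 0, site_alpha < 1, q_threshold > 0, q_threshold < 1,
            B >= 1)
  if (is.null(dataset))
    dataset <- read_methylome(beta_path, annotation_path, subjects_path)
  if (is.character(islands)) islands <- read_islands(islands)
  if (is.character(expr)) expr <- read_expression(expr)
  if (!is.null(gene_sets))
    gene_sets <- lapply(gene_sets, function(g)
      if (is.character(g)) read_gene_set(g) else g)

  if (filter) dataset <- filter_probes(dataset)
  smoothed <- smooth_beta(dataset, window_bp = window_bp)
  stats <- site_test(smoothed, var_equal = var_equal)
  regions <- build_candidate_regions(stats, site_alpha = site_alpha,
                                     max_gap_bp = max_gap_bp)
  null <- permutation_null(smoothed, B = B, seed = seed,
                           site_alpha = site_alpha, max_gap_bp = max_gap_bp,
                           var_equal = var_equal)
  regions <- calibrate_and_fdr(regions, null)
  regions <- call_dmrs(regions, q_threshold = q_threshold,
                       effect_threshold = effect_threshold)

  links <- NULL
  if (!is.null(expr)) {
    al <- align_subjects(smoothed, expr)
    links <- link_regions_to_expression(regions, al$dataset, al$expr,
                                        min_abs_r = min_abs_r)
  }
  context <- context_test <- gradient <- NULL
  if (!is.null(islands)) {
    context <- classify_context(stats$pos, stats$chrom, islands)
    in_dmr <- regions$is_dmr[attr(regions, "site_cr")] %in% TRUE
    if (any(in_dmr)) {
      context_test <- context_distribution_test(context, in_dmr)
      gradient <- hypermethylation_gradient(context[in_dmr],
                                            stats$direction[in_dmr])
    }
  }
  enrichment <- NULL
  if (!is.null(gene_sets)) {
    enrichment <- lapply(gene_sets, function(g)
      gene_set_enrichment(regions, g, feature = "admr"))
  }

  summary <- summarize_dmr_landscape(regions, stats, context)
  summary$n_expression_correlating <-
    if (is.null(links)) NA_integer_ else summarize_links(links, regions)$n_expression_correlating
  summary$seed <- seed
  summary$parameters <- list(site_alpha = site_alpha, max_gap_bp = max_gap_bp,
                             window_bp = window_bp, B = B,
                             q_threshold = q_threshold,
                             effect_threshold = effect_threshold,
                             min_abs_r = min_abs_r,
                             t_test = if (var_equal) "pooled" else "welch")

  res <- list(stats = stats, regions = regions, null = null, links = links,
              context = context, context_test = context_test,
              gradient = gradient, enrichment = enrichment, summary = summary)
  if (!is.null(out_dir)) write_run(res, out_dir)
  invisible(res)
}

write_run <- function(res, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  data.table::fwrite(res$stats, file.path(out_dir, "sitestats.tsv"), sep = "\t")
  data.table::fwrite(as.data.frame(res$regions),
                     file.path(out_dir, "regions.tsv"), sep = "\t")
  data.table::fwrite(data.frame(p = res$null$pooled,
                                permutation = rep(seq_along(res$null$m_b),
                                                  res$null$m_b)),
                     file.path(out_dir, "null_pool.tsv"), sep = "\t")
  if (!is.null(res$links))
    data.table::fwrite(res$links, file.path(out_dir, "expression_links.tsv"),
                       sep = "\t")
  if (!is.null(res$enrichment)) {
    enr <- do.call(rbind, lapply(res$enrichment, function(e)
      data.frame(set = e$set_name, a = e$table[1, 1], b = e$table[1, 2],
                 c = e$table[2, 1], d = e$table[2, 2],
                 odds_ratio = e$odds_ratio, p = e$p_value)))
    data.table::fwrite(enr, file.path(out_dir, "enrichment.tsv"), sep = "\t")
  }
  jsonlite::write_json(res$summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(res)
}
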