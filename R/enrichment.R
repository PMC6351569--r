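CPG_CONTEXTS <- c("island", "shore_north", "shore_south",
                  "shelf_north", "shelf_south", "sea")

#' Classify genomic positions into CpG island / shore / shelf / sea
#'
#' A position inside an island is `island`; within 2000 bp outside an island
#' edge it is a shore; within 2000-4000 bp a shelf; anything farther is
#' `sea`. North is the lower-coordinate side of the nearest island, south the
#' higher-coordinate side. When flanks of two islands overlap, the nearest
#' island wins (so island > shore > shelf); exact distance ties resolve to
#' the south flank of the lower-coordinate island.
#'
#' @param position,chromosome Vectors of 1-based positions and chromosome
#'   names (recycled to common length).
#' @param islands data.frame `chrom`, `start`, `end` (1-based inclusive,
#'   non-overlapping per chromosome; see [read_islands()]).
#' @return Character vector of context labels.
#' @export
classify_context <- function(position, chromosome, islands) {
  n <- max(length(position), length(chromosome))
  position <- rep_len(position, n); chromosome <- rep_len(chromosome, n)
  out <- rep("sea", n)
  for (ch in unique(chromosome)) {
    idx <- which(chromosome == ch)
    isl <- islands[islands$chrom == ch, , drop = FALSE]
    if (!nrow(isl)) next
    isl <- isl[order(isl$start), , drop = FALSE]
    p <- position[idx]
    k <- findInterval(p, isl$start)  # index of nearest island at or left of p
    inside <- k >= 1L & p <= ifelse(k >= 1L, isl$end[pmax(k, 1L)], 0L)
    d_left <- ifelse(k >= 1L, p - isl$end[pmax(k, 1L)], Inf)     # past an island's end
    d_right <- ifelse(k < nrow(isl), isl$start[pmin(k + 1L, nrow(isl))] - p, Inf)
    use_left <- d_left <= d_right  # tie resolves to the lower-coordinate island
    d <- pmin(d_left, d_right)
    lab <- rep("sea", length(p))
    lab[d <= 4000] <- ifelse(use_left[d <= 4000], "shelf_south", "shelf_north")
    lab[d <= 2000] <- ifelse(use_left[d <= 2000], "shore_south", "shore_north")
    lab[inside] <- "island"
    out[idx] <- lab
  }
  out
}

sample_odds_ratio <- function(a, b, c, d) {
  if (b * c == 0 && a * d == 0) return(NaN)
  if (b * c == 0) return(Inf)
  (a * d) / (b * c)
}

enrichment_result <- function(set_name, a, b, c, d) {
  tab <- matrix(c(a, b, c, d), nrow = 2, byrow = TRUE,
                dimnames = list(c("in_set", "not_in_set"),
                                c("feature", "no_feature")))
  or <- sample_odds_ratio(a, b, c, d)
  p <- stats::fisher.test(tab)$p.value
  structure(list(set_name = set_name, table = tab, odds_ratio = or,
                 p_value = p, degenerate = !is.finite(or)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment '%s': OR = %.3g, p = %.3g%s\n", x$set_name,
              x$odds_ratio, x$p_value,
              if (x$degenerate) " (degenerate table)" else ""))
  print(x$table)
  invisible(x)
}

#' Test the distribution of feature sites across CpG contexts
#'
#' Chi-square goodness-of-fit of the feature sites' context counts against
#' expected counts from the context distribution of all analyzed sites, plus
#' a per-context 2x2 enrichment (in-context vs not, feature vs not) with the
#' sample odds ratio and two-sided Fisher's exact p.
#'
#' @param context Character vector of context labels for all analyzed sites.
#' @param is_feature Logical vector: which sites carry the feature (e.g. lie
#'   inside a called aDMR).
#' @return list: `chi2`, `df`, `p`, `observed`, `expected`, and
#'   `per_context` (named list of `enrichment_result`).
#' @export
context_distribution_test <- function(context, is_feature) {
  if (!any(is_feature)) stop("no feature sites")
  ctx <- factor(context, levels = CPG_CONTEXTS)
  bg <- table(ctx)
  obs <- table(ctx[is_feature])
  use <- bg > 0
  if (any(!use)) message("context(s) absent from background dropped: ",
                         paste(names(bg)[!use], collapse = ", "))
  prop <- bg[use] / sum(bg)
  gof <- stats::chisq.test(as.vector(obs[use]), p = as.vector(prop))
  # per-context table orientation: rows in-context vs not, cols feature vs not
  per <- lapply(names(bg)[use], function(cx) {
    a <- sum(ctx == cx & is_feature); b <- sum(ctx == cx & !is_feature)
    c_ <- sum(ctx != cx & is_feature); d <- sum(ctx != cx & !is_feature)
    enrichment_result(cx, a, b, c_, d)
  })
  names(per) <- names(bg)[use]
  list(chi2 = unname(gof$statistic), df = unname(gof$parameter),
       p = gof$p.value, observed = obs[use],
       expected = unname(gof$expected), per_context = per)
}

#' Hypermethylation fraction by CpG context
#'
#' Computes, per context, the fraction of feature sites that are
#' hypermethylated (older > younger) and tests homogeneity of those fractions
#' across contexts with a chi-square test on the context x direction table
#' (no continuity correction).
#'
#' @param context Context labels of the feature (aDMR-associated) sites.
#' @param direction Their directions (`"hyper"`/`"hypo"`).
#' @return list: `fractions` (named hyper fractions), `counts` (context x
#'   direction table), `chi2`, `df`, `p`. Contexts with no sites are dropped
#'   with a message.
#' @export
hypermethylation_gradient <- function(context, direction) {
  ctx <- factor(context, levels = CPG_CONTEXTS)
  dir <- factor(direction, levels = c("hyper", "hypo"))
  tab <- table(ctx, dir)
  empty <- rowSums(tab) == 0
  if (any(empty)) {
    message("context(s) with no feature sites dropped: ",
            paste(rownames(tab)[empty], collapse = ", "))
    tab <- tab[!empty, , drop = FALSE]
  }
  frac <- tab[, "hyper"] / rowSums(tab)
  ht <- stats::chisq.test(tab, correct = FALSE)
  list(fractions = frac, counts = tab,
       chi2 = unname(ht$statistic), df = unname(ht$parameter), p = ht$p.value)
}

#' Gene-set enrichment in regions carrying a feature
#'
#' Builds the gene-level 2x2 table (in-set vs not x carries-feature vs not)
#' over the universe of genes annotated to at least one analyzed region; a
#' gene carries the feature when at least one of its regions has it. Reports
#' the sample (cross-product) odds ratio and the two-sided Fisher's exact p.
#'
#' @param regions A `candidate_regions` data.frame with `is_dmr` set.
#' @param set A `gene_set` (see [read_gene_set()]).
#' @param feature One of `"admr"`, `"expr_admr"`, `"hyper_admr"`,
#'   `"hypo_admr"`. `"expr_admr"` requires `links`.
#' @param links Optional `region_expression_links` (for `"expr_admr"`).
#' @param universe Optional character vector restricting the gene universe;
#'   default: all genes annotated to the regions.
#' @return An `enrichment_result`.
#' @export
gene_set_enrichment <- function(regions, set,
                                feature = c("admr", "expr_admr",
                                            "hyper_admr", "hypo_admr"),
                                links = NULL, universe = NULL) {
  feature <- match.arg(feature)
  gene_of <- region_genes(regions)
  if (is.null(universe)) universe <- unique(unlist(gene_of))
  universe <- unique(normalize_gene(universe))
  universe <- universe[!is.na(universe) & nzchar(universe)]
  carriers <- feature_carriers(regions, gene_of, feature, links)
  set_genes <- intersect(normalize_gene(set$genes), universe)
  dropped <- length(set$genes) - length(set_genes)
  if (dropped) message(dropped, " set gene(s) outside the analyzed universe dropped")
  if (!length(set_genes))
    stop("gene set '", set$name, "' has no genes in the analyzed universe")
  if (setequal(set_genes, universe)) stop("set equals universe")
  a <- length(intersect(set_genes, carriers))
  b <- length(setdiff(set_genes, carriers))
  c_ <- length(intersect(setdiff(universe, set_genes), carriers))
  d <- length(universe) - a - b - c_
  enrichment_result(set$name, a, b, c_, d)
}

# per-region annotated gene list from the region's member sites
region_genes <- function(regions) {
  site_cr <- attr(regions, "site_cr")
  gene <- attr(regions, "site_gene")
  if (is.null(gene)) stop("regions lack site gene annotation")
  split(normalize_gene(gene), site_cr)
}

feature_carriers <- function(regions, gene_of, feature, links) {
  has <- switch(feature,
    admr = regions$is_dmr %in% TRUE,
    hyper_admr = regions$is_dmr %in% TRUE & regions$effect_size > 0,
    hypo_admr = regions$is_dmr %in% TRUE & regions$effect_size < 0,
    expr_admr = {
      if (is.null(links)) stop("feature 'expr_admr' requires expression links")
      regions$cr_id %in%
        links$cr_id[links$is_expression_correlating]
    })
  g <- unique(unlist(gene_of[as.character(which(has))]))
  g[!is.na(g)]
}
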