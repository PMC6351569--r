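#' Link candidate regions to local gene expression
#'
#' For every region annotated to a gene present in the expression matrix, the
#' Pearson correlation (across subjects) between each member site's
#' methylation and that gene's expression is computed, and the region is
#' represented by the member site with maximal |r| (sign retained). A region
#' annotated to several genes yields one link per gene; its
#' expression-correlating flag uses the best gene. The flag requires
#' |r| >= `min_abs_r` and the region to be a called DMR.
#'
#' @param regions A `candidate_regions` data.frame (with `is_dmr` set for
#'   flagging; regions with `is_dmr` NA are treated as non-DMRs).
#' @param dataset The [methylome] whose beta values the regions were built
#'   from (subjects aligned with `expr`).
#' @param expr Expression matrix genes x subjects, subjects in the dataset's
#'   order (see [align_subjects()]).
#' @param min_abs_r Correlation threshold; default 0.3.
#' @return data.frame of class `region_expression_links`: `cr_id`, `gene`,
#'   `best_site_id`, `r`, `n_subjects`, `is_expression_correlating`.
#'   Zero-variance site or gene vectors are skipped with a message.
#' @export
link_regions_to_expression <- function(regions, dataset, expr, min_abs_r = 0.3) {
  if (!identical(colnames(expr), dataset$subjects$subject_id))
    stop("expression subjects are not aligned to the methylome; ",
         "run align_subjects() first")
  site_cr <- attr(regions, "site_cr")
  site_id <- attr(regions, "site_id")
  if (is.null(site_cr))
    stop("regions lack their site map; pass the object from build_candidate_regions()")
  ord <- match(site_id, dataset$sites$site_id)
  gene <- normalize_gene(dataset$sites$gene[ord])
  keep <- !is.na(gene) & gene %in% rownames(expr)
  n_skip <- sum(!keep)
  if (n_skip) message(n_skip, " site(s) without expressed annotated gene skipped")
  if (!any(keep))
    return(empty_links())

  B <- dataset$beta[ord[keep], , drop = FALSE]
  E <- expr[gene[keep], , drop = FALSE]
  n <- ncol(B)
  zb <- B - rowMeans(B)
  ze <- E - rowMeans(E)
  sb <- sqrt(rowSums(zb^2)); se <- sqrt(rowSums(ze^2))
  r <- rowSums(zb * ze) / (sb * se)
  degen <- sb == 0 | se == 0
  if (any(degen)) {
    message(sum(degen), " pair(s) with zero variance skipped")
    r[degen] <- NA_real_
  }

  d <- data.frame(cr = site_cr[keep], gene = gene[keep],
                  site_id = site_id[keep], r = r, stringsAsFactors = FALSE)
  d <- d[!is.na(d$r), , drop = FALSE]
  if (!nrow(d)) return(empty_links())
  d <- d[order(d$cr, d$gene, -abs(d$r)), , drop = FALSE]
  best <- d[!duplicated(d[, c("cr", "gene")]), , drop = FALSE]
  is_dmr <- regions$is_dmr[best$cr]
  is_dmr[is.na(is_dmr)] <- FALSE
  links <- data.frame(cr_id = regions$cr_id[best$cr],
                      gene = best$gene,
                      best_site_id = best$site_id,
                      r = best$r,
                      n_subjects = n,
                      is_expression_correlating =
                        abs(best$r) >= min_abs_r & is_dmr,
                      stringsAsFactors = FALSE)
  rownames(links) <- NULL
  class(links) <- c("region_expression_links", "data.frame")
  links
}

empty_links <- function() {
  structure(data.frame(cr_id = character(0), gene = character(0),
                       best_site_id = character(0), r = numeric(0),
                       n_subjects = integer(0),
                       is_expression_correlating = logical(0),
                       stringsAsFactors = FALSE),
            class = c("region_expression_links", "data.frame"))
}

#' Summarize region-expression links
#'
#' @param links Output of [link_regions_to_expression()].
#' @param regions The matching `candidate_regions`.
#' @return list with counts: `n_regions`, `n_dmrs`, `n_expression_correlating`
#'   (regions whose best gene passes the flag), `n_genes_with_dmr`,
#'   `n_genes_expression_correlating`.
#' @export
summarize_links <- function(links, regions) {
  flagged <- links[links$is_expression_correlating, , drop = FALSE]
  list(n_regions = nrow(regions),
       n_dmrs = sum(regions$is_dmr, na.rm = TRUE),
       n_expression_correlating = length(unique(flagged$cr_id)),
       n_genes_with_dmr = length(unique(
         links$gene[links$cr_id %in% regions$cr_id[regions$is_dmr %in% TRUE]])),
       n_genes_expression_correlating = length(unique(flagged$gene)))
}
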