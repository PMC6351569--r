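#' Simulation configuration for synthetic methylome studies
#'
#' Defines the study conditions a synthetic dataset emulates: a two-group
#' cohort (default 20 younger + 19 older subjects, the design the region
#' caller is built for), spatially clustered CpG sites, beta-distributed
#' methylation with a single concentration (precision) noise knob, implanted
#' group-difference regions, methylation-expression coupling and gene sets
#' with configurable enrichment.
#'
#' @param n_sites Total number of sites to generate.
#' @param n_subjects_young,n_subjects_old Group sizes; defaults 20 and 19.
#' @param n_chromosomes Number of chromosomes sites are spread over.
#' @param cluster_size_mean Mean cluster size (geometric: 1 + Geom); default 4.
#' @param intra_gap_mean Mean gap in bp between neighbouring sites of one
#'   cluster; default 200 (well under the 1000-bp merging rule).
#' @param inter_gap_mean Mean gap in bp between clusters; default 5000
#'   (well over the merging rule, so clusters are merge units).
#' @param concentration Beta-distribution precision; default 100
#'   (array-like noise, SD about 0.03 at mean 0.5).
#' @param dmr_specs List of implanted-region specs from [dmr_spec()]; empty
#'   list for a global-null dataset.
#' @param island_fraction Fraction of clusters covered by a CpG island.
#' @param n_coupled_genes Number of implanted-region genes whose expression is
#'   coupled to methylation of a member site.
#' @param target_r Target Pearson correlation for coupled pairs, in \[-1, 1\].
#' @param n_genes_in_set Size of the generated gene sets.
#' @param geneset_dmr_fraction Fraction of enriched-set genes drawn from genes
#'   overlapping implanted regions.
#' @param seed Integer seed; identical config + seed reproduces the dataset
#'   bit for bit.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_sites = 20000,
                       n_subjects_young = 20, n_subjects_old = 19,
                       n_chromosomes = 4,
                       cluster_size_mean = 4,
                       intra_gap_mean = 200,
                       inter_gap_mean = 5000,
                       concentration = 100,
                       dmr_specs = list(),
                       island_fraction = 0.3,
                       n_coupled_genes = length(dmr_specs),
                       target_r = -0.7,
                       n_genes_in_set = 40,
                       geneset_dmr_fraction = 0.25,
                       seed = 1) {
  cfg <- list(n_sites = n_sites, n_subjects_young = n_subjects_young,
              n_subjects_old = n_subjects_old, n_chromosomes = n_chromosomes,
              cluster_size_mean = cluster_size_mean,
              intra_gap_mean = intra_gap_mean, inter_gap_mean = inter_gap_mean,
              concentration = concentration, dmr_specs = dmr_specs,
              island_fraction = island_fraction,
              n_coupled_genes = n_coupled_genes, target_r = target_r,
              n_genes_in_set = n_genes_in_set,
              geneset_dmr_fraction = geneset_dmr_fraction, seed = seed)
  counts <- c(n_sites, n_subjects_young, n_subjects_old, n_chromosomes)
  if (any(counts < 1)) stop("all counts must be > 0")
  if (concentration <= 0) stop("concentration must be positive")
  if (abs(target_r) > 1) stop("target correlation must be in [-1, 1]")
  if (island_fraction < 0 || island_fraction > 1)
    stop("island_fraction must be in [0, 1]")
  for (spec in dmr_specs) {
    if (abs(spec$delta_beta) >= 1) stop("|delta_beta| must be < 1")
    if (spec$n_sites < 1) stop("dmr_spec n_sites must be > 0")
    # a baseline mean must exist with mean and mean + delta both in the
    # clipping margin [0.05, 0.95]
    if (max(0.05, 0.05 - spec$delta_beta) > min(0.95, 0.95 - spec$delta_beta))
      stop("delta_beta ", spec$delta_beta,
           " leaves no admissible baseline mean within [0.05, 0.95]")
  }
  structure(cfg, class = "sim_config")
}

#' Implanted differentially methylated region specification
#'
#' @param n_sites Number of member sites.
#' @param delta_beta Signed group difference (older - younger) on the beta
#'   scale, |delta_beta| < 1.
#' @param span_bp Genomic span of the implanted sites; default 400 bp so
#'   member gaps stay below the merging rule.
#' @export
dmr_spec <- function(n_sites = 5, delta_beta = 0.10, span_bp = 400) {
  list(n_sites = as.integer(n_sites), delta_beta = delta_beta,
       span_bp = as.integer(span_bp))
}

#' Generate a synthetic methylome with known ground truth
#'
#' Sites are laid out as clusters along chromosomes (geometric cluster sizes,
#' exponential intra/inter-cluster gaps). Outside implanted regions the two
#' groups share one per-site mean; inside, the older-group mean is shifted by
#' its region spec's `delta_beta`. All true means are kept within \[0.05, 0.95\]
#' before beta noise is added. Each cluster carries one synthetic gene id;
#' a configurable fraction of clusters is covered by a CpG island interval.
#'
#' @param config A [sim_config].
#' @return list(dataset, truth): `dataset` is a [methylome]; `truth` is a list
#'   of class `sim_truth` with `regions` (implanted intervals with their
#'   signed delta), `dmr_genes`, `genes` (full synthetic gene universe),
#'   `islands`, `site_cluster`, `mu_young`, `mu_old`.
#' @export
generate_methylome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  specs <- config$dmr_specs
  n_dmr_sites <- sum(vapply(specs, `[[`, integer(1L), "n_sites"))
  if (n_dmr_sites >= config$n_sites)
    stop("implanted regions require more sites than n_sites allows")

  # background cluster skeleton, then implanted clusters inserted at random
  sizes <- integer(0)
  while (sum(sizes) < config$n_sites - n_dmr_sites)
    sizes <- c(sizes, 1L + stats::rgeom(256L, 1 / config$cluster_size_mean))
  excess <- sum(sizes) - (config$n_sites - n_dmr_sites)
  while (excess > 0) {
    if (sizes[length(sizes)] > excess) {
      sizes[length(sizes)] <- sizes[length(sizes)] - excess
      excess <- 0L
    } else {
      excess <- excess - sizes[length(sizes)]
      sizes <- sizes[-length(sizes)]
    }
  }
  is_dmr_cluster <- logical(length(sizes))
  spec_of_cluster <- rep(NA_integer_, length(sizes))
  if (length(specs)) {
    slots <- sort(sample.int(length(sizes) + length(specs), length(specs)))
    full_n <- length(sizes) + length(specs)
    is_dmr_cluster <- logical(full_n)
    is_dmr_cluster[slots] <- TRUE
    spec_of_cluster <- rep(NA_integer_, full_n)
    spec_of_cluster[slots] <- sample(length(specs))
    tmp <- integer(full_n)
    tmp[!is_dmr_cluster] <- sizes
    tmp[is_dmr_cluster] <- vapply(specs[spec_of_cluster[slots]], `[[`,
                                  integer(1L), "n_sites")
    sizes <- tmp
  }
  n_clusters <- length(sizes)

  # contiguous blocks of clusters per chromosome
  chrom_of_cluster <- sort(rep_len(seq_len(config$n_chromosomes), n_clusters))
  pos <- integer(0); chrom <- character(0); site_cluster <- integer(0)
  cl_start <- integer(n_clusters); cl_end <- integer(n_clusters)
  for (ch in seq_len(config$n_chromosomes)) {
    cur <- 10000L
    for (k in which(chrom_of_cluster == ch)) {
      cur <- cur + 1L + as.integer(stats::rexp(1L, 1 / config$inter_gap_mean))
      if (is_dmr_cluster[k] && sizes[k] > 1L) {
        span <- specs[[spec_of_cluster[k]]]$span_bp
        p <- cur + as.integer(round(seq(0, span, length.out = sizes[k])))
      } else {
        gaps <- 1L + as.integer(stats::rexp(sizes[k] - 1L,
                                            1 / config$intra_gap_mean))
        p <- cur + c(0L, cumsum(gaps))
      }
      cl_start[k] <- p[1L]; cl_end[k] <- p[length(p)]
      pos <- c(pos, p)
      chrom <- c(chrom, rep.int(paste0("chr", ch), sizes[k]))
      site_cluster <- c(site_cluster, rep.int(k, sizes[k]))
      cur <- p[length(p)]
    }
  }

  # per-cluster baseline means with per-site jitter, clipped to [0.05, 0.95];
  # implanted clusters draw a baseline admissible for their delta
  cl_mu <- stats::runif(n_clusters, 0.10, 0.90)
  for (k in which(is_dmr_cluster)) {
    d <- specs[[spec_of_cluster[k]]]$delta_beta
    lo <- max(0.05, 0.05 - d); hi <- min(0.95, 0.95 - d)
    cl_mu[k] <- stats::runif(1L, lo, hi)
  }
  mu <- cl_mu[site_cluster] + stats::rnorm(length(pos), 0, 0.02)
  delta_site <- numeric(length(pos))
  in_dmr <- is_dmr_cluster[site_cluster]
  delta_site[in_dmr] <- vapply(specs[spec_of_cluster[site_cluster[in_dmr]]],
                               `[[`, numeric(1L), "delta_beta")
  mu_young <- pmin(pmax(mu, 0.05), 0.95)
  mu_young[in_dmr] <- pmin(pmax(mu[in_dmr], 0.05 + pmax(0, -delta_site[in_dmr])),
                           0.95 - pmax(0, delta_site[in_dmr]))
  mu_old <- mu_young + delta_site

  n_y <- config$n_subjects_young; n_o <- config$n_subjects_old
  n_sites <- length(pos)
  conc <- config$concentration
  rb <- function(m, n) {
    x <- stats::rbeta(length(m) * n, rep(m * conc, n), rep((1 - m) * conc, n))
    matrix(pmin(pmax(x, 1e-6), 1 - 1e-6), nrow = length(m))
  }
  beta <- cbind(rb(mu_young, n_y), rb(mu_old, n_o))

  genes <- sprintf("G%05d", seq_len(n_clusters))
  sites <- data.frame(site_id = sprintf("s%06d", seq_len(n_sites)),
                      chrom = chrom, pos = pos, flags = "",
                      gene = genes[site_cluster], stringsAsFactors = FALSE)
  subjects <- data.frame(
    subject_id = c(sprintf("Y%02d", seq_len(n_y)), sprintf("O%02d", seq_len(n_o))),
    group = rep(c("younger", "older"), c(n_y, n_o)),
    stringsAsFactors = FALSE)
  dataset <- methylome(beta, sites, subjects)

  island_cl <- which(stats::runif(n_clusters) < config$island_fraction)
  islands <- data.frame(chrom = sprintf("chr%d", chrom_of_cluster[island_cl]),
                        start = pmax(1L, cl_start[island_cl] - 50L),
                        end = cl_end[island_cl] + 50L,
                        stringsAsFactors = FALSE)
  islands <- merge_islands(islands[order(islands$chrom, islands$start), ,
                                   drop = FALSE])

  dmr_cl <- which(is_dmr_cluster)
  regions <- data.frame(
    chrom = sprintf("chr%d", chrom_of_cluster[dmr_cl]),
    start = cl_start[dmr_cl], end = cl_end[dmr_cl],
    delta_beta = vapply(specs[spec_of_cluster[dmr_cl]], `[[`, numeric(1L),
                        "delta_beta"),
    gene = genes[dmr_cl], stringsAsFactors = FALSE)
  truth <- structure(list(regions = regions,
                          dmr_genes = genes[dmr_cl],
                          genes = genes,
                          islands = islands,
                          site_cluster = site_cluster,
                          mu_young = mu_young, mu_old = mu_old),
                     class = "sim_truth")
  list(dataset = dataset, truth = truth)
}

#' Generate expression coupled to implanted-region methylation
#'
#' For each coupled (site, gene) pair the gene's expression is a linear blend
#' of the site's standardized beta values and independent noise so that the
#' population correlation equals the target r; all other genes are
#' independent Gaussian noise. Coupled sites are the central member sites of
#' implanted regions (their cluster gene is the coupled gene).
#'
#' @param dataset A [methylome] from [generate_methylome()].
#' @param truth The matching `sim_truth`.
#' @param config The [sim_config] (uses `n_coupled_genes`, `target_r`, `seed`).
#' @return Expression matrix genes x subjects; coupled pairs are recorded in
#'   attribute `coupled` (data.frame site_id, gene, target_r).
#' @export
generate_expression <- function(dataset, truth, config) {
  set.seed(config$seed + 1L)
  n_sub <- nrow(dataset$subjects)
  genes <- truth$genes
  expr <- matrix(stats::rnorm(length(genes) * n_sub, mean = 7, sd = 2),
                 nrow = length(genes),
                 dimnames = list(genes, dataset$subjects$subject_id))
  n_cpl <- min(config$n_coupled_genes, nrow(truth$regions))
  coupled <- data.frame(site_id = character(0), gene = character(0),
                        target_r = numeric(0), stringsAsFactors = FALSE)
  if (n_cpl > 0) {
    reg_idx <- sample.int(nrow(truth$regions), n_cpl)
    for (i in reg_idx) {
      g <- truth$regions$gene[i]
      members <- which(dataset$sites$gene == g)
      site <- members[ceiling(length(members) / 2)]
      v <- dataset$beta[site, ]
      if (stats::sd(v) == 0)
        stop("cannot couple zero-variance methylation site '",
             dataset$sites$site_id[site], "'")
      z <- as.vector(scale(v))
      r <- config$target_r
      expr[g, ] <- 7 + 2 * (r * z + sqrt(1 - r^2) * stats::rnorm(n_sub))
      coupled <- rbind(coupled,
                       data.frame(site_id = dataset$sites$site_id[site],
                                  gene = g, target_r = r,
                                  stringsAsFactors = FALSE))
    }
  }
  attr(expr, "coupled") <- coupled
  expr
}

#' Generate gene sets with configured implanted-region enrichment
#'
#' Builds an "enriched" set drawing the configured fraction of its genes from
#' genes overlapping implanted regions (the rest from background genes), and
#' a size-matched "background" control set sampled uniformly from the whole
#' gene universe.
#'
#' @param truth A `sim_truth`.
#' @param config The [sim_config] (uses `n_genes_in_set`,
#'   `geneset_dmr_fraction`, `seed`).
#' @param seed Optional override of the sampling seed.
#' @return list(enriched, background) of `gene_set` objects.
#' @export
generate_gene_sets <- function(truth, config, seed = config$seed + 2L) {
  set.seed(seed)
  n_set <- config$n_genes_in_set
  if (n_set > length(truth$genes)) stop("n_genes_in_set exceeds gene universe")
  if (n_set == 0)
    return(list(enriched = structure(list(name = "enriched", genes = character(0)),
                                     class = "gene_set"),
                background = structure(list(name = "background", genes = character(0)),
                                       class = "gene_set")))
  n_dmr <- round(config$geneset_dmr_fraction * n_set)
  if (n_dmr > length(truth$dmr_genes))
    stop("requested overlap (", n_dmr, " genes) exceeds the ",
         length(truth$dmr_genes), " implanted-region genes available")
  bg_pool <- setdiff(truth$genes, truth$dmr_genes)
  if (n_set - n_dmr > length(bg_pool)) stop("not enough background genes")
  enriched <- c(sample(truth$dmr_genes, n_dmr),
                sample(bg_pool, n_set - n_dmr))
  background <- sample(truth$genes, n_set)
  list(enriched = structure(list(name = "enriched", genes = sort(enriched)),
                            class = "gene_set"),
       background = structure(list(name = "background", genes = sort(background)),
                              class = "gene_set"))
}

#' Generate a full synthetic study and optionally write it to disk
#'
#' Convenience wrapper chaining [generate_methylome()],
#' [generate_expression()] and [generate_gene_sets()]. When `dir` is given,
#' writes the same delimited formats the readers consume (beta/annotation/
#' subject TSVs, island BED, gene-set text files) plus `ground_truth.json`.
#'
#' @param config A [sim_config].
#' @param dir Optional output directory.
#' @return list(dataset, truth, expr, gene_sets).
#' @export
simulate_study <- function(config, dir = NULL) {
  gm <- generate_methylome(config)
  expr <- generate_expression(gm$dataset, gm$truth, config)
  sets <- generate_gene_sets(gm$truth, config)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_methylome(gm$dataset,
                    file.path(dir, "beta.tsv"),
                    file.path(dir, "annotation.tsv"),
                    file.path(dir, "subjects.tsv"))
    isl <- gm$truth$islands
    data.table::fwrite(data.frame(isl$chrom, isl$start - 1L, isl$end,
                                  sprintf("island%04d", seq_len(nrow(isl)))),
                       file.path(dir, "islands.bed"),
                       sep = "\t", col.names = FALSE)
    data.table::fwrite(data.frame(gene = rownames(expr), expr,
                                  check.names = FALSE),
                       file.path(dir, "expression.tsv"), sep = "\t")
    writeLines(sets$enriched$genes, file.path(dir, "geneset_enriched.txt"))
    writeLines(sets$background$genes, file.path(dir, "geneset_background.txt"))
    jsonlite::write_json(
      list(regions = gm$truth$regions, dmr_genes = gm$truth$dmr_genes,
           coupled = attr(expr, "coupled")),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  list(dataset = gm$dataset, truth = gm$truth, expr = expr, gene_sets = sets)
}
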