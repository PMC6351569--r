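#' Construct a methylome dataset
#'
#' Bundles a beta-value matrix (sites x subjects), per-site annotation and
#' subject group labels into a validated `methylome` object, the central
#' container of the package. Sites are sorted by (chromosome, position);
#' ties on position keep their input order.
#'
#' @param beta Numeric matrix, sites x subjects, values in \[0, 1\].
#' @param sites data.frame with columns `site_id`, `chrom`, `pos` (1-based bp)
#'   and optionally `flags` (semicolon-joined QC flags among
#'   `poor_hybridization`, `snp_overlap`, `multi_mapping`, `sex_chromosome`),
#'   `gene` (symbol or NA) and `context`.
#' @param subjects data.frame with columns `subject_id` and `group`
#'   (`"younger"` or `"older"`).
#' @return An object of class `methylome`: a list with elements `beta`,
#'   `sites`, `subjects`.
#' @export
methylome <- function(beta, sites, subjects) {
  beta <- as.matrix(beta)
  storage.mode(beta) <- "double"
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  subjects <- as.data.frame(subjects, stringsAsFactors = FALSE)

  req <- c("site_id", "chrom", "pos")
  if (!all(req %in% names(sites)))
    stop("site annotation must have columns: ", paste(req, collapse = ", "))
  if (!all(c("subject_id", "group") %in% names(subjects)))
    stop("subjects must have columns subject_id, group")
  if (is.null(sites$flags)) sites$flags <- ""
  sites$flags[is.na(sites$flags)] <- ""
  if (is.null(sites$gene)) sites$gene <- NA_character_
  if (nrow(beta) != nrow(sites))
    stop("beta has ", nrow(beta), " rows but annotation has ", nrow(sites), " sites")
  if (ncol(beta) != nrow(subjects))
    stop("beta has ", ncol(beta), " columns but ", nrow(subjects), " subjects given")
  if (anyDuplicated(sites$site_id))
    stop("duplicate site_id: ", sites$site_id[duplicated(sites$site_id)][1L])
  if (anyDuplicated(subjects$subject_id))
    stop("duplicate subject_id: ", subjects$subject_id[duplicated(subjects$subject_id)][1L])
  bad_group <- setdiff(unique(subjects$group), c("younger", "older"))
  if (length(bad_group))
    stop("unknown group label: ", paste(bad_group, collapse = ", "),
         " (expected 'younger'/'older')")
  if (anyNA(beta) || any(!is.finite(beta)))
    stop("beta matrix contains missing or non-finite values; imputation is not supported")
  bad <- which(beta < 0 | beta > 1, arr.ind = TRUE)
  if (nrow(bad)) {
    stop(sprintf("beta value %.4g outside [0,1] at site '%s', subject '%s'",
                 beta[bad[1L, 1L], bad[1L, 2L]],
                 sites$site_id[bad[1L, 1L]],
                 subjects$subject_id[bad[1L, 2L]]))
  }

  ord <- order(sites$chrom, sites$pos)  # stable: position ties keep input order
  sites <- sites[ord, , drop = FALSE]
  beta <- beta[ord, , drop = FALSE]
  rownames(beta) <- sites$site_id
  colnames(beta) <- subjects$subject_id
  rownames(sites) <- NULL
  structure(list(beta = beta, sites = sites, subjects = subjects),
            class = "methylome")
}

#' @export
print.methylome <- function(x, ...) {
  cat("methylome dataset:", nrow(x$beta), "sites x", ncol(x$beta), "subjects\n")
  cat("  chromosomes:", length(unique(x$sites$chrom)),
      " | younger:", sum(x$subjects$group == "younger"),
      " older:", sum(x$subjects$group == "older"), "\n")
  invisible(x)
}

#' Read a methylome dataset from delimited files
#'
#' @param beta_path TSV: first column `site_id`, remaining columns one per
#'   subject, beta values in \[0, 1\].
#' @param annotation_path TSV with columns `site_id`, `chrom`, `pos`, `flags`
#'   (semicolon-joined, may be empty), `gene`.
#' @param subjects_path TSV with columns `subject_id`, `group`.
#' @return A [methylome] object. Subjects present in the beta header but
#'   missing from the subject table (or vice versa) are dropped with a warning.
#' @export
read_methylome <- function(beta_path, annotation_path, subjects_path) {
  bt <- data.table::fread(beta_path, sep = "\t", header = TRUE, data.table = FALSE)
  ann <- data.table::fread(annotation_path, sep = "\t", header = TRUE,
                           data.table = FALSE,
                           colClasses = list(character = c("site_id", "chrom")))
  subj <- data.table::fread(subjects_path, sep = "\t", header = TRUE, data.table = FALSE)

  if (names(bt)[1L] != "site_id")
    stop("beta matrix must have 'site_id' as its first column")
  beta <- as.matrix(bt[, -1L, drop = FALSE])
  rownames(beta) <- as.character(bt$site_id)

  shared_subj <- intersect(colnames(beta), subj$subject_id)
  if (length(shared_subj) < ncol(beta) || length(shared_subj) < nrow(subj))
    warning("subject ids differ between beta matrix and subject table; ",
            "restricting to the ", length(shared_subj), " shared subjects")
  if (!length(shared_subj)) stop("no shared subjects between beta matrix and subject table")
  beta <- beta[, shared_subj, drop = FALSE]
  subj <- subj[match(shared_subj, subj$subject_id), , drop = FALSE]

  miss <- setdiff(rownames(beta), ann$site_id)
  if (length(miss))
    stop("sites missing from annotation: ", paste(utils::head(miss, 3L), collapse = ", "))
  ann <- ann[match(rownames(beta), ann$site_id), , drop = FALSE]
  if (!is.null(ann$gene)) ann$gene[ann$gene %in% c("", "NA")] <- NA_character_
  methylome(beta, ann, subj)
}

#' Write a methylome dataset to delimited files
#'
#' Inverse of [read_methylome()]; round-trips losslessly up to numeric
#' formatting (beta values are written in full precision).
#'
#' @param dataset A [methylome] object.
#' @param beta_path,annotation_path,subjects_path Output TSV paths.
#' @export
write_methylome <- function(dataset, beta_path, annotation_path, subjects_path) {
  bt <- data.frame(site_id = dataset$sites$site_id, dataset$beta,
                   check.names = FALSE)
  data.table::fwrite(bt, beta_path, sep = "\t")
  ann <- dataset$sites[, intersect(c("site_id", "chrom", "pos", "flags", "gene"),
                                   names(dataset$sites))]
  data.table::fwrite(ann, annotation_path, sep = "\t")
  data.table::fwrite(dataset$subjects[, c("subject_id", "group")], subjects_path,
                     sep = "\t")
  invisible(dataset)
}

QC_FLAGS <- c("poor_hybridization", "snp_overlap", "multi_mapping", "sex_chromosome")

#' Remove sites failing probe-level quality control
#'
#' Drops sites carrying any QC flag (poor hybridization, SNP overlap,
#' multi-mapping, sex-chromosome) and any site on a sex chromosome regardless
#' of flags, reporting counts removed per category. Idempotent.
#'
#' @param dataset A [methylome] object with `flags` populated.
#' @return The filtered [methylome]; errors if no site survives.
#' @export
filter_probes <- function(dataset) {
  flags <- strsplit(dataset$sites$flags, ";", fixed = TRUE)
  sexchrom <- dataset$sites$chrom %in% c("chrX", "chrY", "X", "Y")
  per_flag <- vapply(QC_FLAGS, function(f)
    sum(vapply(flags, function(x) f %in% x, logical(1L))), integer(1L))
  per_flag["sex_chromosome"] <- sum(sexchrom |
    vapply(flags, function(x) "sex_chromosome" %in% x, logical(1L)))
  keep <- !sexchrom & lengths(flags) == 0L
  if (!any(keep)) stop("probe filtering removed every site")
  message(sprintf("probe filter: %d of %d sites retained (removed: %s)",
                  sum(keep), length(keep),
                  paste(sprintf("%s=%d", names(per_flag), per_flag), collapse = ", ")))
  out <- dataset
  out$beta <- dataset$beta[keep, , drop = FALSE]
  out$sites <- dataset$sites[keep, , drop = FALSE]
  rownames(out$sites) <- NULL
  out
}

#' Align a methylome and an expression matrix on shared subjects
#'
#' @param dataset A [methylome] object.
#' @param expr Numeric matrix genes x subjects with gene symbols as rownames
#'   and subject ids as colnames.
#' @return list(dataset, expr) both restricted to the shared subjects, in the
#'   methylome's subject order; errors if fewer than 2 subjects are shared.
#' @export
align_subjects <- function(dataset, expr) {
  shared <- intersect(dataset$subjects$subject_id, colnames(expr))
  if (length(shared) < 2L)
    stop("fewer than 2 shared subjects between methylome and expression")
  n_m <- nrow(dataset$subjects); n_e <- ncol(expr)
  if (length(shared) < n_m || length(shared) < n_e)
    warning("restricting to ", length(shared), " shared subjects (methylome had ",
            n_m, ", expression had ", n_e, ")")
  keep <- dataset$subjects$subject_id %in% shared
  out <- dataset
  out$beta <- dataset$beta[, keep, drop = FALSE]
  out$subjects <- dataset$subjects[keep, , drop = FALSE]
  rownames(out$subjects) <- NULL
  list(dataset = out, expr = expr[, out$subjects$subject_id, drop = FALSE])
}

#' Read CpG island intervals from a 4-column BED file
#'
#' BED coordinates (0-based half-open) are converted to 1-based inclusive;
#' overlapping or bookended islands are merged per chromosome.
#'
#' @param path BED file: chrom, start, end, name.
#' @return data.frame with columns `chrom`, `start`, `end` (1-based inclusive),
#'   sorted and non-overlapping within chromosome.
#' @export
read_islands <- function(path) {
  bed <- data.table::fread(path, header = FALSE, data.table = FALSE)
  if (ncol(bed) < 3L) stop("island BED needs at least 3 columns")
  isl <- data.frame(chrom = as.character(bed[[1L]]),
                    start = as.integer(bed[[2L]]) + 1L,
                    end   = as.integer(bed[[3L]]),
                    stringsAsFactors = FALSE)
  merge_islands(isl)
}

#' @rdname read_islands
#' @param islands data.frame chrom/start/end, 1-based inclusive.
#' @export
merge_islands <- function(islands) {
  if (!nrow(islands)) return(islands)
  islands <- islands[order(islands$chrom, islands$start, islands$end), , drop = FALSE]
  out <- do.call(rbind, lapply(split(islands, islands$chrom), function(d) {
    hi <- cummax(d$end)
    new_run <- c(TRUE, d$start[-1L] > hi[-nrow(d)] + 1L)
    grp <- cumsum(new_run)
    data.frame(chrom = d$chrom[1L],
               start = tapply(d$start, grp, min),
               end = tapply(d$end, grp, max),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read a gene set (one symbol per line, '#' comments)
#'
#' Symbols are upper-cased and whitespace-stripped so that set files from
#' heterogeneous sources match annotation symbols case-insensitively.
#'
#' @param path Text file, one gene symbol per line.
#' @param name Set name; defaults to the file basename.
#' @return list(name, genes) of class `gene_set`.
#' @export
read_gene_set <- function(path, name = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*", "", lines))
  genes <- unique(normalize_gene(lines[nzchar(lines)]))
  structure(list(name = if (is.null(name)) sub("\\.[^.]*$", "", basename(path)) else name,
                 genes = genes),
            class = "gene_set")
}

normalize_gene <- function(x) toupper(trimws(x))

#' Read an expression matrix from TSV
#'
#' @param path TSV: first column `gene`, remaining columns one per subject.
#' @return Numeric matrix genes x subjects with dimnames.
#' @export
read_expression <- function(path) {
  d <- data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
  m <- as.matrix(d[, -1L, drop = FALSE])
  rownames(m) <- normalize_gene(as.character(d[[1L]]))
  m
}
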