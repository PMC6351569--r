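# Independent reference implementations used as oracles. These deliberately
# use naive loops and textbook formulas, not the package's vectorized paths.

# chi-square survival function for even df = 2m, via the closed-form series
# S(x) = exp(-x/2) * sum_{k=0}^{m-1} (x/2)^k / k!
chisq_sf_even <- function(x, m) {
  h <- x / 2
  exp(-h) * sum(h^seq(0, m - 1) / factorial(seq(0, m - 1)))
}

oracle_fisher <- function(p) {
  if (length(p) == 1L) return(p)
  chisq_sf_even(-2 * sum(log(p)), length(p))
}

# naive per-site Welch t-test via stats::t.test, beta-scale moments by hand
oracle_site_test <- function(dataset, var_equal = FALSE) {
  is_old <- dataset$subjects$group == "older"
  M <- beta_to_m(dataset$beta)
  out <- lapply(seq_len(nrow(M)), function(i) {
    tt <- stats::t.test(M[i, is_old], M[i, !is_old], var.equal = var_equal)
    b_old <- dataset$beta[i, is_old]; b_yng <- dataset$beta[i, !is_old]
    d <- mean(b_old) - mean(b_yng)
    data.frame(site_id = dataset$sites$site_id[i],
               chrom = dataset$sites$chrom[i], pos = dataset$sites$pos[i],
               p = tt$p.value, delta_beta = d,
               variance = stats::var(b_old) / sum(is_old) +
                 stats::var(b_yng) / sum(!is_old),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

# naive left-to-right candidate-region merger; returns integer region id per
# site (input must be sorted by chromosome, position)
oracle_assign_crs <- function(chrom, pos, p, delta, alpha = 0.05, gap = 1000) {
  n <- length(p)
  sig <- p < alpha & delta != 0
  cr <- integer(n); cur <- 0L
  for (i in seq_len(n)) {
    new <- i == 1L || !sig[i] || !sig[i - 1L] ||
      chrom[i] != chrom[i - 1L] || (pos[i] - pos[i - 1L]) > gap ||
      sign(delta[i]) != sign(delta[i - 1L])
    if (new) cur <- cur + 1L
    cr[i] <- cur
  }
  cr
}

# brute-force enumeration of the permutation null: every distinct assignment
# of subjects to the older-group size, naive tests and merging throughout
oracle_permutation_pool <- function(dataset, alpha = 0.05, gap = 1000) {
  n <- nrow(dataset$subjects)
  n_old <- sum(dataset$subjects$group == "older")
  M <- beta_to_m(dataset$beta)
  pooled <- numeric(0); m_b <- integer(0)
  for (idx in utils::combn(n, n_old, simplify = FALSE)) {
    is_old <- seq_len(n) %in% idx
    p <- numeric(nrow(M)); d <- numeric(nrow(M))
    for (i in seq_len(nrow(M))) {
      tt <- stats::t.test(M[i, is_old], M[i, !is_old])
      p[i] <- tt$p.value
      d[i] <- mean(M[i, is_old]) - mean(M[i, !is_old])
    }
    cr <- oracle_assign_crs(dataset$sites$chrom, dataset$sites$pos, p, d,
                            alpha, gap)
    pcr <- vapply(split(p, cr), oracle_fisher, numeric(1L))
    pooled <- c(pooled, unname(pcr))
    m_b <- c(m_b, length(pcr))
  }
  list(pooled = pooled, m_b = m_b)
}

# step-up Benjamini-Hochberg, written out
oracle_bh <- function(p) {
  n <- length(p)
  o <- order(p)
  q <- p[o] * n / seq_len(n)
  q <- rev(cummin(rev(q)))
  out <- numeric(n); out[o] <- pmin(q, 1)
  out
}

# two-sided Fisher exact p by hypergeometric enumeration: sum of the
# probabilities of all tables (fixed margins) no more likely than observed
oracle_fisher_exact <- function(a, b, c, d) {
  m <- a + b; n <- c + d; k <- a + c
  lo <- max(0L, k - n); hi <- min(k, m)
  probs <- stats::dhyper(lo:hi, m, n, k)
  p_obs <- stats::dhyper(a, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# small hand-buildable site_stats table
make_stats <- function(pos, p, delta, chrom = "chr1",
                       variance = 1e-4, gene = NA_character_) {
  d <- data.frame(site_id = sprintf("s%03d", seq_along(pos)),
                  chrom = rep_len(chrom, length(pos)), pos = pos, p = p,
                  direction = ifelse(delta > 0, "hyper",
                                     ifelse(delta < 0, "hypo", NA)),
                  delta_beta = delta,
                  variance = rep_len(variance, length(pos)),
                  gene = rep_len(gene, length(pos)),
                  stringsAsFactors = FALSE)
  class(d) <- c("site_stats", "data.frame")
  d
}

# tiny methylome built directly from a beta matrix
make_methylome <- function(beta, pos = NULL, chrom = "chr1",
                           n_old = ncol(beta) %/% 2, gene = NA_character_) {
  n <- ncol(beta)
  if (is.null(pos)) pos <- seq_len(nrow(beta)) * 10000L
  methylome(beta,
            data.frame(site_id = sprintf("s%03d", seq_len(nrow(beta))),
                       chrom = rep_len(chrom, nrow(beta)), pos = pos,
                       flags = "", gene = rep_len(gene, nrow(beta)),
                       stringsAsFactors = FALSE),
            data.frame(subject_id = sprintf("p%02d", seq_len(n)),
                       group = rep(c("younger", "older"),
                                   c(n - n_old, n_old)),
                       stringsAsFactors = FALSE))
}
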