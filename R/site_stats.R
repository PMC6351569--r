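#' Smooth beta values with a centered sliding window
#'
#' For every subject, each site's beta value is replaced by the unweighted
#' mean of beta over all sites on the same chromosome whose position lies
#' within +/- `window_bp`/2 of the site (endpoints inclusive). An isolated
#' site keeps its own value; `window_bp = 0` is the identity.
#'
#' @param dataset A [methylome] object (sites sorted by chromosome, position).
#' @param window_bp Window width in basepairs; default 500.
#' @return The dataset with `beta` replaced by its smoothed version.
#' @export
smooth_beta <- function(dataset, window_bp = 500) {
  if (window_bp < 0) stop("window_bp must be >= 0")
  if (window_bp == 0) return(dataset)
  half <- window_bp / 2
  pos <- dataset$sites$pos
  chrom <- dataset$sites$chrom
  out <- dataset$beta
  for (idx in split(seq_along(pos), chrom)) {
    p <- pos[idx]
    # p is sorted; windows found by binary search, means by cumulative sums
    hi <- findInterval(p + half, p)
    lo <- findInterval(p - half - 0.5, p) + 1L
    n <- hi - lo + 1L
    cs <- apply(dataset$beta[idx, , drop = FALSE], 2L, cumsum)
    cs <- rbind(0, cs)
    out[idx, ] <- (cs[hi + 1L, , drop = FALSE] - cs[lo, , drop = FALSE]) / n
  }
  dataset$beta <- out
  dataset
}

#' Logit2 (M-value) transform of beta values
#'
#' M = log2(b / (1 - b)) with b clipped into \[epsilon, 1 - epsilon\] so the
#' transform stays finite at the boundaries. Strictly increasing on the
#' clipped range and antisymmetric: `beta_to_m(1 - b) == -beta_to_m(b)`.
#'
#' @param beta Numeric vector or matrix of beta values in \[0, 1\].
#' @param epsilon Clipping guard in (0, 0.5); default 1e-6.
#' @return M-values, same shape as `beta`.
#' @export
beta_to_m <- function(beta, epsilon = 1e-6) {
  if (epsilon <= 0 || epsilon >= 0.5) stop("epsilon must be in (0, 0.5)")
  b <- pmin(pmax(beta, epsilon), 1 - epsilon)
  log2(b / (1 - b))
}

# Row-wise per-group means and unbiased variances via two crossproducts.
row_group_moments <- function(X, is_old) {
  n1 <- sum(is_old); n0 <- sum(!is_old)
  g1 <- as.numeric(is_old); g0 <- as.numeric(!is_old)
  m1 <- as.vector(X %*% g1) / n1; m0 <- as.vector(X %*% g0) / n0
  v1 <- pmax(0, (as.vector(X^2 %*% g1) - n1 * m1^2) / (n1 - 1))
  v0 <- pmax(0, (as.vector(X^2 %*% g0) - n0 * m0^2) / (n0 - 1))
  list(m1 = m1, m0 = m0, v1 = v1, v0 = v0, n1 = n1, n0 = n0)
}

# Row-wise two-sample t-tests between subject groups.
# X: sites x subjects matrix (M-values for the test); is_old: logical vector.
# Returns p, t and per-group means/variances of X. Degenerate rows (zero
# variance in both groups) get p = 1 when the means agree and p = machine
# minimum otherwise.
row_t_test <- function(X, is_old, var_equal = FALSE) {
  n1 <- sum(is_old); n0 <- sum(!is_old)
  if (n1 < 2L || n0 < 2L) stop("both groups need >= 2 subjects")
  mo <- row_group_moments(X, is_old)
  m1 <- mo$m1; m0 <- mo$m0; v1 <- mo$v1; v0 <- mo$v0
  d <- m1 - m0
  if (var_equal) {
    sp2 <- ((n1 - 1) * v1 + (n0 - 1) * v0) / (n1 + n0 - 2)
    se2 <- sp2 * (1 / n1 + 1 / n0)
    df <- rep.int(n1 + n0 - 2, length(d))
  } else {
    a1 <- v1 / n1; a0 <- v0 / n0
    se2 <- a1 + a0
    df <- se2^2 / (a1^2 / (n1 - 1) + a0^2 / (n0 - 1))
  }
  tt <- d / sqrt(se2)
  p <- 2 * stats::pt(-abs(tt), df)
  degen <- se2 == 0
  if (any(degen)) {
    p[degen] <- ifelse(d[degen] == 0, 1, .Machine$double.xmin)
    if (any(degen & d != 0))
      warning("zero within-group variance with unequal means at ",
              sum(degen & d != 0), " site(s); p set to machine minimum")
  }
  p <- pmin(pmax(p, .Machine$double.xmin), 1)
  list(p = p, t = tt, m1 = m1, m0 = m0, v1 = v1, v0 = v0, n1 = n1, n0 = n0)
}

#' Per-site two-group tests on M-values
#'
#' Runs a two-tailed t-test (Welch by default) of older vs younger subjects on
#' the M-values of each site, and computes the per-site effect size
#' `delta_beta` = mean(older) - mean(younger) with its sampling variance
#' s2_old/n_old + s2_young/n_young, both on the (smoothed) beta scale.
#'
#' @param dataset A [methylome] object, normally after [smooth_beta()].
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @param epsilon Clipping guard for the M transform; see [beta_to_m()].
#' @return data.frame of class `site_stats`: `site_id`, `chrom`, `pos`, `p`,
#'   `direction` (`"hyper"`/`"hypo"`, NA when delta_beta is 0), `delta_beta`,
#'   `variance`, plus `gene` if annotated.
#' @export
site_test <- function(dataset, var_equal = FALSE, epsilon = 1e-6) {
  is_old <- dataset$subjects$group == "older"
  M <- beta_to_m(dataset$beta, epsilon)
  tm <- row_t_test(M, is_old, var_equal = var_equal)
  tb <- row_group_moments(dataset$beta, is_old)
  d <- tb$m1 - tb$m0
  v <- tb$v1 / tb$n1 + tb$v0 / tb$n0
  out <- data.frame(site_id = dataset$sites$site_id,
                    chrom = dataset$sites$chrom,
                    pos = dataset$sites$pos,
                    p = tm$p,
                    direction = ifelse(d > 0, "hyper", ifelse(d < 0, "hypo", NA)),
                    delta_beta = d,
                    variance = v,
                    stringsAsFactors = FALSE)
  if (!is.null(dataset$sites$gene)) out$gene <- dataset$sites$gene
  class(out) <- c("site_stats", "data.frame")
  out
}
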