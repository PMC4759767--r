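# Differential expression between sensitivity extremes: Welch/pooled t-test
# with BH q-values, and SAM (d statistic with fudge factor s0, permutation
# FDR q-values).

split_classes <- function(m, labels) {
  labels <- labels[names(labels) %in% colnames(m)]
  sens <- names(labels)[labels == "sensitive"]
  res <- names(labels)[labels == "resistant"]
  if (length(sens) < 2 || length(res) < 2)
    stop_argument("each class needs at least 2 samples present in the matrix")
  list(sens = as_plain_matrix(m[, sens, drop = FALSE]),
       res = as_plain_matrix(m[, res, drop = FALSE]))
}

row_group_stats <- function(x) {
  n <- ncol(x)
  mu <- rowMeans(x)
  v <- rowSums((x - mu)^2) / (n - 1)
  list(mu = mu, v = v, n = n)
}

#' Differential expression by row-wise t-tests
#'
#' Welch (default) or pooled two-sample t-tests between sensitive and
#' resistant samples, Benjamini-Hochberg q-values, and the study's fallback
#' rule: rows with q < `q_cut` form the signature, but if fewer than
#' `min_genes` survive, rows with p < `p_fallback` are used instead. The
#' cutoff actually applied is recorded on the returned signature.
#'
#' @param m an [expression_matrix()].
#' @param labels named vector from [select_extremes()].
#' @param q_cut q-value cutoff (default 0.05).
#' @param p_fallback raw-p cutoff used when the q rule yields too few genes
#'   (default 0.001).
#' @param min_genes the "too few" threshold for triggering the fallback
#'   (default 10).
#' @param var_equal use the pooled-variance t-test instead of Welch.
#' @return a [gene_signature()], entries sorted by decreasing |t|.
#' @export
ttest_deg <- function(m, labels, q_cut = 0.05, p_fallback = 0.001,
                      min_genes = 10L, var_equal = FALSE) {
  cls <- split_classes(m, labels)
  s1 <- row_group_stats(cls$sens); s2 <- row_group_stats(cls$res)
  if (var_equal) {
    sp2 <- ((s1$n - 1) * s1$v + (s2$n - 1) * s2$v) / (s1$n + s2$n - 2)
    se <- sqrt(sp2 * (1 / s1$n + 1 / s2$n))
    df <- rep(s1$n + s2$n - 2, length(se))
  } else {
    se <- sqrt(s1$v / s1$n + s2$v / s2$n)
    df <- (s1$v / s1$n + s2$v / s2$n)^2 /
      ((s1$v / s1$n)^2 / (s1$n - 1) + (s2$v / s2$n)^2 / (s2$n - 1))
  }
  t_stat <- (s1$mu - s2$mu) / se
  t_stat[se == 0] <- 0
  df[!is.finite(df)] <- s1$n + s2$n - 2
  p <- 2 * pt(-abs(t_stat), df)
  p[se == 0] <- 1
  q <- p.adjust(p, method = "BH")
  entries <- data.frame(row_id = rownames(m), statistic = t_stat, p = p, q = q,
                        direction = ifelse(s1$mu >= s2$mu, "up-in-sensitive",
                                           "down-in-sensitive"),
                        stringsAsFactors = FALSE)
  keep <- entries$q < q_cut & se > 0
  cutoff <- list(rule = "q", value = q_cut)
  if (sum(keep) < min_genes) {
    keep <- entries$p < p_fallback & se > 0
    cutoff <- list(rule = "p", value = p_fallback)
  }
  entries <- entries[keep, , drop = FALSE]
  entries <- entries[order(-abs(entries$statistic), entries$row_id), , drop = FALSE]
  rownames(entries) <- NULL
  gene_signature(entries, method = if (var_equal) "t-test-pooled" else "t-test",
                 cutoff = cutoff)
}

sam_d <- function(mu1, mu2, v1, v2, n1, n2, s0) {
  sp2 <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
  si <- sqrt(sp2 * (1 / n1 + 1 / n2))
  list(d = (mu1 - mu2) / (si + s0), si = si)
}

# Tusher-style s0: the percentile of s_i minimizing the coefficient of
# variation of the spread of d across s_i-quantile bins. Falls back to
# median(s_i) on small problems where the search is degenerate.
sam_s0 <- function(mu1, mu2, v1, v2, n1, n2) {
  si <- sam_d(mu1, mu2, v1, v2, n1, n2, 0)$si
  if (length(si) < 20) return(median(si))
  alphas <- seq(0, 1, by = 0.05)
  cand <- quantile(si, alphas, names = FALSE)
  n_bins <- min(10L, max(2L, floor(length(si) / 10)))
  bins <- cut(rank(si, ties.method = "first"), breaks = n_bins, labels = FALSE)
  cv <- vapply(cand, function(s0) {
    d <- (mu1 - mu2) / (si + s0)
    spread <- tapply(d, bins, mad)
    if (any(!is.finite(spread)) || mean(spread) == 0) return(Inf)
    sd(spread) / mean(spread)
  }, 0)
  if (all(!is.finite(cv))) return(median(si))
  cand[which.min(cv)]
}

#' Differential expression by SAM
#'
#' Significance analysis of microarrays between the two sensitivity classes:
#' per-row statistic d = (mean1 - mean2) / (s_i + s0) with pooled standard
#' error s_i and fudge factor s0 chosen by the percentile search, and
#' permutation-based FDR q-values (median number of permuted |d| exceeding
#' each observed |d|, divided by the observed count, step-up monotonized).
#'
#' @param m an [expression_matrix()].
#' @param labels named vector from [select_extremes()].
#' @param q_cut q-value cutoff (default 0.1).
#' @param n_perm number of label permutations (>= 100).
#' @param rng_seed seed for the permutation stream.
#' @param s0 optional fixed fudge factor; by default chosen by the
#'   percentile search.
#' @return a [gene_signature()] (column `p` is `NA`; SAM reports q only).
#' @export
sam_deg <- function(m, labels, q_cut = 0.1, n_perm = 200L, rng_seed = 1L,
                    s0 = NULL) {
  if (n_perm < 100) stop_argument("n_perm must be at least 100 for stable q-values")
  cls <- split_classes(m, labels)
  x <- cbind(cls$sens, cls$res)
  n1 <- ncol(cls$sens); n2 <- ncol(cls$res)
  grp_stats <- function(idx1) {
    x1 <- x[, idx1, drop = FALSE]; x2 <- x[, -idx1, drop = FALSE]
    mu1 <- rowMeans(x1); mu2 <- rowMeans(x2)
    v1 <- rowSums((x1 - mu1)^2) / (n1 - 1)
    v2 <- rowSums((x2 - mu2)^2) / (n2 - 1)
    list(mu1 = mu1, mu2 = mu2, v1 = v1, v2 = v2)
  }
  obs <- grp_stats(seq_len(n1))
  if (is.null(s0))
    s0 <- sam_s0(obs$mu1, obs$mu2, obs$v1, obs$v2, n1, n2)
  d_obs <- sam_d(obs$mu1, obs$mu2, obs$v1, obs$v2, n1, n2, s0)$d
  d_obs[!is.finite(d_obs)] <- 0

  abs_obs <- abs(d_obs)
  ord <- order(-abs_obs, rownames(m))
  thresholds <- abs_obs[ord]
  exceed <- with_rng(rng_seed, {
    vapply(seq_len(n_perm), function(b) {
      idx1 <- sample.int(n1 + n2, n1)
      pst <- grp_stats(idx1)
      d_p <- sam_d(pst$mu1, pst$mu2, pst$v1, pst$v2, n1, n2, s0)$d
      d_p <- abs(d_p[is.finite(d_p)])
      # counts of permuted |d| >= each observed threshold (desc order)
      length(d_p) - findInterval(thresholds - 1e-15, sort(d_p))
    }, numeric(length(thresholds)))
  })
  exceed <- matrix(exceed, nrow = length(thresholds))
  med_false <- apply(exceed, 1, median)
  fdr <- pmin(1, med_false / seq_along(thresholds))
  q_sorted <- rev(cummin(rev(fdr)))
  q <- numeric(length(d_obs))
  q[ord] <- q_sorted
  entries <- data.frame(row_id = rownames(m), statistic = d_obs,
                        p = NA_real_, q = q,
                        direction = ifelse(obs$mu1 >= obs$mu2, "up-in-sensitive",
                                           "down-in-sensitive"),
                        stringsAsFactors = FALSE)
  entries <- entries[entries$q < q_cut & abs(entries$statistic) > 0, ,
                     drop = FALSE]
  entries <- entries[order(-abs(entries$statistic), entries$row_id), , drop = FALSE]
  rownames(entries) <- NULL
  sig <- gene_signature(entries, method = "SAM",
                        cutoff = list(rule = "q", value = q_cut))
  attr(sig, "s0") <- s0
  sig
}
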