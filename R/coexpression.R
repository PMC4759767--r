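# The co-expression filter: per-gene concordance of correlation structure
# between the reference and the co-expression (target-like) dataset, a random
# null distribution for the selection cutoff, and signature filtering.

#' Per-gene co-expression coefficients
#'
#' For each signature gene g, computes cc(g): the correlation between the
#' vector of g's correlations with every other signature gene in the
#' reference data and the corresponding vector in the co-expression data
#' (self-correlations excluded). cc is symmetric in the two datasets and
#' invariant to per-gene affine rescaling.
#'
#' @param sig_expr_ref,sig_expr_co [expression_matrix()]s over the same gene
#'   row set (>= 3 genes, >= 3 samples each); row order may differ.
#' @param method `"pearson"` (default) or `"spearman"`; the same choice is
#'   used for the profiles and for cc itself.
#' @return data.frame of class `"coexpression_result"` with columns `gene`,
#'   `cc` (cutoff/selection columns are filled by [coexpression_select()]).
#' @export
coexpression_coefficients <- function(sig_expr_ref, sig_expr_co,
                                      method = c("pearson", "spearman")) {
  method <- match.arg(method)
  ref_genes <- rownames(sig_expr_ref); co_genes <- rownames(sig_expr_co)
  if (!setequal(ref_genes, co_genes)) {
    diff <- c(setdiff(ref_genes, co_genes), setdiff(co_genes, ref_genes))
    stop_argument(sprintf("gene sets differ between datasets: %s",
                          paste(head(diff, 10), collapse = ", ")))
  }
  if (length(ref_genes) < 3)
    stop_argument("co-expression profiles need at least 3 genes")
  if (ncol(sig_expr_ref) < 3 || ncol(sig_expr_co) < 3)
    stop_argument("co-expression needs at least 3 samples per dataset")
  genes <- sort(ref_genes)
  cc_values(as_plain_matrix(sig_expr_ref[genes, , drop = FALSE]),
            as_plain_matrix(sig_expr_co[genes, , drop = FALSE]), method)
}

cc_values <- function(ref, co, method) {
  cor_ref <- suppressWarnings(cor(t(ref), method = method))
  cor_co <- suppressWarnings(cor(t(co), method = method))
  g <- nrow(ref)
  cc <- vapply(seq_len(g), function(i)
    suppressWarnings(cor(cor_ref[i, -i], cor_co[i, -i], method = method)),
    0)
  out <- data.frame(gene = rownames(ref), cc = cc, cutoff = NA_real_,
                    rule = NA_character_, selected = NA,
                    stringsAsFactors = FALSE)
  class(out) <- c("coexpression_result", "data.frame")
  out
}

#' Null cutoff for the co-expression coefficient
#'
#' Draws `n_draws` random gene sets of size `sig_size` (uniform, without
#' replacement, from the genes present in both full matrices), computes their
#' co-expression coefficients, pools all values, and returns the requested
#' percentile of the pooled null.
#'
#' @param expr_ref_all,expr_co_all full gene-level [expression_matrix()]s
#'   sharing a common gene universe.
#' @param sig_size signature size the null mimics.
#' @param n_draws number of random gene sets (>= 100).
#' @param percentile percentile of the pooled null (default 90).
#' @param rng_seed seed for the draws.
#' @param method correlation type, as in [coexpression_coefficients()].
#' @return numeric cutoff; attribute `"null_cc"` holds the pooled null values.
#' @export
null_cutoff <- function(expr_ref_all, expr_co_all, sig_size, n_draws = 200L,
                        percentile = 90, rng_seed = 1L,
                        method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (n_draws < 100) stop_argument("n_draws must be at least 100")
  common <- intersect(rownames(expr_ref_all), rownames(expr_co_all))
  if (sig_size > length(common))
    stop_argument(sprintf(
      "sig_size (%d) exceeds the common gene universe (%d genes)",
      sig_size, length(common)))
  if (sig_size < 3) stop_argument("sig_size must be at least 3")
  ref <- as_plain_matrix(expr_ref_all[common, , drop = FALSE])
  co <- as_plain_matrix(expr_co_all[common, , drop = FALSE])
  null_cc <- with_rng(rng_seed, {
    unlist(lapply(seq_len(n_draws), function(b) {
      g <- sample(common, sig_size)
      cc_values(ref[g, , drop = FALSE], co[g, , drop = FALSE], method)$cc
    }))
  })
  null_cc <- null_cc[is.finite(null_cc)]
  cut <- as.numeric(quantile(null_cc, percentile / 100, names = FALSE))
  attr(cut, "null_cc") <- null_cc
  cut
}

#' Apply a selection rule to co-expression coefficients
#'
#' Under `"percentile90"` a gene is selected when its cc exceeds the supplied
#' null cutoff. Under `"p05"` a gene is selected when cc is positive and the
#' two-sided correlation test on cc (t with profile-length minus 2 degrees of
#' freedom) gives p < 0.05.
#'
#' @param res result from [coexpression_coefficients()].
#' @param rule `"percentile90"` or `"p05"`.
#' @param cutoff the null cutoff (required for `"percentile90"`).
#' @param p_cut p-value cutoff for the `"p05"` rule.
#' @return the result with `cutoff`, `rule` and `selected` filled in.
#' @export
coexpression_select <- function(res, rule = c("percentile90", "p05"),
                                cutoff = NULL, p_cut = 0.05) {
  rule <- match.arg(rule)
  if (rule == "percentile90") {
    if (is.null(cutoff)) stop_argument("percentile90 rule needs a null cutoff")
    res$cutoff <- as.numeric(cutoff)
    res$selected <- is.finite(res$cc) & res$cc > as.numeric(cutoff)
  } else {
    n_profile <- nrow(res) - 1  # profile length
    if (n_profile < 3) stop_argument("p05 rule needs profiles of length >= 3")
    tt <- res$cc * sqrt((n_profile - 2) / pmax(1e-12, 1 - res$cc^2))
    p <- 2 * pt(-abs(tt), df = n_profile - 2)
    res$cutoff <- p_cut
    res$selected <- is.finite(res$cc) & res$cc > 0 & p < p_cut
  }
  res$rule <- rule
  res
}

#' Filter a signature by its co-expression result
#'
#' Keeps the signature entries whose gene was selected, preserving the
#' original ordering.
#'
#' @param sig a [gene_signature()].
#' @param res a selected [coexpression_select()] result covering `sig` (keyed
#'   by `row_id` or by collapsed gene symbol).
#' @return the filtered [gene_signature()].
#' @export
filter_signature <- function(sig, res) {
  if (anyNA(res$selected))
    stop_argument("co-expression result has no selection; run coexpression_select()")
  idx <- match(sig$row_id, res$gene)
  if (anyNA(idx))
    stop_argument(sprintf("co-expression result does not cover signature rows: %s",
                          paste(head(sig$row_id[is.na(idx)], 5), collapse = ", ")))
  keep <- res$selected[idx]
  if (!any(keep))
    stop_data(paste("no signature gene passed the co-expression filter;",
                    "relax the cutoff (lower percentile or p05 rule)"))
  out <- sig[keep, , drop = FALSE]
  rownames(out) <- NULL
  gene_signature(as.data.frame(out), method = attr(sig, "method"),
                 cutoff = attr(sig, "cutoff"))
}
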