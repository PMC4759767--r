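# Cross-platform probeset matching: local sequence alignment against ortholog
# probesets, correlation-profile matching, and the two collapse-to-gene
# operators. All strategies produce a cross-platform map in which every
# signature row is either matched exactly once or dropped with a reason.

cross_platform_map <- function(source_id, target_id, strategy, score,
                               dropped, reason) {
  out <- data.frame(source_id = source_id, target_id = target_id,
                    strategy = strategy, score = score, dropped = dropped,
                    reason = reason, stringsAsFactors = FALSE)
  class(out) <- c("cross_platform_map", "data.frame")
  out
}

#' Local alignment score of two nucleotide sequences
#'
#' Best local (Smith-Waterman) alignment score under the scheme match +2,
#' mismatch -3, gap opening -5, gap extension -2 per base (a gap of length L
#' costs 5 + 2L), the scoring family used for "somewhat similar sequences".
#' `N` is treated as a neutral base scoring 0 against anything. The score is
#' symmetric in its arguments.
#'
#' @param seq_a,seq_b character strings over A, C, G, T, N.
#' @return integer alignment score (0 when no positive-scoring local
#'   alignment exists).
#' @export
align_score <- function(seq_a, seq_b) {
  for (s in list(seq_a, seq_b)) {
    if (!is.character(s) || length(s) != 1 || is.na(s) || !nzchar(s))
      stop_argument("sequences must be non-empty character strings")
    if (grepl("[^ACGTN]", s))
      stop_argument("sequences may only contain A, C, G, T, N")
  }
  mat <- matrix(-3, 5, 5, dimnames = list(c("A", "C", "G", "T", "N"),
                                          c("A", "C", "G", "T", "N")))
  diag(mat) <- 2
  mat["N", ] <- 0
  mat[, "N"] <- 0
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
    type = "local", substitutionMatrix = mat,
    gapOpening = 5, gapExtension = 2, scoreOnly = TRUE)
  as.integer(max(0, round(pa)))
}

signature_source_rows <- function(sig, annot_src) {
  idx <- match(sig$row_id, annot_src$probe_id)
  if (anyNA(idx))
    stop_argument(sprintf("signature rows missing from source annotation: %s",
                          paste(sig$row_id[is.na(idx)], collapse = ", ")))
  data.frame(source_id = sig$row_id,
             gene = annot_src$gene_symbol[idx],
             ortholog = annot_src$ortholog_gene[idx],
             sequence_id = annot_src$sequence_id[idx],
             stringsAsFactors = FALSE)
}

#' Match signature probesets by best sequence homology
#'
#' For each signature probeset, scores its target sequence against every
#' probeset of the annotated ortholog gene on the partner platform with
#' [align_score()] and keeps the best-scoring one (ties broken by
#' lexicographically smaller target probe id). Probesets with no annotated
#' ortholog, with unresolvable annotation, or whose best score falls below
#' `floor_score` are dropped with a reason.
#'
#' @param sig a [gene_signature()] with source-platform probe ids.
#' @param annot_src,annot_tgt [probe_annotation()] tables.
#' @param sequences named character vector of target sequences covering the
#'   `sequence_id`s referenced by both annotations.
#' @param floor_score minimal acceptable alignment score (default 20).
#' @param override optional data.frame `(source_id, target_id)` representing
#'   manual annotation; listed pairs are used verbatim.
#' @return a cross-platform map (one row per signature entry).
#' @export
match_by_homology <- function(sig, annot_src, annot_tgt, sequences,
                              floor_score = 20L, override = NULL) {
  rows <- signature_source_rows(sig, annot_src)
  need <- unique(c(rows$sequence_id, annot_tgt$sequence_id))
  need <- need[!is.na(need)]
  missing_seq <- setdiff(need, names(sequences))
  if (length(missing_seq))
    stop_data(sprintf("missing FASTA entries for sequence id(s): %s",
                      paste(head(missing_seq, 5), collapse = ", ")))
  out <- lapply(seq_len(nrow(rows)), function(i) {
    src <- rows[i, ]
    if (!is.null(override) && src$source_id %in% override$source_id) {
      tid <- override$target_id[match(src$source_id, override$source_id)]
      return(cross_platform_map(src$source_id, tid, "homology", NA_real_,
                                FALSE, NA_character_))
    }
    if (is.na(src$ortholog))
      return(cross_platform_map(src$source_id, NA_character_, "homology",
                                NA_real_, TRUE, "no_ortholog"))
    cand <- annot_tgt[annot_tgt$gene_symbol == src$ortholog &
                        !is.na(annot_tgt$sequence_id), , drop = FALSE]
    if (nrow(cand) == 0 || is.na(src$sequence_id))
      return(cross_platform_map(src$source_id, NA_character_, "homology",
                                NA_real_, TRUE, "annotation_failed"))
    scores <- vapply(cand$sequence_id, function(sid)
      align_score(sequences[[src$sequence_id]], sequences[[sid]]), 0L)
    best <- order(-scores, cand$probe_id)[1]
    if (scores[best] < floor_score)
      return(cross_platform_map(src$source_id, NA_character_, "homology",
                                as.numeric(scores[best]), TRUE,
                                "below_threshold"))
    cross_platform_map(src$source_id, cand$probe_id[best], "homology",
                       as.numeric(scores[best]), FALSE, NA_character_)
  })
  do.call(rbind, out)
}

#' Match signature probesets by best correlative match
#'
#' Builds the signature's gene-gene correlation matrix on the source platform,
#' duplicates its rows so they align one-to-one with the candidate probesets
#' on the target platform, builds the candidates' correlation matrix, and for
#' each candidate correlates its correlation profile with the corresponding
#' source profile (entries belonging to the candidate's own gene excluded).
#' Per gene, the candidate with the highest profile correlation is retained;
#' signature genes with no target candidates are dropped with a reason.
#'
#' @param sig a [gene_signature()] (>= 3 entries) with source probe ids.
#' @param expr_src,expr_tgt probe-level [expression_matrix()]s.
#' @param annot_src,annot_tgt [probe_annotation()] tables.
#' @param method correlation type, `"pearson"` (default) or `"spearman"`.
#' @return a cross-platform map with the profile correlation as score.
#' @export
match_by_correlation <- function(sig, expr_src, expr_tgt, annot_src, annot_tgt,
                                 method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (nrow(sig) < 3)
    stop_argument("correlative matching needs a signature of at least 3 genes")
  rows <- signature_source_rows(sig, annot_src)
  cand_of <- lapply(rows$ortholog, function(g) {
    if (is.na(g)) return(character())
    annot_tgt$probe_id[annot_tgt$gene_symbol == g]
  })
  has_cand <- lengths(cand_of) > 0
  kept <- which(has_cand)
  if (length(kept) < 3)
    stop_argument("fewer than 3 signature genes have target candidates")
  # expanded (duplicated) source rows, one per target candidate
  cand_ids <- unlist(cand_of[kept])
  owner <- rep(kept, lengths(cand_of[kept]))  # signature index per candidate
  src_expanded <- as_plain_matrix(expr_src[rows$source_id[owner], , drop = FALSE])
  tgt_cand <- as_plain_matrix(expr_tgt[cand_ids, , drop = FALSE])
  cor_src <- cor(t(src_expanded), method = method)
  cor_tgt <- cor(t(tgt_cand), method = method)
  profile_cc <- vapply(seq_along(cand_ids), function(j) {
    keep <- owner != owner[j]      # drop own-gene entries (incl. diagonal)
    if (sum(keep) < 2) return(NA_real_)
    suppressWarnings(cor(cor_src[j, keep], cor_tgt[j, keep], method = method))
  }, 0)
  out <- lapply(seq_len(nrow(rows)), function(i) {
    if (!has_cand[i]) {
      reason <- if (is.na(rows$ortholog[i])) "no_ortholog" else "annotation_failed"
      return(cross_platform_map(rows$source_id[i], NA_character_, "correlation",
                                NA_real_, TRUE, reason))
    }
    j_set <- which(owner == i)
    cc <- profile_cc[j_set]
    if (all(is.na(cc)))
      return(cross_platform_map(rows$source_id[i], NA_character_, "correlation",
                                NA_real_, TRUE, "annotation_failed"))
    best <- j_set[order(-ifelse(is.na(cc), -Inf, cc), cand_ids[j_set])[1]]
    cross_platform_map(rows$source_id[i], cand_ids[best], "correlation",
                       profile_cc[best], FALSE, NA_character_)
  })
  do.call(rbind, out)
}

probe_gene_map <- function(m, annot) {
  idx <- match(rownames(m), annot$probe_id)
  genes <- annot$gene_symbol[idx]
  unannotated <- is.na(genes)
  if (any(unannotated))
    message(sprintf("dropping %d probe(s) without gene annotation",
                    sum(unannotated)))
  list(genes = genes, keep = !unannotated, idx = idx)
}

#' Collapse probes to gene level by averaging
#'
#' One row per gene: the arithmetic mean of its probes' rows, per sample.
#' Probes without gene annotation are dropped (with a message). With
#' `cross_species = TRUE`, genes lacking a partner-platform ortholog are
#' removed as well.
#'
#' @param m probe-level [expression_matrix()].
#' @param annot [probe_annotation()] for the matrix's platform.
#' @param cross_species drop genes without an annotated ortholog.
#' @return gene-level [expression_matrix()].
#' @export
collapse_average <- function(m, annot, cross_species = FALSE) {
  if (attr(m, "level") != "probe") stop_argument("matrix is not probe-level")
  pm <- probe_gene_map(m, annot)
  v <- as_plain_matrix(m)[pm$keep, , drop = FALSE]
  genes <- pm$genes[pm$keep]
  if (cross_species) {
    has_orth <- !is.na(annot$ortholog_gene[pm$idx[pm$keep]])
    v <- v[has_orth, , drop = FALSE]
    genes <- genes[has_orth]
  }
  sums <- rowsum(v, group = genes)
  counts <- as.vector(table(genes)[rownames(sums)])
  out <- sums / counts
  out <- out[order(rownames(out)), , drop = FALSE]
  expression_matrix(out, level = "gene", platform = attr(m, "platform"),
                    species = attr(m, "species"))
}

#' Collapse probes to gene level by maximum variance
#'
#' One row per gene: the probe row with the largest across-sample variance
#' (ties broken by lexicographically smaller probe id). Row values are taken
#' verbatim from the input. Use [shared_genes()] afterwards to drop genes not
#' present on both platforms.
#'
#' @inheritParams collapse_average
#' @return gene-level [expression_matrix()]; attribute
#'   `"representative_probe"` records the chosen probe per gene.
#' @export
collapse_max_variance <- function(m, annot, cross_species = FALSE) {
  if (attr(m, "level") != "probe") stop_argument("matrix is not probe-level")
  pm <- probe_gene_map(m, annot)
  v <- as_plain_matrix(m)[pm$keep, , drop = FALSE]
  genes <- pm$genes[pm$keep]
  if (cross_species) {
    has_orth <- !is.na(annot$ortholog_gene[pm$idx[pm$keep]])
    v <- v[has_orth, , drop = FALSE]
    genes <- genes[has_orth]
  }
  vars <- apply(v, 1, var)
  ord <- order(genes, -vars, rownames(v))
  first <- !duplicated(genes[ord])
  sel <- ord[first]
  out <- v[sel, , drop = FALSE]
  reps <- setNames(rownames(v)[sel], genes[sel])
  rownames(out) <- genes[sel]
  out <- out[order(rownames(out)), , drop = FALSE]
  em <- expression_matrix(out, level = "gene", platform = attr(m, "platform"),
                          species = attr(m, "species"))
  attr(em, "representative_probe") <- reps[rownames(out)]
  em
}

#' Restrict two gene-level matrices to their common genes
#'
#' After collapsing on both platforms, genes absent from either array are
#' filtered out.
#'
#' @param m_a,m_b gene-level [expression_matrix()]s.
#' @return list of the two matrices restricted to the shared, sorted gene set.
#' @export
shared_genes <- function(m_a, m_b) {
  common <- sort(intersect(rownames(m_a), rownames(m_b)))
  if (!length(common)) stop_data("no genes shared between the two matrices")
  list(a = m_a[common, , drop = FALSE], b = m_b[common, , drop = FALSE])
}
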