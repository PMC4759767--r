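fake_signature <- function(row_ids) {
  gene_signature(data.frame(row_id = row_ids, statistic = 1, p = 0.001,
                            q = 0.01, direction = "up-in-sensitive",
                            stringsAsFactors = FALSE),
                 method = "t-test", cutoff = list(rule = "q", value = 0.05))
}

test_that("align_score matches the scoring scheme and the exhaustive oracle", {
  s <- paste(rep("ACGTG", 5), collapse = "")
  expect_identical(align_score(s, s), 50L)  # 25 matches x 2
  s_sub <- s
  substr(s_sub, 12, 12) <- "C"  # position 12 is G in s
  expect_identical(align_score(s, s_sub),
                   as.integer(oracle_local_align(s, s_sub)))
  expect_error(align_score("", s), "non-empty")
  expect_error(align_score("ACGTX", s), "A, C, G, T, N")
  expect_identical(align_score("ACGTACGTACGT", "TGCATGCATGCA"),
                   as.integer(oracle_local_align("ACGTACGTACGT", "TGCATGCATGCA")))
  withr::with_seed(11, {
    for (i in 1:10) {
      a <- paste(sample(c("A", "C", "G", "T", "N"), sample(6:12, 1),
                        replace = TRUE, prob = c(.24, .24, .24, .24, .04)),
                 collapse = "")
      b <- paste(sample(c("A", "C", "G", "T"), sample(6:12, 1), replace = TRUE),
                 collapse = "")
      expect_identical(align_score(a, b), as.integer(oracle_local_align(a, b)))
      expect_identical(align_score(a, b), align_score(b, a))
    }
  })
})

test_that("homology matching picks the best-scoring ortholog probeset", {
  annot_src <- probe_annotation("src1", "GENE1", "P1", "GENE1", "src1")
  annot_tgt <- probe_annotation(c("tgtA", "tgtB"), c("GENE1", "GENE1"), "P2",
                                c("GENE1", "GENE1"), c("tgtA", "tgtB"))
  src_seq <- paste(rep("ACGTG", 6), collapse = "")
  seqs <- c(src1 = src_seq,
            tgtA = src_seq,                                     # exact copy
            tgtB = paste(rev(strsplit(src_seq, "")[[1]]), collapse = ""))
  map <- match_by_homology(fake_signature("src1"), annot_src, annot_tgt, seqs)
  expect_identical(map$target_id, "tgtA")
  expect_false(map$dropped)

  # single candidate above the floor is taken regardless of relative score
  map1 <- match_by_homology(fake_signature("src1"), annot_src,
                            annot_tgt[annot_tgt$probe_id == "tgtA", ], seqs)
  expect_identical(map1$target_id, "tgtA")

  # missing ortholog and missing FASTA entries are reported
  annot_no <- probe_annotation("src1", "GENE1", "P1", NA_character_, "src1")
  mapd <- match_by_homology(fake_signature("src1"), annot_no, annot_tgt, seqs)
  expect_true(mapd$dropped)
  expect_identical(mapd$reason, "no_ortholog")
  expect_error(match_by_homology(fake_signature("src1"), annot_src, annot_tgt,
                                 seqs[c("src1", "tgtA")]), "FASTA")
})

test_that("homology matching recovers the generator's probe pairing", {
  cfg <- simulation_config(seed = 21, n_genes = 60, n_signature_genes = 20,
                           ortholog_dropout = 0,
                           probes_per_gene_range = list(source = c(1, 1),
                                                        target = c(2, 3)))
  src <- gen_cell_line_panel(cfg, "source")
  tgt <- gen_cell_line_panel(cfg, "target")
  seqs <- c(src$sequences, tgt$sequences)
  sig <- fake_signature(src$annotation$probe_id[1:40])
  map <- match_by_homology(sig, src$annotation, tgt$annotation, seqs)
  kept <- map[!map$dropped, ]
  # the generator's canonical probe (rank 1, least mutated) is the truth
  truth <- sub("_p\\d+$", "_p1", sub("^hu_", "ca_", kept$source_id))
  expect_gte(mean(kept$target_id == truth), 0.95)
})

test_that("correlative matching finds identity structure and planted signals", {
  withr::with_seed(31, {
    v <- matrix(rnorm(200), 10, 20,
                dimnames = list(sprintf("sp%02d", 1:10), sprintf("s%d", 1:20)))
  })
  src <- expression_matrix(v)
  genes <- sprintf("GENE%02d", 1:10)
  annot_src <- probe_annotation(rownames(v), genes, "P1", genes, NA)
  tgt_ids <- sprintf("tp%02d", 1:10)
  perm <- withr::with_seed(32, sample(20))
  tgt <- v[, perm]
  rownames(tgt) <- tgt_ids
  colnames(tgt) <- sprintf("t%d", 1:20)
  annot_tgt <- probe_annotation(tgt_ids, genes, "P2", genes, NA)
  map <- match_by_correlation(fake_signature(rownames(v)), src,
                              expression_matrix(tgt), annot_src, annot_tgt)
  expect_identical(map$target_id, tgt_ids)
  expect_equal(map$score, rep(1, 10), tolerance = 1e-10)

  # two candidates per gene: one shares the source latent signal, one is noise
  withr::with_seed(33, {
    n <- 40
    latent <- matrix(rnorm(20 * n), 20, n)
    src_v <- latent + 0.5 * matrix(rnorm(20 * n), 20, n)
    dimnames(src_v) <- list(sprintf("sp%02d", 1:20), sprintf("s%d", 1:n))
    good <- latent + 0.5 * matrix(rnorm(20 * n), 20, n)
    bad <- matrix(rnorm(20 * n), 20, n)
    tgt_v <- rbind(good, bad)
    rownames(tgt_v) <- c(sprintf("good%02d", 1:20), sprintf("bad%02d", 1:20))
    colnames(tgt_v) <- sprintf("t%d", 1:n)
  })
  genes20 <- sprintf("GENE%02d", 1:20)
  a_src <- probe_annotation(rownames(src_v), genes20, "P1", genes20, NA)
  a_tgt <- probe_annotation(rownames(tgt_v), rep(genes20, 2), "P2",
                            rep(genes20, 2), NA)
  map2 <- match_by_correlation(fake_signature(rownames(src_v)),
                               expression_matrix(src_v),
                               expression_matrix(tgt_v), a_src, a_tgt)
  expect_gte(sum(grepl("^good", map2$target_id)), 18)
  expect_error(match_by_correlation(fake_signature(rownames(src_v)[1:2]),
                                    expression_matrix(src_v),
                                    expression_matrix(tgt_v), a_src, a_tgt),
               "at least 3")
})

test_that("correlative matching agrees with the brute-force assignment oracle", {
  withr::with_seed(34, {
    n <- 30
    lat <- matrix(rnorm(4 * n), 4, n)
    src_v <- lat + 0.4 * matrix(rnorm(4 * n), 4, n)
    dimnames(src_v) <- list(sprintf("sp%d", 1:4), sprintf("s%d", 1:n))
    cand <- rbind(lat + 0.4 * matrix(rnorm(4 * n), 4, n),
                  matrix(rnorm(4 * n), 4, n))
    rownames(cand) <- c(sprintf("c%dA", 1:4), sprintf("c%dB", 1:4))
    colnames(cand) <- sprintf("t%d", 1:n)
  })
  genes4 <- sprintf("GENE%d", 1:4)
  a_src <- probe_annotation(rownames(src_v), genes4, "P1", genes4, NA)
  a_tgt <- probe_annotation(rownames(cand), rep(genes4, 2), "P2",
                            rep(genes4, 2), NA)
  map <- match_by_correlation(fake_signature(rownames(src_v)),
                              expression_matrix(src_v),
                              expression_matrix(cand), a_src, a_tgt)
  # oracle: enumerate all 2^4 assignments; score an assignment by the summed
  # per-gene correlation between source and target correlation profiles
  cor_src <- cor(t(src_v))
  combos <- expand.grid(rep(list(c("A", "B")), 4), stringsAsFactors = FALSE)
  scores <- apply(combos, 1, function(ch) {
    ids <- sprintf("c%d%s", 1:4, ch)
    cor_tgt <- cor(t(cand[ids, ]))
    sum(vapply(1:4, function(i) cor(cor_src[i, -i], cor_tgt[i, -i]), 0))
  })
  best <- sprintf("c%d%s", 1:4, unlist(combos[which.max(scores), ]))
  expect_identical(map$target_id, best)
})

test_that("matching is invariant to candidate and sample order and conserves rows", {
  cfg <- simulation_config(seed = 22, n_genes = 40, ortholog_dropout = 0.2)
  src <- gen_cell_line_panel(cfg, "source")
  tgt <- gen_cell_line_panel(cfg, "target")
  seqs <- c(src$sequences, tgt$sequences)
  sig <- fake_signature(src$annotation$probe_id[seq(1, 60, by = 2)])
  map <- match_by_homology(sig, src$annotation, tgt$annotation, seqs)
  # conservation: every signature row appears exactly once, mapped xor dropped
  expect_identical(map$source_id, sig$row_id)
  expect_true(all(xor(map$dropped, !is.na(map$target_id))))
  expect_true(all(map$reason[map$dropped] %in%
                    c("no_ortholog", "annotation_failed", "below_threshold")))
  # candidate listing order does not matter
  shuf <- tgt$annotation[withr::with_seed(1, sample(nrow(tgt$annotation))), ]
  expect_equal(match_by_homology(sig, src$annotation, shuf, seqs), map)
  # sample order does not matter for the correlative strategy
  sig3 <- fake_signature(src$annotation$probe_id[1:12])
  m1 <- match_by_correlation(sig3, src$expression, tgt$expression,
                             src$annotation, tgt$annotation)
  perm <- withr::with_seed(2, sample(ncol(tgt$expression)))
  m2 <- match_by_correlation(sig3, src$expression, tgt$expression[, perm],
                             src$annotation, tgt$annotation)
  expect_equal(m1, m2)
})

test_that("collapse operators implement their arithmetic and tie-break rules", {
  v <- matrix(c(1, 2, 3,
                3, 4, 5,
                7, 7, 7.5), 3, 3, byrow = TRUE,
              dimnames = list(c("pA", "pB", "pC"), c("s1", "s2", "s3")))
  annot <- probe_annotation(c("pA", "pB", "pC"), c("G1", "G1", "G2"), "P1",
                            c("G1", "G1", "G2"), NA)
  avg <- collapse_average(expression_matrix(v), annot)
  expect_equal(as_vanilla(avg)["G1", ], c(s1 = 2, s2 = 3, s3 = 4))
  expect_equal(as_vanilla(avg)["G2", ], c(s1 = 7, s2 = 7, s3 = 7.5))

  # max variance keeps the higher-variance probe; ties break lexicographically
  v2 <- matrix(c(0, 2, 4,
                 1, 2, 3,
                 5, 6, 7,
                 8, 9, 10), 4, 3, byrow = TRUE,
               dimnames = list(c("pA", "pB", "pD", "pC"), c("s1", "s2", "s3")))
  annot2 <- probe_annotation(c("pA", "pB", "pD", "pC"),
                             c("G1", "G1", "G2", "G2"), "P1", NA, NA)
  mv <- collapse_max_variance(expression_matrix(v2), annot2)
  expect_equal(unname(attr(mv, "representative_probe")["G1"]), "pA")
  expect_equal(unname(attr(mv, "representative_probe")["G2"]), "pC")  # tie -> id order
  expect_equal(as_vanilla(mv)["G1", ], c(s1 = 0, s2 = 2, s3 = 4))
})

test_that("collapse operators satisfy their conservation properties", {
  withr::with_seed(41, {
    v <- matrix(rnorm(2000), 200, 10,
                dimnames = list(sprintf("p%03d", 1:200), sprintf("s%d", 1:10)))
    genes <- sprintf("G%03d", sample(1:80, 200, replace = TRUE))
  })
  m <- expression_matrix(v)
  annot <- probe_annotation(rownames(v), genes, "P1", genes, NA)
  mv <- collapse_max_variance(m, annot)
  # independent recomputation of the argmax-variance probe per gene
  expected <- vapply(sort(unique(genes)), function(g) {
    probes <- rownames(v)[genes == g]
    vars <- apply(v[probes, , drop = FALSE], 1, var)
    probes[order(-vars, probes)[1]]
  }, "")
  expect_identical(attr(mv, "representative_probe")[names(expected)], expected)
  # no new values fabricated: each collapsed row is an input row
  for (g in rownames(mv))
    expect_equal(as_vanilla(mv)[g, ],
                 v[attr(mv, "representative_probe")[g], ])

  avg <- collapse_average(m, annot)
  # single-probe genes are unchanged
  singles <- names(which(table(genes) == 1))
  for (g in head(singles, 3))
    expect_equal(as_vanilla(avg)[g, ], v[genes == g, ])
  # averaging commutes with per-sample shifts
  shift <- seq_len(ncol(v))
  avg_shifted <- collapse_average(expression_matrix(sweep(v, 2, shift, "+")),
                                  annot)
  expect_equal(as_vanilla(avg_shifted), sweep(as_vanilla(avg), 2, shift, "+"),
               tolerance = 1e-12)
})
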