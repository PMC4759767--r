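two_class_panel <- function(n_genes, n_per_class, sep_gene = NULL, delta = 4,
                            seed = 1) {
  withr::with_seed(seed, {
    n <- 2 * n_per_class
    samples <- sprintf("s%02d", seq_len(n))
    v <- matrix(rnorm(n_genes * n), n_genes, n,
                dimnames = list(sprintf("g%02d", seq_len(n_genes)), samples))
    labels <- setNames(rep(c("sensitive", "resistant"), each = n_per_class),
                       samples)
    if (!is.null(sep_gene))
      v[sep_gene, ] <- ifelse(labels == "sensitive", delta / 2, -delta / 2) +
        rnorm(n, sd = 0.1)
    list(m = expression_matrix(v), labels = labels)
  })
}

test_that("LDA posteriors match the closed-form Gaussian Bayes rule in 1-D", {
  # class means +/- 2, unit variance: logit of the positive class at x is
  # (mu1 - mu2) * (x - (mu1 + mu2) / 2) / sigma^2 = 4x; at x = 2, 1/(1+e^-8)
  n <- 4000
  withr::with_seed(51, {
    x <- c(rnorm(n, 2), rnorm(n, -2))
  })
  samples <- sprintf("s%05d", seq_len(2 * n))
  train <- expression_matrix(matrix(x, 1, 2 * n,
                                    dimnames = list("g1", samples)))
  labels <- setNames(rep(c("sensitive", "resistant"), each = n), samples)
  test <- expression_matrix(matrix(c(2, 0, -2), 1, 3,
                                   dimnames = list("g1", c("a", "b", "c"))))
  post <- lda_posteriors(train, labels, test)
  expect_equal(unname(rowSums(post)), rep(1, 3), tolerance = 1e-12)
  expect_equal(post["a", "sensitive"], 1 / (1 + exp(-8)), tolerance = 0.02)
  expect_equal(post["b", "sensitive"], 0.5, tolerance = 0.02)

  # equidistant point under the pooled metric with equal priors -> 0.5/0.5
  f <- two_class_panel(3, 10, seed = 52)
  mid <- expression_matrix(matrix(
    (rowMeans(as_vanilla(f$m)[, f$labels == "sensitive"]) +
       rowMeans(as_vanilla(f$m)[, f$labels == "resistant"])) / 2, 3, 1,
    dimnames = list(rownames(f$m), "mid")))
  pm <- lda_posteriors(f$m, f$labels, mid, prior = "equal")
  expect_equal(unname(pm["mid", "sensitive"]), 0.5, tolerance = 1e-10)

  # cross-check against the reference LDA implementation on random data
  f2 <- two_class_panel(4, 12, seed = 53)
  tst <- two_class_panel(4, 6, seed = 54)$m
  ours <- lda_posteriors(f2$m, f2$labels, tst)
  mass <- MASS::lda(t(as_vanilla(f2$m)), grouping = factor(f2$labels,
                    levels = c("sensitive", "resistant")))
  theirs <- predict(mass, t(as_vanilla(tst)))$posterior
  expect_equal(unname(ours[, "sensitive"]),
               unname(theirs[, "sensitive"]), tolerance = 1e-6)
})

test_that("MiPP statistics follow the penalized-posterior arithmetic", {
  labels <- setNames(rep("sensitive", 4), sprintf("s%d", 1:4))
  post <- cbind(sensitive = c(0.9, 0.8, 0.7, 0.6),
                resistant = c(0.1, 0.2, 0.3, 0.4))
  rownames(post) <- names(labels)
  st <- mipp_statistics(post, labels)
  expect_equal(st$mipp, 3.0)
  expect_equal(st$smipp, 0.75)

  perfect <- cbind(sensitive = rep(1, 7), resistant = rep(0, 7))
  rownames(perfect) <- sprintf("s%d", 1:7)
  expect_equal(mipp_statistics(perfect,
                               setNames(rep("sensitive", 7), rownames(perfect)))$smipp, 1)
  expect_equal(mipp_statistics(perfect,
                               setNames(rep("resistant", 7), rownames(perfect)))$smipp, -1)

  # additivity: one more correct sample with posterior p adds exactly p;
  # one more misclassified sample subtracts exactly 1
  base <- mipp_statistics(post, labels)$mipp
  post2 <- rbind(post, s5 = c(sensitive = 0.66, resistant = 0.34))
  lab2 <- c(labels, s5 = "sensitive")
  expect_equal(mipp_statistics(post2, lab2)$mipp, base + 0.66)
  lab2_wrong <- c(labels, s5 = "resistant")
  expect_equal(mipp_statistics(post2, lab2_wrong)$mipp, base - 1)
})

test_that("forward selection finds a planted separator and is deterministic", {
  first_hit <- vapply(1:20, function(s) {
    f <- two_class_panel(10, 8, sep_gene = "g03", seed = 60 + s)
    models <- select_models(f$m, f$labels, n_outer_splits = 3,
                            n_eval_splits = 10, rng_seed = s)
    models[[1]]$genes[1] == "g03"
  }, TRUE)
  expect_gte(sum(first_hit), 19)

  f <- two_class_panel(8, 8, sep_gene = "g01", seed = 99)
  m1 <- select_models(f$m, f$labels, rng_seed = 42)
  m2 <- select_models(f$m, f$labels, rng_seed = 42)
  expect_identical(lapply(m1, `[[`, "genes"), lapply(m2, `[[`, "genes"))
  expect_equal(vapply(m1, `[[`, 0, "smipp_eval"),
               vapply(m2, `[[`, 0, "smipp_eval"))
})

test_that("forward selection is near-optimal against the exhaustive subset oracle", {
  f <- two_class_panel(6, 10, sep_gene = "g02", delta = 2, seed = 71)
  X <- t(as_vanilla(f$m))
  # fixed split: reproduce the exact split forward_select() draws first
  split <- coxen:::with_rng(7, coxen:::stratified_split(f$labels, 2 / 3))
  fwd <- coxen:::with_rng(7, coxen:::forward_select(
    X, f$labels, rownames(f$m), "LDA", 2 / 3, 10, 0.01, "proportions"))
  subsets <- unlist(lapply(1:6, function(k)
    combn(rownames(f$m), k, simplify = FALSE)), recursive = FALSE)
  best <- max(vapply(subsets, function(genes) {
    post <- lda_posteriors(f$m[, split$train], f$labels[split$train],
                           f$m[, split$test], genes = genes)
    mipp_statistics(post, f$labels)$smipp
  }, 0))
  expect_gte(fwd$smipp, 0.9 * best)
})

test_that("null data does not yield confident models", {
  smipps <- vapply(1:20, function(s) {
    f <- two_class_panel(10, 10, seed = 300 + s)
    models <- select_models(f$m, f$labels, n_outer_splits = 5,
                            n_eval_splits = 20, rng_seed = s)
    mean(vapply(models, `[[`, 0, "smipp_eval"))
  }, 0)
  expect_lte(mean(smipps), 0.3)
})

test_that("model scores average posteriors and apply the 0.5 call rule", {
  f <- two_class_panel(6, 8, sep_gene = "g01", seed = 81)
  models <- select_models(f$m, f$labels, n_outer_splits = 3,
                          n_eval_splits = 10, rng_seed = 1)
  tst <- two_class_panel(6, 5, sep_gene = "g01", seed = 82)$m
  sc <- predict_scores(models, tst)
  expect_true(all(sc$model_score >= 0 & sc$model_score <= 1))
  expect_identical(sc$call, ifelse(sc$model_score >= 0.5, "sensitive",
                                   "resistant"))
  one <- predict_scores(models[1], tst)
  post1 <- lda_posteriors(f$m, f$labels, tst, genes = models[[1]]$genes)
  expect_equal(one$model_score, unname(post1[, "sensitive"]), tolerance = 1e-9)

  # two models with posteriors 0.9 and 0.1 average to score 0.5, which the
  # boundary rule calls sensitive; built from hand-crafted 1-gene LDA fits
  # with unit variance and means +/- log(9)/2, so the logit at x = 1 is
  # exactly +/- log(9) and the posteriors are exactly 0.9 / 0.1
  m <- log(9) / 2
  mk <- function(mu_s) structure(list(
    genes = "g01", rule = "LDA",
    fit = structure(list(means = list(sensitive = c(g01 = mu_s),
                                      resistant = c(g01 = -mu_s)),
                         inv_cov = matrix(1, 1, 1), genes = "g01",
                         prior = c(sensitive = 0.5, resistant = 0.5)),
                    class = "coxen_lda")), class = "mipp_model")
  point <- expression_matrix(matrix(1, 1, 1, dimnames = list("g01", "x")))
  sc2 <- predict_scores(list(mk(m), mk(-m)), point)
  expect_equal(sc2$model_score, 0.5, tolerance = 1e-9)
  # boundary: a score of exactly 0.5 (each model posterior exactly 0.5 at the
  # class-mean midpoint) is called sensitive
  origin <- expression_matrix(matrix(0, 1, 1, dimnames = list("g01", "x")))
  sc3 <- predict_scores(list(mk(m), mk(-m)), origin)
  expect_identical(sc3$model_score, 0.5)
  expect_identical(sc3$call, "sensitive")

  bad <- models
  bad[[1]]$genes <- c("absent_gene")
  expect_error(predict_scores(bad, tst), "absent_gene")
})
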