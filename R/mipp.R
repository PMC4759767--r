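# Misclassification-penalized posterior (MiPP) model building: pooled-
# covariance LDA posteriors (with optional logistic / SVM rules), the MiPP
# and sMiPP statistics, sequential forward gene selection over random
# training/test splits, and averaged-posterior "model scores".
#
# The MiPP statistic is implemented from its original source (it is cited,
# not printed, in the study this package reproduces): MiPP is the sum of the
# true-class posteriors over correctly classified samples minus the number of
# misclassified samples; sMiPP = MiPP / n.

CLASS_LEVELS <- c("sensitive", "resistant")

#' Pooled-covariance LDA posteriors
#'
#' Gaussian linear discriminant posteriors with a pooled covariance matrix.
#' When the pooled covariance is singular (or near-singular), a ridge
#' `lambda = 1e-6 * trace / p` is added to the diagonal and a message is
#' logged. Posteriors sum to 1 per sample.
#'
#' @param train,test [expression_matrix()]s (genes x samples).
#' @param labels named vector from [select_extremes()] covering the training
#'   samples; each class needs >= 2 of them.
#' @param genes gene subset to use (default: all rows of `train`).
#' @param prior `"proportions"` (class frequencies, default) or `"equal"`.
#' @return matrix (test samples x 2) of posteriors, columns `sensitive`,
#'   `resistant`.
#' @export
lda_posteriors <- function(train, labels, test, genes = rownames(train),
                           prior = c("proportions", "equal")) {
  prior <- match.arg(prior)
  miss <- setdiff(genes, rownames(train))
  if (length(miss))
    stop_argument(sprintf("genes missing from training matrix: %s",
                          paste(head(miss, 5), collapse = ", ")))
  miss <- setdiff(genes, rownames(test))
  if (length(miss))
    stop_argument(sprintf("genes missing from test matrix: %s",
                          paste(head(miss, 5), collapse = ", ")))
  fit <- lda_fit(t(as_plain_matrix(train[genes, names(labels), drop = FALSE])),
                 labels, prior)
  lda_predict(fit, t(as_plain_matrix(test[genes, , drop = FALSE])))
}

# X: samples x genes, y: named labels aligned with rows of X
lda_fit <- function(X, y, prior = "proportions") {
  y <- factor(y[rownames(X)], levels = CLASS_LEVELS)
  if (any(table(y) < 2))
    stop_argument("each class needs at least 2 training samples")
  p <- ncol(X)
  mus <- lapply(CLASS_LEVELS, function(cl) colMeans(X[y == cl, , drop = FALSE]))
  names(mus) <- CLASS_LEVELS
  pooled <- Reduce(`+`, lapply(CLASS_LEVELS, function(cl) {
    Xi <- X[y == cl, , drop = FALSE]
    crossprod(sweep(Xi, 2, mus[[cl]]))
  })) / (nrow(X) - 2)
  ridge_used <- FALSE
  if (p == 1) {
    if (pooled[1, 1] <= 0) { pooled[1, 1] <- 1e-6; ridge_used <- TRUE }
    inv <- 1 / pooled
  } else {
    inv <- tryCatch(solve(pooled), error = function(e) NULL)
    if (is.null(inv) || kappa(pooled) > 1e12) {
      lambda <- 1e-6 * sum(diag(pooled)) / p
      if (lambda <= 0) lambda <- 1e-6
      pooled <- pooled + diag(lambda, p)
      inv <- solve(pooled)
      ridge_used <- TRUE
    }
  }
  if (ridge_used)
    message("singular pooled covariance: ridge regularization applied")
  pr <- if (prior == "equal") c(0.5, 0.5) else as.vector(prop.table(table(y)))
  names(pr) <- CLASS_LEVELS
  structure(list(means = mus, inv_cov = as.matrix(inv), prior = pr,
                 genes = colnames(X)), class = "coxen_lda")
}

lda_predict <- function(fit, X) {
  X <- X[, fit$genes, drop = FALSE]
  disc <- vapply(CLASS_LEVELS, function(cl) {
    mu <- fit$means[[cl]]
    drop(X %*% (fit$inv_cov %*% mu)) - drop(0.5 * t(mu) %*% fit$inv_cov %*% mu) +
      log(fit$prior[[cl]])
  }, numeric(nrow(X)))
  if (is.null(dim(disc))) disc <- matrix(disc, nrow = 1,
                                         dimnames = list(rownames(X), CLASS_LEVELS))
  mx <- apply(disc, 1, max)
  post <- exp(disc - mx)
  post <- post / rowSums(post)
  dimnames(post) <- list(rownames(X), CLASS_LEVELS)
  post
}

# classification-rule plugins ------------------------------------------------

fit_rule <- function(rule, X, y, prior = "proportions") {
  switch(rule,
    LDA = lda_fit(X, y, prior),
    LOG = {
      y01 <- as.integer(factor(y[rownames(X)], levels = CLASS_LEVELS)) == 1L
      df <- data.frame(.y = y01, X, check.names = FALSE)
      structure(list(fit = suppressWarnings(
        glm(.y ~ ., data = df, family = binomial())), genes = colnames(X)),
        class = "coxen_log")
    },
    SVMLIN = ,
    SVMRBF = {
      if (!requireNamespace("e1071", quietly = TRUE))
        stop_argument("SVM rules require the e1071 package")
      kern <- if (rule == "SVMLIN") "linear" else "radial"
      structure(list(fit = e1071::svm(
        X, factor(y[rownames(X)], levels = CLASS_LEVELS), kernel = kern,
        probability = TRUE), genes = colnames(X)), class = "coxen_svm")
    },
    stop_argument(sprintf("unknown classification rule '%s'", rule)))
}

rule_posteriors <- function(fit, X) {
  X <- X[, fit$genes, drop = FALSE]
  if (inherits(fit, "coxen_lda")) return(lda_predict(fit, X))
  if (inherits(fit, "coxen_log")) {
    p_sens <- predict(fit$fit, newdata = data.frame(X, check.names = FALSE),
                      type = "response")
    out <- cbind(sensitive = p_sens, resistant = 1 - p_sens)
    rownames(out) <- rownames(X)
    return(out)
  }
  pr <- attr(predict(fit$fit, X, probability = TRUE), "probabilities")
  out <- pr[, CLASS_LEVELS, drop = FALSE]
  rownames(out) <- rownames(X)
  out
}

#' MiPP statistics of a set of posteriors
#'
#' MiPP = sum of the true-class posteriors over correctly classified samples
#' minus the number of misclassified samples; sMiPP = MiPP / n. A sample is
#' classified sensitive when its sensitive-class posterior is >= 0.5.
#'
#' @param posteriors matrix (samples x 2, columns `sensitive`/`resistant`)
#'   with row names, or a named vector of sensitive-class posteriors.
#' @param labels named true labels (`"sensitive"`/`"resistant"`).
#' @return list with `mipp`, `smipp`, `error_rate`, `n`.
#' @export
mipp_statistics <- function(posteriors, labels) {
  if (is.null(dim(posteriors)))
    posteriors <- cbind(sensitive = posteriors, resistant = 1 - posteriors)
  ids <- rownames(posteriors)
  if (is.null(ids) || !all(ids %in% names(labels)))
    stop_argument("posteriors must be named and covered by the labels")
  if (nrow(posteriors) == 0) stop_argument("no posteriors supplied")
  truth <- labels[ids]
  call <- ifelse(posteriors[, "sensitive"] >= 0.5, "sensitive", "resistant")
  correct <- call == truth
  p_true <- posteriors[cbind(seq_along(truth), match(truth, CLASS_LEVELS))]
  mipp <- sum(p_true[correct]) - sum(!correct)
  n <- length(truth)
  list(mipp = mipp, smipp = mipp / n, error_rate = mean(!correct), n = n)
}

stratified_split <- function(labels, frac) {
  parts <- lapply(CLASS_LEVELS, function(cl) {
    ids <- names(labels)[labels == cl]
    k <- max(2L, round(frac * length(ids)))
    k <- min(k, length(ids) - 2L)
    if (k < 2) stop_argument("classes too small for the requested split")
    sample(ids, k)
  })
  train_ids <- unlist(parts)
  list(train = train_ids, test = setdiff(names(labels), train_ids))
}

forward_select <- function(X, labels, candidates, rule, frac, max_genes, tol,
                           prior) {
  sp <- stratified_split(labels, frac)
  chosen <- character()
  best_smipp <- -Inf
  repeat {
    remaining <- setdiff(candidates, chosen)
    if (!length(remaining) || length(chosen) >= max_genes) break
    trial <- vapply(remaining, function(g) {
      fit <- tryCatch(fit_rule(rule, X[sp$train, c(chosen, g), drop = FALSE],
                               labels, prior), error = function(e) NULL)
      if (is.null(fit)) return(-Inf)
      post <- rule_posteriors(fit, X[sp$test, c(chosen, g), drop = FALSE])
      mipp_statistics(post, labels)$smipp
    }, 0)
    gain <- max(trial) - if (is.finite(best_smipp)) best_smipp else 0
    if (length(chosen) > 0 && gain <= tol) break
    pick <- names(trial)[order(-trial, names(trial))[1]]
    if (!is.finite(trial[pick])) break
    chosen <- c(chosen, pick)
    best_smipp <- trial[pick]
  }
  list(genes = chosen, smipp = best_smipp, split = sp)
}

#' Forward MiPP model selection over random splits
#'
#' For each of `n_outer_splits` random stratified splits of the training
#' panel, runs sequential forward selection: starting from the empty set,
#' repeatedly adds the candidate gene maximizing held-out sMiPP, stopping
#' when the gain drops to `tol` or `max_genes` is reached. Every distinct
#' selected gene set is then re-scored on `n_eval_splits` fresh random
#' splits, and the top `n_top` models by mean evaluation sMiPP are returned,
#' refitted on the full training panel. Fully seeded and deterministic.
#'
#' @param expr training [expression_matrix()] restricted (by the caller) to
#'   the co-expression-filtered candidate genes.
#' @param labels named class labels; each class needs >= 4 samples.
#' @param rule classification rule: `"LDA"` (default), `"LOG"`, `"SVMLIN"`,
#'   `"SVMRBF"`.
#' @param n_outer_splits number of forward-selection splits (default 20).
#' @param n_eval_splits number of evaluation splits (default 50).
#' @param split_fraction training fraction of each split (default 2/3).
#' @param max_genes cap on model size (default 10).
#' @param n_top how many top models to keep (3-5; default 5, the variance-minimizing end of the range).
#' @param tol minimal sMiPP gain to continue forward selection (default 0.01).
#' @param rng_seed seed.
#' @param prior LDA prior, see [lda_posteriors()].
#' @return list of `"mipp_model"` objects (genes, rule, fitted parameters,
#'   training sMiPP, error rate, evaluation sMiPP, seed).
#' @export
select_models <- function(expr, labels, rule = "LDA", n_outer_splits = 20L,
                          n_eval_splits = 50L, split_fraction = 2 / 3,
                          max_genes = 10L, n_top = 5L, tol = 0.01,
                          rng_seed = 1L, prior = "proportions") {
  candidates <- rownames(expr)
  if (length(candidates) < 1) stop_argument("no candidate genes supplied")
  labels <- labels[names(labels) %in% colnames(expr)]
  if (sum(labels == "sensitive") < 4 || sum(labels == "resistant") < 4)
    stop_argument("each class needs at least 4 samples for split-based selection")
  if (n_top < 1) stop_argument("n_top must be at least 1")
  X <- t(as_plain_matrix(expr[, names(labels), drop = FALSE]))
  with_rng(rng_seed, {
    sels <- lapply(seq_len(n_outer_splits), function(b)
      forward_select(X, labels, candidates, rule, split_fraction, max_genes,
                     tol, prior))
    sets <- unique(lapply(sels, function(s) s$genes))
    sets <- Filter(length, sets)
    if (!length(sets))
      stop_argument("forward selection produced no non-empty model")
    eval_splits <- lapply(seq_len(n_eval_splits), function(b)
      stratified_split(labels, split_fraction))
    eval_smipp <- vapply(sets, function(genes) {
      mean(vapply(eval_splits, function(sp) {
        fit <- tryCatch(fit_rule(rule, X[sp$train, genes, drop = FALSE],
                                 labels, prior), error = function(e) NULL)
        if (is.null(fit)) return(-1)
        mipp_statistics(rule_posteriors(fit, X[sp$test, genes, drop = FALSE]),
                        labels)$smipp
      }, 0))
    }, 0)
    keys <- vapply(sets, paste, "", collapse = ",")
    ord <- order(-eval_smipp, keys)
    top <- ord[seq_len(min(n_top, length(sets)))]
    lapply(top, function(i) {
      genes <- sets[[i]]
      fit <- fit_rule(rule, X[, genes, drop = FALSE], labels, prior)
      post <- rule_posteriors(fit, X[, genes, drop = FALSE])
      st <- mipp_statistics(post, labels)
      structure(list(genes = genes, rule = rule, fit = fit,
                     smipp_train = st$smipp, error_rate_train = st$error_rate,
                     smipp_eval = eval_smipp[i], rng_seed = rng_seed),
                class = "mipp_model")
    })
  })
}

#' @export
print.mipp_model <- function(x, ...) {
  cat(sprintf("<mipp_model> rule=%s, %d gene(s): %s\n  sMiPP train=%.3f eval=%.3f, training error=%.3f\n",
              x$rule, length(x$genes), paste(x$genes, collapse = ", "),
              x$smipp_train, x$smipp_eval, x$error_rate_train))
  invisible(x)
}

#' Ensemble model scores on a test panel
#'
#' The "model score" of a sample is the unweighted mean over the selected
#' models of its sensitive-class posterior; samples with score >= 0.5 are
#' called sensitive, below 0.5 resistant.
#'
#' @param models list of models from [select_models()].
#' @param test [expression_matrix()] containing every model gene.
#' @return data.frame of class `"model_score"` with columns `sample_id`,
#'   `model_score`, `call`.
#' @export
predict_scores <- function(models, test) {
  if (!length(models)) stop_argument("no models supplied")
  Xt <- t(as_plain_matrix(test))
  post <- vapply(models, function(mdl) {
    miss <- setdiff(mdl$genes, colnames(Xt))
    if (length(miss))
      stop_data(sprintf("gene '%s' of model (%s) missing from test matrix",
                        miss[1], paste(mdl$genes, collapse = ",")))
    rule_posteriors(mdl$fit, Xt[, mdl$genes, drop = FALSE])[, "sensitive"]
  }, numeric(nrow(Xt)))
  if (is.null(dim(post))) post <- matrix(post, nrow = 1)
  score <- rowMeans(post)
  out <- data.frame(sample_id = colnames(test), model_score = score,
                    call = ifelse(score >= 0.5, "sensitive", "resistant"),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("model_score", "data.frame")
  out
}
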