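# Config-driven orchestration of the seven-step workflow: signature
# identification on the reference panel, cross-platform matching, the
# co-expression filter against a target-like panel, MiPP model building
# (on the reference extremes or, in "in vivo" wiring, on the tumor panel),
# prediction on the test panel, and evaluation.

#' Pipeline configuration
#'
#' @param synthetic a [simulation_config()]; panels are generated from it.
#'   Alternatively pass `datasets`, a list with pre-loaded `reference`,
#'   `coexpression` and `test` panels (each a list as returned by
#'   [load_dataset()] / the generators).
#' @param datasets optional pre-loaded panels (see `synthetic`).
#' @param drug drug to model.
#' @param deg_method `"t-test"` or `"SAM"`.
#' @param deg_cutoffs list of cutoffs passed to the DEG function.
#' @param extremes list with `fraction` or `count` for [select_extremes()].
#' @param match_strategy exactly one of `"homology"`, `"correlation"`,
#'   `"collapse_average"`, `"collapse_max_variance"`.
#' @param coexp_rule `"percentile90"` or `"p05"`.
#' @param n_null_draws draws for [null_cutoff()].
#' @param training_role `"reference"` (train on reference extremes) or
#'   `"tumor-panel"` ("in vivo" wiring: train on the co-expression tumor
#'   panel with responder labels).
#' @param mipp list of settings forwarded to [select_models()].
#' @param cutoffs responder cutoffs, see [responder_cutoffs()].
#' @param seed integer master seed.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(synthetic = NULL, datasets = NULL, drug = "DOX",
                            deg_method = c("t-test", "SAM"),
                            deg_cutoffs = list(),
                            extremes = list(fraction = 0.2),
                            match_strategy = c("homology", "correlation",
                                               "collapse_average",
                                               "collapse_max_variance"),
                            coexp_rule = c("percentile90", "p05"),
                            n_null_draws = 200L,
                            training_role = c("reference", "tumor-panel"),
                            mipp = list(), cutoffs = responder_cutoffs(),
                            seed = 1L) {
  if (is.null(synthetic) && is.null(datasets))
    stop_config("either a synthetic simulation_config or datasets must be given")
  if (length(match_strategy) != 1 ||
      !match_strategy %in% c("homology", "correlation", "collapse_average",
                             "collapse_max_variance"))
    stop_config("exactly one probe-match strategy must be set")
  cfg <- list(synthetic = synthetic, datasets = datasets, drug = drug,
              deg_method = match.arg(deg_method), deg_cutoffs = deg_cutoffs,
              extremes = extremes, match_strategy = match_strategy,
              coexp_rule = match.arg(coexp_rule),
              n_null_draws = as.integer(n_null_draws),
              training_role = match.arg(training_role), mipp = mipp,
              cutoffs = cutoffs, seed = as.integer(seed))
  class(cfg) <- "pipeline_config"
  cfg
}

pipeline_log <- function(state, fmt, ...) {
  line <- sprintf(fmt, ...)
  state$log <- c(state$log, line)
  state
}

#' Run the full modeling pipeline
#'
#' Executes signature identification, cross-platform matching, the
#' co-expression filter, MiPP model selection, test-panel scoring and
#' evaluation, writing every intermediate artifact (signature, map,
#' co-expression result, models, scores, evaluation report, log, config) into
#' `out_dir`. Reruns with the same config reproduce identical outputs.
#'
#' @param config a [pipeline_config()].
#' @param out_dir run directory (created; `NULL` for no files).
#' @return list with all intermediate artifacts and the evaluation report.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (!inherits(config, "pipeline_config"))
    stop_config("config must be a pipeline_config()")
  state <- list(log = character())
  stage <- "load"
  result <- tryCatch({
    # -- panels ---------------------------------------------------------
    if (!is.null(config$synthetic)) {
      sc <- config$synthetic
      ref <- gen_cell_line_panel(sc, "source")
      coexp <- gen_tumor_panel(sc, ref$truth, "target",
                               n_samples = sc$n_coexp_samples,
                               role = "coexpression")
      test <- gen_tumor_panel(sc, ref$truth, "target",
                              n_samples = sc$n_test_samples, role = "test")
      sequences <- c(ref$sequences, coexp$sequences)
      sequences <- sequences[!duplicated(names(sequences))]
    } else {
      ref <- config$datasets$reference
      coexp <- config$datasets$coexpression
      test <- config$datasets$test
      sequences <- c(ref$sequences, coexp$sequences)
      sequences <- sequences[!duplicated(names(sequences))]
    }
    state <- pipeline_log(state, "panels: reference %d x %d, coexpression %d x %d, test %d x %d",
                          nrow(ref$expression), ncol(ref$expression),
                          nrow(coexp$expression), ncol(coexp$expression),
                          nrow(test$expression), ncol(test$expression))

    # -- step 1-2: standardize reference, label extremes ---------------
    stage <- "harmonize"
    strategy <- config$match_strategy
    collapse <- strategy %in% c("collapse_average", "collapse_max_variance")
    if (collapse) {
      collapse_fun <- if (strategy == "collapse_average") collapse_average
                      else collapse_max_variance
      ref_mat <- collapse_fun(ref$expression, ref$annotation,
                              cross_species = TRUE)
      co_mat <- collapse_fun(coexp$expression, coexp$annotation,
                             cross_species = TRUE)
      test_mat <- collapse_fun(test$expression, test$annotation,
                               cross_species = TRUE)
      shared <- shared_genes(ref_mat, co_mat)
      common <- intersect(rownames(shared$a), rownames(test_mat))
      ref_mat <- ref_mat[common, , drop = FALSE]
      co_mat <- co_mat[common, , drop = FALSE]
      test_mat <- test_mat[common, , drop = FALSE]
    } else {
      ref_mat <- ref$expression
      co_mat <- coexp$expression
      test_mat <- test$expression
    }
    ref_std <- standardize_genes(ref_mat)
    labels <- do.call(select_extremes,
                      c(list(response = ref$response, drug = config$drug),
                        config$extremes))
    state <- pipeline_log(state, "extremes: %d sensitive + %d resistant (rule: %s)",
                          sum(labels == "sensitive"), sum(labels == "resistant"),
                          paste(names(config$extremes), unlist(config$extremes),
                                collapse = ", "))

    # -- step 3: differential expression on the extremes ----------------
    stage <- "deg"
    deg_args <- c(list(m = ref_std[, names(labels), drop = FALSE],
                       labels = labels), config$deg_cutoffs)
    sig <- if (config$deg_method == "SAM") {
      deg_args$rng_seed <- deg_args$rng_seed %||% (config$seed + 1L)
      do.call(sam_deg, deg_args)
    } else do.call(ttest_deg, deg_args)
    state <- pipeline_log(state, "signature: %d rows by %s (%s < %g)",
                          nrow(sig), attr(sig, "method"),
                          attr(sig, "cutoff")$rule, attr(sig, "cutoff")$value)
    if (nrow(sig) < 3)
      stop_data("signature has fewer than 3 rows; relax the DEG cutoffs")

    # -- step 4: cross-platform matching --------------------------------
    stage <- "probe_match"
    if (collapse) {
      map <- cross_platform_map(sig$row_id, sig$row_id, strategy, NA_real_,
                                FALSE, NA_character_)
    } else if (strategy == "homology") {
      map <- match_by_homology(sig, ref$annotation, coexp$annotation, sequences)
    } else {
      map <- match_by_correlation(sig, standardize_genes(ref_mat),
                                  standardize_genes(co_mat),
                                  ref$annotation, coexp$annotation)
    }
    kept_map <- map[!map$dropped, , drop = FALSE]
    state <- pipeline_log(state, "matching (%s): %d mapped, %d dropped",
                          strategy, nrow(kept_map), sum(map$dropped))
    if (nrow(kept_map) < 3)
      stop_data("fewer than 3 signature rows mapped across platforms")
    sig_kept <- sig[sig$row_id %in% kept_map$source_id, , drop = FALSE]

    # -- step 5: co-expression filter -----------------------------------
    stage <- "coexpression"
    co_std <- standardize_genes(co_mat)
    test_std <- standardize_genes(test_mat)
    # align the two signature sub-matrices on source row ids
    sig_ref <- ref_std[kept_map$source_id, , drop = FALSE]
    sig_co <- co_std[kept_map$target_id, , drop = FALSE]
    rownames(sig_co) <- kept_map$source_id
    cc <- coexpression_coefficients(sig_ref, sig_co)
    # null universe: gene-level collapse by averaging on both platforms
    if (collapse) {
      null_ref <- ref_std; null_co <- co_std
    } else {
      null_ref <- standardize_genes(
        collapse_average(ref_mat, ref$annotation, cross_species = TRUE))
      null_co <- standardize_genes(
        collapse_average(co_mat, coexp$annotation, cross_species = TRUE))
      sh <- shared_genes(null_ref, null_co)
      null_ref <- sh$a; null_co <- sh$b
    }
    cut <- NULL
    if (config$coexp_rule == "percentile90")
      cut <- null_cutoff(null_ref, null_co, sig_size = nrow(cc),
                         n_draws = config$n_null_draws,
                         rng_seed = config$seed + 2L)
    cc <- coexpression_select(cc, rule = config$coexp_rule, cutoff = cut)
    sig_final <- filter_signature(sig_kept, cc)
    state <- pipeline_log(state, "co-expression filter (%s, cutoff %.3f): %d of %d genes kept",
                          config$coexp_rule, cc$cutoff[1], nrow(sig_final),
                          nrow(cc))

    # -- step 6: MiPP model building ------------------------------------
    stage <- "mipp"
    final_map <- kept_map[kept_map$source_id %in% sig_final$row_id, ,
                          drop = FALSE]
    if (config$training_role == "reference") {
      train_mat <- ref_std[final_map$source_id, names(labels), drop = FALSE]
      train_labels <- labels
      predict_ids <- final_map$source_id
    } else {
      # "in vivo" wiring: train on the co-expression tumor panel with
      # responder labels derived from the drug-specific cutoff
      resp <- label_responders(coexp$clinical, config$drug, config$cutoffs,
                               treated_only = FALSE)
      train_labels <- setNames(ifelse(resp == "responder", "sensitive",
                                      "resistant"), names(resp))
      train_mat <- sig_co[final_map$source_id, names(train_labels), drop = FALSE]
      predict_ids <- final_map$source_id
    }
    mipp_args <- c(list(expr = train_mat, labels = train_labels,
                        rng_seed = config$seed + 3L), config$mipp)
    models <- do.call(select_models, mipp_args)
    state <- pipeline_log(state, "MiPP: %d model(s), eval sMiPP %s",
                          length(models),
                          paste(sprintf("%.3f", vapply(models, `[[`, 0,
                                                       "smipp_eval")),
                                collapse = ", "))

    # -- step 7: predict on the test panel and evaluate -----------------
    stage <- "evaluate"
    test_sig <- test_std[final_map$target_id, , drop = FALSE]
    rownames(test_sig) <- final_map$source_id
    scores <- predict_scores(models, test_sig)
    report <- list()
    if (!is.null(test$clinical)) {
      resp_truth <- label_responders(test$clinical, config$drug, config$cutoffs)
      common <- intersect(names(resp_truth), scores$sample_id)
      pred <- scores$call[match(common, scores$sample_id)]
      k <- sum((pred == "sensitive") == (resp_truth[common] == "responder"))
      report$responder <- list(
        n = length(common), k_correct = k,
        error_rate = 1 - k / length(common),
        binomial_p = binomial_accuracy_test(k, length(common)))
      grp <- setNames(ifelse(pred == "sensitive", "responder", "non-responder"),
                      common)
      if (length(unique(grp)) == 2) {
        lr <- km_logrank(test$clinical, grp)
        report$logrank <- list(statistic = lr$statistic, p = lr$p)
      }
    }
    if (!is.null(test$response))
      report$association <- score_sensitivity_association(scores, test$response,
                                                          config$drug)
    if (!is.null(test$truth$responder)) {
      tr <- ifelse(test$truth$responder[scores$sample_id], "sensitive",
                   "resistant")
      report$truth <- list(
        error_rate = mean(scores$call != tr),
        n = nrow(scores))
    }
    state <- pipeline_log(state, "evaluation: %s",
                          jsonlite::toJSON(report, auto_unbox = TRUE,
                                           digits = 4))
    list(signature = sig, map = map, coexpression = cc,
         signature_final = sig_final, models = models, scores = scores,
         evaluation = report, labels = labels,
         training = list(matrix = train_mat, labels = train_labels),
         test_matrix = test_sig, log = state$log, config = config)
  }, coxen_error = function(e) {
    stop(errorCondition(
      sprintf("pipeline failed at stage '%s': %s", stage, conditionMessage(e)),
      class = class(e)))
  })

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) write.table(x, file.path(out_dir, f), sep = "\t",
                                     quote = FALSE, row.names = FALSE)
    wt(as.data.frame(result$signature), "signature.tsv")
    wt(result$map, "map.tsv")
    wt(result$coexpression, "coexpression.tsv")
    wt(result$scores, "scores.tsv")
    models_json <- lapply(result$models, function(m)
      m[c("genes", "rule", "smipp_train", "smipp_eval", "error_rate_train",
          "rng_seed")])
    jsonlite::write_json(models_json, file.path(out_dir, "models.json"),
                         auto_unbox = TRUE, digits = NA)
    jsonlite::write_json(result$evaluation, file.path(out_dir, "evaluation.json"),
                         auto_unbox = TRUE, digits = NA)
    cfg_out <- result$config
    cfg_out$datasets <- NULL
    jsonlite::write_json(cfg_out, file.path(out_dir, "config.json"),
                         auto_unbox = TRUE, digits = NA, force = TRUE)
    writeLines(result$log, file.path(out_dir, "log.txt"))
  }
  result
}
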