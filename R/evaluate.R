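# Validation of predictions against measured sensitivity and clinical
# outcome: exact binomial accuracy tests, responder labeling against
# drug-specific disease-free-interval cutoffs, Kaplan-Meier / log-rank
# comparisons (with an ordered trend variant), univariate screening plus
# stepwise multivariate proportional-hazards modeling, and the
# treatment-match classification of patients.

#' Exact binomial accuracy test
#'
#' One-sided upper-tail probability P(X >= k) for X ~ Binomial(n, 1/2): the
#' chance that a fair-coin classifier gets at least `k_correct` of `n` calls
#' right.
#'
#' @param k_correct number of correct calls.
#' @param n number of calls.
#' @return p-value.
#' @export
binomial_accuracy_test <- function(k_correct, n) {
  if (n < 1) stop_argument("n must be at least 1")
  if (k_correct < 0 || k_correct > n)
    stop_argument("k_correct must lie in [0, n]")
  pbinom(k_correct - 1, n, 0.5, lower.tail = FALSE)
}

#' Drug-specific responder cutoffs
#'
#' Historical-median disease-free-interval cutoffs used to dichotomize tumor
#' outcomes: 276 days for doxorubicin, 296 days for carboplatin.
#'
#' @param ... named cutoffs in days overriding or extending the defaults.
#' @return named numeric vector of cutoffs.
#' @export
responder_cutoffs <- function(...) {
  out <- c(DOX = 276, CARBO = 296)
  extra <- c(...)
  out[names(extra)] <- extra
  if (any(out <= 0)) stop_config("responder cutoffs must be positive")
  out
}

treatment_drugs <- function(treatment) strsplit(treatment, "+", fixed = TRUE)

#' Label tumors as responders or non-responders
#'
#' A sample treated with (or with a combination containing) the evaluated
#' drug is a responder when its disease-free interval is at or above the
#' drug-specific cutoff (>= rule; the boundary day counts as response).
#' Samples whose treatment does not involve the drug are omitted.
#'
#' @param clin a [clinical_table()].
#' @param drug the drug whose model is being evaluated.
#' @param cutoffs named cutoff vector from [responder_cutoffs()].
#' @param treated_only restrict to samples whose treatment involved `drug`
#'   (default). With `FALSE`, every sample is labeled against the drug's
#'   cutoff (as when deriving training labels for a whole tumor panel).
#' @return named character vector `"responder"`/`"non-responder"` over the
#'   evaluable samples.
#' @export
label_responders <- function(clin, drug, cutoffs = responder_cutoffs(),
                             treated_only = TRUE) {
  if (!drug %in% names(cutoffs))
    stop_config(sprintf("no responder cutoff configured for drug '%s'", drug))
  treated <- if (treated_only)
    vapply(treatment_drugs(clin$treatment), function(d) drug %in% d, TRUE)
  else rep(TRUE, nrow(clin))
  cl <- clin[treated, , drop = FALSE]
  if (nrow(cl) == 0)
    stop_argument(sprintf("no sample was treated with '%s'", drug))
  setNames(ifelse(cl$dfi_days >= cutoffs[[drug]], "responder", "non-responder"),
           cl$sample_id)
}

#' Kaplan-Meier curves and log-rank comparison
#'
#' Kaplan-Meier estimates per group and the log-rank chi-square test across
#' groups. With `ordered = TRUE` (groups given as a factor whose level order
#' is the hypothesized ordering), the trend variant with equally spaced
#' scores 0..k-1 is computed from the per-group observed/expected counts and
#' their covariance.
#'
#' @param clin a [clinical_table()].
#' @param groups named vector/factor of group labels over (a subset of) the
#'   clinical samples.
#' @param ordered use the ordered-alternative trend log-rank.
#' @return list with `fit` (a [survival::survfit] object), `statistic`, `df`,
#'   `p`, and the per-group observed/expected table.
#' @export
km_logrank <- function(clin, groups, ordered = FALSE) {
  ids <- intersect(clin$sample_id, names(groups))
  cl <- clin[match(ids, clin$sample_id), , drop = FALSE]
  g <- factor(groups[ids], levels = if (is.factor(groups)) levels(groups)
              else sort(unique(as.character(groups))))
  g <- droplevels(g)
  if (nlevels(g) < 2) stop_argument("need at least 2 non-empty groups")
  surv <- survival::Surv(cl$dfi_days, cl$event)
  fit <- survival::survfit(surv ~ g)
  sd <- survival::survdiff(surv ~ g)
  if (!ordered) {
    stat <- sd$chisq
    df <- nlevels(g) - 1
  } else {
    w <- seq_len(nlevels(g)) - 1
    oe <- sd$obs - sd$exp
    num <- sum(w * oe)^2
    den <- drop(t(w) %*% sd$var %*% w)
    stat <- num / den
    df <- 1
  }
  list(fit = fit, statistic = as.numeric(stat), df = df,
       p = pchisq(stat, df, lower.tail = FALSE),
       table = data.frame(group = levels(g), n = as.vector(sd$n),
                          observed = sd$obs, expected = sd$exp))
}

#' Univariate screen and stepwise multivariate proportional-hazards model
#'
#' Fits a univariate Cox proportional-hazards model per covariate (hazard
#' ratio, 95% CI, p). Covariates with univariate p below `screen_p` enter a
#' multivariate fit that is then reduced by bidirectional stepwise selection
#' (AIC by default; `criterion = "p"` drops the least significant covariate
#' until all are below 0.05). Non-converging covariates are reported and
#' excluded with a warning.
#'
#' @param clin a [clinical_table()].
#' @param covariates covariate column names in `clin`.
#' @param screen_p univariate screening threshold (default 0.25).
#' @param criterion stepwise criterion, `"AIC"` (default) or `"p"`.
#' @return list with `univariate` and `multivariate` HR tables and the final
#'   `fit`.
#' @export
cox_analysis <- function(clin, covariates, screen_p = 0.25,
                         criterion = c("AIC", "p")) {
  criterion <- match.arg(criterion)
  if (sum(clin$event) < 10)
    stop_argument("proportional-hazards analysis needs at least 10 events")
  miss <- setdiff(covariates, names(clin))
  if (length(miss))
    stop_argument(sprintf("covariates absent from clinical table: %s",
                          paste(miss, collapse = ", ")))
  surv <- survival::Surv(clin$dfi_days, clin$event)
  uni <- do.call(rbind, lapply(covariates, function(cv) {
    fit <- tryCatch(
      survival::coxph(surv ~ x, data = data.frame(x = clin[[cv]])),
      error = function(e) NULL, warning = function(w) NULL)
    if (is.null(fit) || !is.finite(coef(fit))) {
      warning(sprintf("univariate fit for '%s' did not converge; excluded", cv),
              call. = FALSE)
      return(data.frame(covariate = cv, hr = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, p = NA_real_))
    }
    s <- summary(fit)
    data.frame(covariate = cv, hr = unname(s$conf.int[1, "exp(coef)"]),
               ci_lower = unname(s$conf.int[1, 3]),
               ci_upper = unname(s$conf.int[1, 4]),
               p = unname(s$coefficients[1, "Pr(>|z|)"]))
  }))
  screened <- uni$covariate[!is.na(uni$p) & uni$p < screen_p]
  multivariate <- NULL; final_fit <- NULL
  if (length(screened)) {
    dat <- clin[, c("dfi_days", "event", screened), drop = FALSE]
    full <- survival::coxph(
      stats::as.formula(paste("survival::Surv(dfi_days, event) ~",
                              paste(screened, collapse = " + "))),
      data = dat)
    final_fit <- if (criterion == "AIC") {
      MASS::stepAIC(full, direction = "both", trace = 0)
    } else {
      fit <- full
      repeat {
        ps <- summary(fit)$coefficients[, "Pr(>|z|)"]
        if (all(ps < 0.05) || length(ps) <= 1) break
        keep <- setdiff(names(ps)[-which.max(ps)], "")
        if (!length(keep)) break
        fit <- survival::coxph(
          stats::as.formula(paste("survival::Surv(dfi_days, event) ~",
                                  paste(keep, collapse = " + "))), data = dat)
      }
      fit
    }
    if (length(coef(final_fit))) {
      s <- summary(final_fit)
      multivariate <- data.frame(covariate = rownames(s$coefficients),
                                 hr = unname(s$conf.int[, "exp(coef)"]),
                                 ci_lower = unname(s$conf.int[, 3]),
                                 ci_upper = unname(s$conf.int[, 4]),
                                 p = unname(s$coefficients[, "Pr(>|z|)"]))
      rownames(multivariate) <- NULL
    }
  }
  list(univariate = uni, screened = screened, multivariate = multivariate,
       fit = final_fit)
}

#' Classify patients as treatment-matched or mismatched
#'
#' A patient is "matched" when the model for the drug actually received
#' predicts sensitivity (model score > 0.5). For combination-treated patients
#' the `strict` rule requires both drugs' scores > 0.5; the `relaxed` rule
#' requires at least one.
#'
#' @param scores_by_drug named list of [predict_scores()] results, one per
#'   drug.
#' @param clin a [clinical_table()].
#' @param combo_rule `"strict"` or `"relaxed"`.
#' @return named character vector `"matched"`/`"mismatched"` over the
#'   clinical samples.
#' @export
coxen_match <- function(scores_by_drug, clin, combo_rule = c("strict", "relaxed")) {
  combo_rule <- match.arg(combo_rule)
  score_of <- function(drug, sample) {
    tab <- scores_by_drug[[drug]]
    if (is.null(tab))
      stop_data(sprintf("no score table for drug '%s' (sample '%s')",
                        drug, sample))
    i <- match(sample, tab$sample_id)
    if (is.na(i))
      stop_data(sprintf("missing %s score for sample '%s'", drug, sample))
    tab$model_score[i]
  }
  drugs_per <- treatment_drugs(clin$treatment)
  out <- vapply(seq_len(nrow(clin)), function(i) {
    sc <- vapply(drugs_per[[i]], score_of, 0, sample = clin$sample_id[i])
    sens <- sc > 0.5
    ok <- if (length(sens) == 1) sens
          else if (combo_rule == "strict") all(sens) else any(sens)
    if (ok) "matched" else "mismatched"
  }, "")
  setNames(out, clin$sample_id)
}

#' Association between model scores and measured drug response
#'
#' Z-standardizes both the model scores and the log-scale response values and
#' reports (a) their Pearson and Spearman correlations and (b) a
#' proportional-hazards fit that treats the (shifted-positive) standardized
#' response as an uncensored "time" with the standardized score as covariate.
#' Sensitive = low response, so a useful model has negative correlation.
#'
#' @param scores a [predict_scores()] result.
#' @param response a [drug_response_table()].
#' @param drug drug to evaluate.
#' @return list with `pearson`, `spearman` (estimate + p each), `cox`
#'   (hr, p), `n`; or a one-element list `undefined = TRUE` with a `reason`
#'   when scores have zero variance.
#' @export
score_sensitivity_association <- function(scores, response, drug) {
  r <- response[response$drug == drug, , drop = FALSE]
  ids <- intersect(scores$sample_id, r$sample_id)
  if (length(ids) < 5)
    stop_argument("need at least 5 overlapping samples")
  s <- scores$model_score[match(ids, scores$sample_id)]
  y <- r$log10_response[match(ids, r$sample_id)]
  if (sd(s) == 0 || sd(y) == 0)
    return(list(undefined = TRUE,
                reason = "zero-variance scores or responses"))
  sz <- (s - mean(s)) / sd(s)
  yz <- (y - mean(y)) / sd(y)
  pe <- cor.test(sz, yz, method = "pearson")
  sp <- suppressWarnings(cor.test(sz, yz, method = "spearman"))
  # rank-invariant in time, so the shift to positive values is immaterial;
  # perfectly monotone score-response pairs give a divergent (infinite-HR)
  # fit, which is still reported rather than raised
  cox <- suppressWarnings(
    survival::coxph(survival::Surv(yz - min(yz) + 1,
                                   rep(1L, length(yz))) ~ sz))
  scox <- summary(cox)
  list(pearson = list(estimate = unname(pe$estimate), p = pe$p.value),
       spearman = list(estimate = unname(sp$estimate), p = sp$p.value),
       cox = list(hr = unname(scox$conf.int[1, "exp(coef)"]),
                  p = unname(scox$coefficients[1, "Pr(>|z|)"])),
       n = length(ids))
}
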