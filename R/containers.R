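#' @importFrom stats cor cor.test median pbinom pchisq pt quantile rbinom
#'   rexp rnorm runif sd setNames var mad p.adjust predict binomial coef glm
#' @importFrom utils read.delim write.table head
NULL

# condition helpers ----------------------------------------------------------

coxen_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "coxen_error", "error")))
}
stop_config   <- function(msg) coxen_stop(msg, "coxen_config_error")
stop_format   <- function(msg) coxen_stop(msg, "coxen_format_error")
stop_argument <- function(msg) coxen_stop(msg, "coxen_argument_error")
stop_data     <- function(msg) coxen_stop(msg, "coxen_data_error")

#' Construct an expression matrix
#'
#' A thin matrix container for log-scale expression values with row
#' (probe or gene) and column (sample) identifiers plus platform/species
#' metadata. All downstream stages consume and return this class.
#'
#' @param values numeric matrix, rows = probes or genes, columns = samples;
#'   must carry unique dimnames and contain only finite values.
#' @param level `"probe"` or `"gene"`; at gene level row names are gene
#'   symbols, one row per gene.
#' @param platform platform label (e.g. an array name).
#' @param species species label.
#' @return a matrix of class `"expression_matrix"` with `level`, `platform`
#'   and `species` attributes.
#' @export
expression_matrix <- function(values, level = c("probe", "gene"),
                              platform = "unknown", species = "unknown") {
  level <- match.arg(level)
  if (!is.matrix(values) || !is.numeric(values))
    stop_format("expression values must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop_format("expression matrix must have row and column names")
  dup_r <- rownames(values)[duplicated(rownames(values))]
  if (length(dup_r))
    stop_format(sprintf("duplicate row id(s): %s",
                        paste(unique(dup_r), collapse = ", ")))
  dup_c <- colnames(values)[duplicated(colnames(values))]
  if (length(dup_c))
    stop_format(sprintf("duplicate sample id(s): %s",
                        paste(unique(dup_c), collapse = ", ")))
  if (!all(is.finite(values)))
    stop_format("expression matrix contains non-finite values")
  structure(values, class = c("expression_matrix", class(matrix())),
            level = level, platform = platform, species = species)
}

#' @export
`[.expression_matrix` <- function(x, i, j, ..., drop = FALSE) {
  out <- NextMethod(drop = drop)
  if (is.matrix(out)) {
    attr(out, "level")    <- attr(x, "level")
    attr(out, "platform") <- attr(x, "platform")
    attr(out, "species")  <- attr(x, "species")
    class(out) <- class(x)
  }
  out
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d x %d [%s level, platform=%s, species=%s]\n",
              nrow(x), ncol(x), attr(x, "level"), attr(x, "platform"),
              attr(x, "species")))
  print(utils::head(unclass(x)[, seq_len(min(5, ncol(x))), drop = FALSE]))
  invisible(x)
}

as_plain_matrix <- function(m) {
  attributes(m) <- list(dim = dim(m), dimnames = dimnames(m))
  m
}

#' Construct a probe annotation table
#'
#' @param probe_id character, unique per platform.
#' @param gene_symbol character, non-empty gene symbol per probe.
#' @param platform platform label (recycled).
#' @param ortholog_gene gene symbol of the ortholog on the partner platform;
#'   `NA` where no ortholog is annotated.
#' @param sequence_id optional key into a FASTA store of probe target
#'   sequences; `NA` where absent.
#' @return data.frame of class `"probe_annotation"`.
#' @export
probe_annotation <- function(probe_id, gene_symbol, platform = "unknown",
                             ortholog_gene = NA_character_,
                             sequence_id = NA_character_) {
  if (anyDuplicated(probe_id))
    stop_format(sprintf("duplicate probe id(s): %s",
      paste(unique(probe_id[duplicated(probe_id)]), collapse = ", ")))
  if (any(!nzchar(gene_symbol) | is.na(gene_symbol)))
    stop_format("gene symbols must be non-empty")
  out <- data.frame(probe_id = as.character(probe_id),
                    gene_symbol = as.character(gene_symbol),
                    platform = as.character(platform),
                    ortholog_gene = as.character(ortholog_gene),
                    sequence_id = as.character(sequence_id),
                    stringsAsFactors = FALSE)
  class(out) <- c("probe_annotation", "data.frame")
  out
}

#' Construct a drug response table
#'
#' One row per (sample, drug): the log10 median-effect dose (Dm) or log10
#' GI50. Lower values mean more sensitive.
#'
#' @param sample_id,drug,log10_response vectors of equal length.
#' @return data.frame of class `"drug_response"`.
#' @export
drug_response_table <- function(sample_id, drug, log10_response) {
  if (any(!is.finite(log10_response)))
    stop_format("drug response values must be finite")
  key <- paste(sample_id, drug, sep = "\r")
  if (anyDuplicated(key))
    stop_format("more than one response value for some (sample, drug) pair")
  out <- data.frame(sample_id = as.character(sample_id),
                    drug = as.character(drug),
                    log10_response = as.numeric(log10_response),
                    stringsAsFactors = FALSE)
  class(out) <- c("drug_response", "data.frame")
  out
}

#' Construct a clinical outcome table
#'
#' @param sample_id sample identifiers.
#' @param dfi_days disease-free interval in days (> 0).
#' @param event 1 = recurrence/death observed, 0 = censored.
#' @param treatment treatment arm, e.g. `"DOX"`, `"CARBO"` or `"DOX+CARBO"`.
#' @param ... additional covariate columns (equal length vectors), e.g.
#'   `proximal_humerus`, `alp_elevated`, `monocytes`, `lymphocytes`,
#'   `body_weight_kg`, `age_years`.
#' @return data.frame of class `"clinical_table"`.
#' @export
clinical_table <- function(sample_id, dfi_days, event, treatment, ...) {
  if (any(dfi_days <= 0)) stop_format("dfi_days must be > 0")
  if (!all(event %in% c(0L, 1L))) stop_format("event must be 0 or 1")
  out <- data.frame(sample_id = as.character(sample_id),
                    dfi_days = as.numeric(dfi_days),
                    event = as.integer(event),
                    treatment = as.character(treatment),
                    stringsAsFactors = FALSE)
  extra <- list(...)
  for (nm in names(extra)) out[[nm]] <- extra[[nm]]
  class(out) <- c("clinical_table", "data.frame")
  out
}

#' Construct a gene signature
#'
#' Ordered list of differentially expressed rows with statistics, as produced
#' by [ttest_deg()] / [sam_deg()].
#'
#' @param entries data.frame with columns `row_id`, `statistic`, `p` (NA for
#'   SAM), `q`, `direction` (`"up-in-sensitive"` / `"down-in-sensitive"`).
#' @param method `"t-test"` or `"SAM"`.
#' @param cutoff list recording the rule actually applied, e.g.
#'   `list(rule = "q", value = 0.05)`.
#' @return data.frame of class `"gene_signature"` with `method` and `cutoff`
#'   attributes.
#' @export
gene_signature <- function(entries, method, cutoff) {
  need <- c("row_id", "statistic", "p", "q", "direction")
  if (!all(need %in% names(entries)))
    stop_argument(sprintf("signature entries need columns: %s",
                          paste(need, collapse = ", ")))
  structure(entries, class = c("gene_signature", "data.frame"),
            method = method, cutoff = cutoff)
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %d entries, method=%s, cutoff: %s < %g\n",
              nrow(x), attr(x, "method"), attr(x, "cutoff")$rule,
              attr(x, "cutoff")$value))
  print(utils::head(as.data.frame(x)))
  invisible(x)
}
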