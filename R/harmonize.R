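# Loading, within-gene standardization, and sensitivity-extreme labeling.

#' Load a dataset from plain-text files
#'
#' Reads the tabular dialects written by [write_panel()]: an expression TSV
#' (first column = row id, header = sample ids), optional probe-annotation,
#' drug-response, clinical TSVs and a FASTA of probe target sequences.
#' Cross-references sample ids and reports response/clinical samples absent
#' from the expression matrix.
#'
#' @param paths named list or vector with element `expression` and optionally
#'   `annotation`, `response`, `clinical`, `fasta`.
#' @param level,platform,species metadata attached to the expression matrix.
#' @return list with elements `expression`, `annotation`, `response`,
#'   `clinical`, `sequences` (absent components are `NULL`).
#' @export
load_dataset <- function(paths, level = "probe", platform = "unknown",
                         species = "unknown") {
  paths <- as.list(paths)
  if (is.null(paths$expression))
    stop_argument("paths must name an 'expression' file")
  for (p in unlist(paths))
    if (!file.exists(p)) stop_data(sprintf("file not found: %s", p))

  raw <- read.delim(paths$expression, check.names = FALSE,
                    colClasses = "character", stringsAsFactors = FALSE)
  ids <- raw[[1]]
  dup <- unique(ids[duplicated(ids)])
  if (length(dup))
    stop_format(sprintf("duplicate row id(s) in expression file: %s",
                        paste(dup, collapse = ", ")))
  cells <- as.matrix(raw[, -1, drop = FALSE])
  values <- suppressWarnings(matrix(as.numeric(cells), nrow(cells), ncol(cells),
                                    dimnames = list(ids, colnames(cells))))
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1, ]
    stop_format(sprintf(
      "non-numeric expression value at row '%s', column '%s'",
      ids[bad["row"]], colnames(cells)[bad["col"]]))
  }
  expr <- expression_matrix(values, level = level, platform = platform,
                            species = species)

  annot <- NULL
  if (!is.null(paths$annotation)) {
    a <- read.delim(paths$annotation, stringsAsFactors = FALSE,
                    colClasses = "character")
    og <- a$ortholog_gene %||% rep(NA_character_, nrow(a))
    og[is.na(og) | !nzchar(og)] <- NA_character_
    annot <- probe_annotation(a$probe_id, a$gene_symbol,
                              a$platform %||% "unknown", og,
                              a$sequence_id %||% NA_character_)
  }
  response <- NULL
  if (!is.null(paths$response)) {
    r <- read.delim(paths$response, stringsAsFactors = FALSE)
    response <- drug_response_table(r$sample_id, r$drug, r$log10_response)
    unknown <- setdiff(response$sample_id, colnames(expr))
    if (length(unknown))
      warning(sprintf("response table samples absent from expression matrix: %s",
                      paste(unknown, collapse = ", ")), call. = FALSE)
  }
  clinical <- NULL
  if (!is.null(paths$clinical)) {
    cl <- read.delim(paths$clinical, stringsAsFactors = FALSE)
    extra <- cl[, setdiff(names(cl), c("sample_id", "dfi_days", "event",
                                       "treatment")), drop = FALSE]
    clinical <- do.call(clinical_table,
                        c(list(sample_id = cl$sample_id, dfi_days = cl$dfi_days,
                               event = cl$event, treatment = cl$treatment),
                          as.list(extra)))
    unknown <- setdiff(clinical$sample_id, colnames(expr))
    if (length(unknown))
      warning(sprintf("clinical table samples absent from expression matrix: %s",
                      paste(unknown, collapse = ", ")), call. = FALSE)
  }
  sequences <- NULL
  if (!is.null(paths$fasta)) {
    ss <- Biostrings::readDNAStringSet(paths$fasta)
    sequences <- setNames(as.character(ss), names(ss))
  }
  list(expression = expr, annotation = annot, response = response,
       clinical = clinical, sequences = sequences)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Within-gene standardization
#'
#' Centers and scales every row to mean 0 and sample standard deviation 1
#' (n-1 denominator), the footing on which expression from different species
#' and platforms is compared. Constant rows cannot be standardized; they are
#' dropped with a warning naming them.
#'
#' @param m an [expression_matrix()] with at least 2 samples.
#' @return an [expression_matrix()] of the same level/platform/species with
#'   standardized rows (constant rows removed).
#' @export
standardize_genes <- function(m) {
  if (ncol(m) < 2) stop_argument("standardization needs at least 2 samples")
  v <- as_plain_matrix(m)
  mu <- rowMeans(v)
  s <- apply(v, 1, sd)
  constant <- s == 0 | !is.finite(s)
  if (any(constant)) {
    warning(sprintf("dropping %d constant row(s): %s", sum(constant),
                    paste(head(rownames(v)[constant], 5), collapse = ", ")),
            call. = FALSE)
    v <- v[!constant, , drop = FALSE]
    mu <- mu[!constant]; s <- s[!constant]
  }
  out <- (v - mu) / s
  expression_matrix(out, level = attr(m, "level"),
                    platform = attr(m, "platform"), species = attr(m, "species"))
}

#' Label drug-sensitivity extremes
#'
#' Ranks samples by response to `drug` (low log GI50 / Dm = sensitive) and
#' labels the lowest k as `"sensitive"` and the highest k as `"resistant"`,
#' excluding the middle. k is either given directly (`count`) or as a
#' fraction of the panel (`fraction`, k = round(f * n)). Ties at the cutoffs
#' are broken by stable lexicographic sample-id order, so labels are
#' deterministic and invariant under monotone transforms of the responses.
#'
#' @param response a [drug_response_table()].
#' @param drug drug to rank by.
#' @param fraction fraction per extreme (default 0.2, i.e. top and bottom
#'   20 percent); ignored when `count` is given.
#' @param count samples per extreme.
#' @return named character vector (values `"sensitive"`/`"resistant"`,
#'   names = sample ids); excluded samples are absent.
#' @export
select_extremes <- function(response, drug, fraction = 0.2, count = NULL) {
  r <- response[response$drug == drug, , drop = FALSE]
  if (nrow(r) == 0) stop_argument(sprintf("drug '%s' not in response table", drug))
  n <- nrow(r)
  k <- if (!is.null(count)) as.integer(count) else as.integer(round(fraction * n))
  if (k < 1) stop_argument("extreme group size must be at least 1")
  if (2 * k > n)
    stop_argument(sprintf("cannot take %d + %d extremes from %d samples", k, k, n))
  ord <- order(r$log10_response, r$sample_id)
  sens <- r$sample_id[ord[seq_len(k)]]
  res <- r$sample_id[ord[seq(n - k + 1, n)]]
  setNames(c(rep("sensitive", k), rep("resistant", k)), c(sens, res))
}
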