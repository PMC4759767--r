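# Synthetic paired-species panels with a planted, partially conserved
# drug-sensitivity signature. Gene-level signal for signature genes is
# a_g * latent sensitivity; probes replicate the gene signal with independent
# probe noise; drug response is a monotone (decreasing) function of latent
# sensitivity so that low log-dose = sensitive.

#' Simulation configuration for the synthetic panels
#'
#' Defaults emulate the study layout of a 60-line human reference panel, a
#' 16-tumor co-expression panel, and a 33-tumor test panel with a 20-gene
#' drug-sensitivity signature of standardized effect size 2.
#'
#' @param seed integer RNG seed (all generator randomness derives from it).
#' @param n_ref_samples,n_coexp_samples,n_test_samples panel sizes.
#' @param n_genes size of the shared ortholog gene universe.
#' @param probes_per_gene_range named list with integer pairs `source` and
#'   `target`: the range of probes per gene on each platform.
#' @param n_signature_genes number of genes carrying sensitivity signal.
#' @param effect_size planted standardized mean difference (in units of the
#'   within-group standard deviation) between extreme sensitivity groups.
#' @param conservation_fraction fraction of signature genes whose
#'   co-expression structure (coupling to the latent factor) is preserved in
#'   the tumor panels; the rest are scrambled by gene-wise permutation.
#' @param noise_sd residual gene-level noise standard deviation; probe noise
#'   is `0.25 * noise_sd`.
#' @param censoring_rate fraction of tumor samples censored.
#' @param dfi_scale_days baseline disease-free-interval scale in days.
#' @param drug_names drugs for which responses are generated.
#' @param ortholog_dropout fraction of genes lacking an annotated ortholog on
#'   the partner platform (exercises the drop-with-reason path).
#' @param mutation_rate per-base substitution rate applied to the shared
#'   ancestor sequence when deriving probe target sequences.
#' @return list of class `"simulation_config"`.
#' @export
simulation_config <- function(seed = 1L,
                              n_ref_samples = 60L,
                              n_coexp_samples = 16L,
                              n_test_samples = 33L,
                              n_genes = 200L,
                              probes_per_gene_range = list(source = c(1L, 3L),
                                                           target = c(1L, 3L)),
                              n_signature_genes = 20L,
                              effect_size = 2,
                              conservation_fraction = 0.8,
                              noise_sd = 1,
                              censoring_rate = 0.2,
                              dfi_scale_days = 300,
                              drug_names = c("DOX", "CARBO"),
                              ortholog_dropout = 0.05,
                              mutation_rate = 0.05) {
  cfg <- list(seed = as.integer(seed), n_ref_samples = as.integer(n_ref_samples),
              n_coexp_samples = as.integer(n_coexp_samples),
              n_test_samples = as.integer(n_test_samples),
              n_genes = as.integer(n_genes),
              probes_per_gene_range = probes_per_gene_range,
              n_signature_genes = as.integer(n_signature_genes),
              effect_size = effect_size,
              conservation_fraction = conservation_fraction,
              noise_sd = noise_sd, censoring_rate = censoring_rate,
              dfi_scale_days = dfi_scale_days,
              drug_names = as.character(drug_names),
              ortholog_dropout = ortholog_dropout,
              mutation_rate = mutation_rate)
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  chk <- function(ok, field, why)
    if (!ok) stop_config(sprintf("invalid configuration field '%s': %s", field, why))
  chk(length(cfg$seed) == 1 && is.finite(cfg$seed), "seed", "must be a single integer")
  for (f in c("n_ref_samples", "n_coexp_samples", "n_test_samples", "n_genes",
              "n_signature_genes"))
    chk(cfg[[f]] >= 1, f, "must be a positive count")
  chk(cfg$n_signature_genes <= cfg$n_genes, "n_signature_genes",
      "cannot exceed n_genes")
  chk(cfg$conservation_fraction >= 0 && cfg$conservation_fraction <= 1,
      "conservation_fraction", "must lie in [0, 1]")
  chk(cfg$censoring_rate >= 0 && cfg$censoring_rate < 1, "censoring_rate",
      "must lie in [0, 1)")
  chk(cfg$noise_sd > 0, "noise_sd", "must be > 0")
  chk(cfg$effect_size >= 0, "effect_size", "must be >= 0")
  chk(cfg$dfi_scale_days > 0, "dfi_scale_days", "must be > 0")
  chk(is.list(cfg$probes_per_gene_range) &&
        all(c("source", "target") %in% names(cfg$probes_per_gene_range)),
      "probes_per_gene_range", "must be a list with 'source' and 'target' pairs")
  for (side in c("source", "target")) {
    rng <- cfg$probes_per_gene_range[[side]]
    chk(length(rng) == 2 && rng[1] >= 1 && rng[2] >= rng[1],
        "probes_per_gene_range",
        sprintf("%s range must be an increasing pair with lower bound >= 1", side))
  }
  chk(length(cfg$drug_names) >= 1 && all(nzchar(cfg$drug_names)), "drug_names",
      "must list at least one drug")
  chk(cfg$ortholog_dropout >= 0 && cfg$ortholog_dropout < 1, "ortholog_dropout",
      "must lie in [0, 1)")
  chk(cfg$mutation_rate >= 0 && cfg$mutation_rate < 1, "mutation_rate",
      "must lie in [0, 1)")
  invisible(cfg)
}

# Run expr with a private RNG stream so generator calls are reproducible and
# do not disturb the caller's RNG state.
with_rng <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed %% .Machine$integer.max)
  force(expr)
}

mutate_sequence <- function(seq, rate) {
  bases <- c("A", "C", "G", "T")
  chars <- strsplit(seq, "")[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) {
    repl <- vapply(chars[hit],
                   function(b) sample(setdiff(bases, b), 1L), "")
    chars[hit] <- repl
  }
  paste(chars, collapse = "")
}

# Platform layout shared by both species: gene universe, ortholog links,
# signature membership, per-gene signal coefficients, probe maps and probe
# target sequences derived from a common ancestor per gene. Deterministic in
# config$seed so independent generator calls agree.
make_platform_pair <- function(cfg) {
  with_rng(cfg$seed, {
    genes <- sprintf("G%04d", seq_len(cfg$n_genes))
    sig <- sort(sample(genes, cfg$n_signature_genes))
    n_cons <- round(cfg$conservation_fraction * cfg$n_signature_genes)
    conserved <- sort(sample(sig, n_cons))
    # signed coupling to the latent factor; half up-in-sensitive
    a <- setNames(numeric(cfg$n_genes), genes)
    sign_pattern <- rep(c(1, -1), length.out = length(sig))
    a[sig] <- sign_pattern * cfg$effect_size / 2 * cfg$noise_sd
    baseline <- setNames(rnorm(cfg$n_genes, mean = 7, sd = 1.5), genes)
    ancestor <- setNames(vapply(genes, function(g)
      paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE), collapse = ""),
      ""), genes)
    dropout <- setNames(runif(cfg$n_genes) < cfg$ortholog_dropout, genes)

    build_side <- function(side, species, platform) {
      rng <- cfg$probes_per_gene_range[[side]]
      k <- sample(seq(rng[1], rng[2]), cfg$n_genes, replace = TRUE)
      gene_of_probe <- rep(genes, k)
      probe_id <- sprintf("%s_%s_p%d", substr(species, 1, 2), gene_of_probe,
                          unlist(lapply(k, seq_len)))
      # first probe per gene is the faithful copy of the ancestor; later
      # probes drift more, so homology matching has a well-defined truth
      probe_rank <- unlist(lapply(k, seq_len))
      seqs <- setNames(mapply(function(g, r) {
        rate <- if (r == 1L) cfg$mutation_rate / 2 else min(0.95, cfg$mutation_rate * 3)
        mutate_sequence(ancestor[[g]], rate)
      }, gene_of_probe, probe_rank), probe_id)
      annot <- probe_annotation(
        probe_id = probe_id, gene_symbol = gene_of_probe, platform = platform,
        ortholog_gene = ifelse(dropout[gene_of_probe], NA_character_,
                               gene_of_probe),
        sequence_id = probe_id)
      list(annot = annot, sequences = seqs, gene_of_probe = gene_of_probe,
           probe_rank = probe_rank, species = species, platform = platform)
    }
    src <- build_side("source", "human", "HU133A_synth")
    tgt <- build_side("target", "canine", "CAN2_synth")
    list(genes = genes, signature = sig, conserved = conserved, a = a,
         baseline = baseline, ancestor = ancestor, source = src, target = tgt)
  })
}

panel_expression <- function(cfg, side, latent, sample_ids, scramble = character()) {
  n <- length(latent)
  genes <- side_layout <- NULL
  layout <- side
  genes <- layout$pair$genes
  a <- layout$pair$a
  gene_signal <- outer(a[genes], latent) +
    matrix(rnorm(length(genes) * n, sd = cfg$noise_sd), length(genes), n) +
    layout$pair$baseline[genes]
  rownames(gene_signal) <- genes
  if (length(scramble)) {
    for (g in scramble)
      gene_signal[g, ] <- gene_signal[g, sample.int(n)]
  }
  probe_noise <- matrix(rnorm(length(layout$side$gene_of_probe) * n,
                              sd = 0.25 * cfg$noise_sd),
                        length(layout$side$gene_of_probe), n)
  values <- gene_signal[layout$side$gene_of_probe, , drop = FALSE] + probe_noise
  rownames(values) <- layout$side$annot$probe_id
  colnames(values) <- sample_ids
  expression_matrix(values, level = "probe",
                    platform = layout$side$platform,
                    species = layout$side$species)
}

#' Generate a synthetic cell-line panel
#'
#' Produces a probe-level expression matrix, its probe annotation (with
#' ortholog links and target-sequence ids), a drug-response table driven by a
#' latent per-sample sensitivity factor, and the ground truth used by tests.
#' Identical `(config, species_tag)` yields bit-identical output.
#'
#' @param config a [simulation_config()].
#' @param species_tag `"source"` (human-like reference platform) or
#'   `"target"` (canine-like platform).
#' @return list with elements `expression`, `annotation`, `response`,
#'   `sequences` (named character vector of probe target sequences) and
#'   `truth` (signature/conserved gene ids, latent sensitivity).
#' @export
gen_cell_line_panel <- function(config, species_tag = c("source", "target")) {
  validate_simulation_config(config)
  species_tag <- match.arg(species_tag)
  pair <- make_platform_pair(config)
  side <- pair[[species_tag]]
  seed <- config$seed * 13L + match(species_tag, c("source", "target"))
  with_rng(seed, {
    n <- config$n_ref_samples
    samples <- sprintf("%s_CL%02d", toupper(substr(side$species, 1, 2)), seq_len(n))
    latent <- rnorm(n)
    expr <- panel_expression(config, list(pair = pair, side = side),
                             latent, samples)
    resp <- do.call(rbind, lapply(config$drug_names, function(d)
      data.frame(sample_id = samples, drug = d,
                 log10_response = -2 * latent + rnorm(n, sd = config$noise_sd),
                 stringsAsFactors = FALSE)))
    response <- drug_response_table(resp$sample_id, resp$drug, resp$log10_response)
    truth <- list(signature_gene_ids = pair$signature,
                  conserved_gene_ids = pair$conserved,
                  latent_sensitivity = setNames(latent, samples),
                  responder = NULL)
    list(expression = expr, annotation = side$annot, response = response,
         sequences = side$sequences, truth = truth)
  })
}

#' Generate a synthetic tumor panel
#'
#' Tumor expression carries the planted sensitivity signal only for the
#' conserved subset of the signature; non-conserved signature genes are
#' scrambled by gene-wise permutation across samples, which destroys both
#' their co-expression with the rest of the signature and their association
#' with outcome. Disease-free intervals are exponential (Weibull shape 1)
#' with log-hazard `hazard_slope * latent sensitivity`; censoring is
#' Bernoulli(`censoring_rate`) with censored times observed uniformly before
#' the event.
#'
#' @param config a [simulation_config()].
#' @param truth truth list from [gen_cell_line_panel()] (defines signature and
#'   conserved gene sets); may be `NULL`, in which case it is re-derived from
#'   `config`.
#' @param species_tag platform on which the tumors are profiled
#'   (default `"target"`).
#' @param n_samples number of tumors (default `config$n_test_samples`; pass
#'   `config$n_coexp_samples` for the co-expression panel role).
#' @param hazard_slope log-hazard slope on latent sensitivity (default -1:
#'   more sensitive tumors recur later).
#' @param role label mixed into the RNG stream so the co-expression and test
#'   panels are independent draws.
#' @return list with `expression`, `annotation`, `clinical`, `sequences`,
#'   `truth` (with per-tumor latent sensitivity and responder flags).
#' @export
gen_tumor_panel <- function(config, truth = NULL,
                            species_tag = c("target", "source"),
                            n_samples = config$n_test_samples,
                            hazard_slope = -1,
                            role = c("test", "coexpression")) {
  validate_simulation_config(config)
  species_tag <- match.arg(species_tag)
  role <- match.arg(role)
  if (length(config$drug_names) == 0 || !any(nzchar(config$drug_names)))
    stop_config("invalid configuration field 'drug_names': empty drug list")
  pair <- make_platform_pair(config)
  side <- pair[[species_tag]]
  seed <- config$seed * 101L + 7L * match(role, c("test", "coexpression")) +
    match(species_tag, c("source", "target"))
  with_rng(seed, {
    samples <- sprintf("%s%02d", toupper(substr(role, 1, 2)), seq_len(n_samples))
    latent <- rnorm(n_samples)
    scramble <- setdiff(pair$signature, pair$conserved)
    expr <- panel_expression(config, list(pair = pair, side = side),
                             latent, samples, scramble = scramble)
    rate <- exp(hazard_slope * latent) / config$dfi_scale_days
    t_event <- rexp(n_samples, rate = rate)
    event <- rbinom(n_samples, 1L, prob = 1 - config$censoring_rate)
    dfi <- ifelse(event == 1L, t_event, runif(n_samples, 0, t_event))
    dfi <- pmax(dfi, 1)  # days, strictly positive
    arms <- config$drug_names
    if (length(arms) >= 2)
      arms <- c(arms, paste(arms[1:2], collapse = "+"))
    clin <- clinical_table(
      sample_id = samples, dfi_days = dfi, event = event,
      treatment = sample(arms, n_samples, replace = TRUE),
      proximal_humerus = rbinom(n_samples, 1, 0.3),
      alp_elevated = rbinom(n_samples, 1, 0.4),
      monocytes = round(exp(rnorm(n_samples, log(500), 0.4))),
      lymphocytes = round(exp(rnorm(n_samples, log(1500), 0.4))),
      body_weight_kg = round(rnorm(n_samples, 35, 8), 1),
      age_years = round(runif(n_samples, 2, 13), 1))
    tumor_truth <- list(signature_gene_ids = pair$signature,
                        conserved_gene_ids = pair$conserved,
                        latent_sensitivity = setNames(latent, samples),
                        responder = setNames(latent > 0, samples))
    if (!is.null(truth)) {
      tumor_truth$signature_gene_ids <- truth$signature_gene_ids
      tumor_truth$conserved_gene_ids <- truth$conserved_gene_ids
    }
    list(expression = expr, annotation = side$annot, clinical = clin,
         sequences = side$sequences, truth = tumor_truth)
  })
}

#' Write a synthetic panel to a directory of plain-text files
#'
#' Writes the tabular formats consumed by [load_dataset()]: `expression.tsv`,
#' `annotation.tsv`, `response.tsv` / `clinical.tsv` (if present),
#' `sequences.fasta` and `truth.json`.
#'
#' @param panel list as returned by [gen_cell_line_panel()] or
#'   [gen_tumor_panel()].
#' @param dir output directory (created if needed).
#' @return invisibly, the named character vector of file paths written.
#' @export
write_panel <- function(panel, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c()
  expr_df <- data.frame(row_id = rownames(panel$expression),
                        as_plain_matrix(panel$expression),
                        check.names = FALSE, stringsAsFactors = FALSE)
  p <- file.path(dir, "expression.tsv")
  write.table(expr_df, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["expression"] <- p
  p <- file.path(dir, "annotation.tsv")
  write.table(panel$annotation, p, sep = "\t", quote = FALSE, row.names = FALSE)
  paths["annotation"] <- p
  if (!is.null(panel$response)) {
    p <- file.path(dir, "response.tsv")
    write.table(panel$response, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths["response"] <- p
  }
  if (!is.null(panel$clinical)) {
    p <- file.path(dir, "clinical.tsv")
    write.table(panel$clinical, p, sep = "\t", quote = FALSE, row.names = FALSE)
    paths["clinical"] <- p
  }
  if (!is.null(panel$sequences)) {
    p <- file.path(dir, "sequences.fasta")
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(panel$sequences), p)
    paths["fasta"] <- p
  }
  if (!is.null(panel$truth)) {
    p <- file.path(dir, "truth.json")
    jsonlite::write_json(panel$truth, p, auto_unbox = FALSE, digits = NA)
    paths["truth"] <- p
  }
  invisible(paths)
}
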