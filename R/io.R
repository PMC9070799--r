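# Readers and writers for the package's external formats (FASTA via
# Biostrings, strict TSV dialect) and the end-to-end pipeline driver.
# TSV dialect: tab separators, header row, '.' decimal, UTF-8, no quoting,
# NA as empty field. Coordinates in all outputs are 0-based half-open.

#' Read a FASTA file into a named character vector
#'
#' @param path FASTA file path.
#' @param mode `"protein"` or `"nucleotide"`.
#' @return Named character vector of sequences in file order.
#' @export
read_fasta <- function(path, mode = c("protein", "nucleotide")) {
  mode <- match.arg(mode)
  set <- if (mode == "protein") Biostrings::readAAStringSet(path)
         else Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids))
    stop("duplicate FASTA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- as.character(set)
  if (any(nchar(seqs) == 0L))
    stop("empty FASTA record(s): ", paste(ids[nchar(seqs) == 0L], collapse = ", "))
  stats::setNames(seqs, ids)
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @param mode `"protein"` or `"nucleotide"`.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, mode = c("protein", "nucleotide")) {
  mode <- match.arg(mode)
  set <- if (mode == "protein") Biostrings::AAStringSet(seqs)
         else Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(set, path, width = 70L)
  invisible(path)
}

#' Write a data frame as strict TSV
#'
#' Numeric columns are serialized with 17 significant digits so values
#' round-trip bit-identically through [read_tsv_strict()].
#'
#' @param df Data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tsv_strict <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) {
      v <- sprintf("%.17g", out[[j]])
      v[is.na(out[[j]])] <- ""
      out[[j]] <- v
    }
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, na = "",
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a strict TSV file
#'
#' @param path File path.
#' @return Data frame; empty fields become `NA`.
#' @export
read_tsv_strict <- function(path) {
  utils::read.delim(path, sep = "\t", quote = "", na.strings = "",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    fileEncoding = "UTF-8")
}

#' Read a genes-by-tissues abundance matrix from TSV
#'
#' Expects an `id` column followed by one numeric column per tissue.
#'
#' @param path File path.
#' @return Numeric matrix with gene ids as rownames.
#' @export
read_abundance <- function(path) {
  df <- read_tsv_strict(path)
  stopifnot("id" %in% names(df))
  m <- as.matrix(df[, setdiff(names(df), "id"), drop = FALSE])
  mode(m) <- "double"
  rownames(m) <- df$id
  if (any(m < 0, na.rm = TRUE)) stop("negative abundance in ", path)
  m
}

#' Run the full LCR-abundance analysis pipeline
#'
#' Chains the stages in dependency order: LCR detection, abundance
#' integration, codon economy and TWnTE scoring, quartile-shift
#' permutation tests (baseline plus requested variants), and the logistic
#' regression. Reruns with the same inputs and seed are reproducible.
#'
#' @param proteins Named character vector of protein sequences.
#' @param cds Named character vector of in-frame CDS sequences (same ids).
#' @param tab,pab Genes-by-tissues abundance matrices (rownames = ids).
#' @param trna_counts Named anticodon copy-number vector.
#' @param kdeg Optional named per-protein degradation coefficients.
#' @param lcr_parameters An [lcr_params()] object.
#' @param translation_parameters A [translation_params()] object, or
#'   `NULL` to fit (alpha, beta) against `rates`.
#' @param rates Optional named measured translation rates (needed when
#'   `translation_parameters` is `NULL`).
#' @param rules A [wobble_rules()] object, or `NULL` to fit the wobble
#'   constraints to the transcriptome first.
#' @param gene Optional named map id -> gene for the isoform-dedup
#'   variant.
#' @param variants Permutation variants to run besides `"baseline"`.
#' @param n_perm,seed Permutation settings.
#' @param regressors Regressor columns for the logistic fit; `"kdeg"` and
#'   `"twnte"` are dropped automatically when unavailable.
#' @param out_dir Optional directory; when given, every stage's table is
#'   written there as TSV together with a `run_log.tsv` of all parameters.
#' @return List with `annotations`, `summaries` (merged per-protein
#'   table), `economy`, `scores`, `translation_fit` (when fitted),
#'   `wobble_fit` (when fitted), `permutation` (tidy results over
#'   variants), `ranksum` (Mann-Whitney check per abundance type),
#'   `regression`, and `log` (parameter record).
#' @export
run_pipeline <- function(proteins, cds, tab, pab, trna_counts,
                         kdeg = NULL,
                         lcr_parameters = lcr_params(),
                         translation_parameters = translation_params(),
                         rates = NULL, rules = wobble_rules(),
                         gene = NULL,
                         variants = "baseline", n_perm = 10000L, seed = 1L,
                         regressors = c("pab", "tab", "kdeg", "twnte", "length"),
                         out_dir = NULL) {
  ids <- names(proteins)
  if (is.null(ids) || !setequal(ids, names(cds)))
    stop("stage detect: protein and CDS ids must match")
  missing_tab <- setdiff(ids, rownames(tab))
  missing_pab <- setdiff(ids, rownames(pab))
  if (length(missing_tab) || length(missing_pab))
    stop("stage integrate: ids missing from abundance tables: ",
         paste(utils::head(c(missing_tab, missing_pab), 5L), collapse = ", "))

  ann <- annotate_lcrs(proteins, lcr_parameters)
  tab_sum <- integrate_abundance(tab[ids, , drop = FALSE])
  pab_sum <- integrate_abundance(pab[ids, , drop = FALSE])

  wobble_fit <- NULL
  if (is.null(rules)) {
    wobble_fit <- fit_wobble(trna_counts, cds[ids],
                             tab_sum$integrated_abundance[match(ids, tab_sum$id)])
    rules <- wobble_fit$rules
  }
  tab_w <- tab_sum$integrated_abundance[match(ids, tab_sum$id)]
  tab_w[is.na(tab_w)] <- 0
  economy <- codon_economy(trna_counts, cds[ids], tab_w, rules)

  translation_fit <- NULL
  if (is.null(translation_parameters)) {
    if (is.null(rates))
      stop("stage twnte: measured rates required to fit translation parameters")
    translation_fit <- fit_translation_params(cds[ids], economy, rates)
    translation_parameters <- translation_fit$params
  }
  scores <- score_transcripts(cds[ids], economy, translation_parameters)

  summaries <- data.frame(
    id = ids,
    gene = if (is.null(gene)) ids else unname(gene[ids]),
    length = nchar(proteins),
    lcr_status = ann$lcr_status,
    has_homopolymer = ann$has_homopolymer,
    primary_aa = ann$primary_aa,
    tab = tab_sum$integrated_abundance[match(ids, tab_sum$id)],
    pab = pab_sum$integrated_abundance[match(ids, pab_sum$id)],
    tau = tab_sum$tau[match(ids, tab_sum$id)],
    twnte = scores$twnte[match(ids, scores$id)],
    nte = scores$nte[match(ids, scores$id)],
    kdeg = if (is.null(kdeg)) NA_real_ else unname(kdeg[ids]),
    row.names = NULL)

  variants <- unique(c("baseline", variants))
  perm <- do.call(rbind, lapply(variants, function(v)
    run_variants(summaries, v, n_perm = n_perm, seed = seed)))

  both <- is.finite(summaries$tab) & summaries$tab > 0 &
    is.finite(summaries$pab) & summaries$pab > 0
  ranksum <- data.frame(
    abundance_type = c("tab", "pab"),
    p = c(ranksum_check(summaries$tab[both], summaries$lcr_status[both]),
          ranksum_check(summaries$pab[both], summaries$lcr_status[both])))

  regs <- regressors
  if (is.null(kdeg)) regs <- setdiff(regs, "kdeg")
  regression <- fit_lcr_logistic(summaries, regression_spec(regs))

  log <- data.frame(
    parameter = c("window", "k1", "k2", "n_perm", "seed", "alpha", "beta",
                  "s_AA", "s_UG", "s_GU", "s_AC", "quantile_type",
                  "regressors"),
    value = c(lcr_parameters$window, lcr_parameters$k1, lcr_parameters$k2,
              n_perm, seed, translation_parameters$alpha,
              translation_parameters$beta, rules$s_AA, rules$s_UG,
              rules$s_GU, rules$s_AC, 7, paste(regs, collapse = ",")))

  result <- list(annotations = ann, summaries = summaries, economy = economy,
                 scores = scores, translation_fit = translation_fit,
                 wobble_fit = wobble_fit, permutation = perm,
                 ranksum = ranksum, regression = regression, log = log)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_tsv_strict(ann, file.path(out_dir, "lcr_annotations.tsv"))
    write_tsv_strict(summaries, file.path(out_dir, "gene_summaries.tsv"))
    write_tsv_strict(as.data.frame(economy), file.path(out_dir, "codon_economy.tsv"))
    write_tsv_strict(scores, file.path(out_dir, "translation_scores.tsv"))
    write_tsv_strict(perm, file.path(out_dir, "permutation_results.tsv"))
    write_tsv_strict(regression$coefficients,
                     file.path(out_dir, "regression_coefficients.tsv"))
    write_tsv_strict(log, file.path(out_dir, "run_log.tsv"))
  }
  result
}
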