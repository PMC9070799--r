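# Synthetic proteome/transcriptome generator with known ground truth:
# matched protein/CDS pairs with controllable LCR content, log-normal
# per-tissue abundance with configurable LCR effects, a tRNA pool, protein
# degradation coefficients, translation rates generated from the TWnTE
# model plus noise, and post-mortem ischemia decay samples.

#' Configuration of a synthetic dataset
#'
#' All randomness downstream of a config flows from one RNG stream seeded
#' with `seed`, so identical configs give bit-identical datasets.
#'
#' @param n_genes Number of genes (>= 0).
#' @param n_tissues Number of tissues (default 13, a typical
#'   multi-tissue expression panel).
#' @param lcr_fraction Proportion of genes given a low-complexity region.
#' @param lcr_effect_tab,lcr_effect_pab log2 fold-effect of LCR status on
#'   transcript / protein abundance.
#' @param abundance_log_sd SD of the per-gene baseline on the log2 scale.
#' @param dropout_rate Proportion of gene-by-tissue cells set to zero.
#' @param protein_length_range Integer pair: protein lengths (residues).
#' @param lcr_length_range Integer pair: inserted LCR segment lengths;
#'   the minimum must be at least 15 so every injected segment contains a
#'   full detector window.
#' @param homopolymer_fraction Proportion of injected LCRs that are
#'   single-residue tracts (the rest are 2-3 residue biased repeats).
#' @param n_anticodons Number of distinct tRNA species (<= 61).
#' @param trna_copy_range Integer pair: genomic copy numbers per species.
#'   The default band is deliberately narrow: in the mammalian regime the
#'   translation-efficiency contrast between genes comes mainly from
#'   biased codon usage concentrating demand, not from extreme
#'   within-family tRNA abundance differences.
#' @param codon_usage_bias Maximum per-gene codon-adaptation intensity:
#'   a genome-wide preferred synonymous codon is drawn per amino acid,
#'   and each gene uses its preferred codons with a probability drawn
#'   from a U-shaped (Beta(0.5, 0.5)) distribution scaled to this value,
#'   so genes range from unbiased to strongly adapted — the structure
#'   that supply/demand translation-efficiency scales exploit. 0 gives
#'   uniform synonymous choice everywhere.
#' @param true_alpha,true_beta Perturbability and resupply used to
#'   generate translation rates from the TWnTE model.
#' @param translation_noise_sd SD of multiplicative log-normal noise on
#'   generated translation rates (natural-log scale).
#' @param ischemia_decay_range Pair of nonnegative per-minute decay
#'   constants for post-mortem transcript decay.
#' @param isoform_fraction Proportion of genes duplicated as a second
#'   isoform (exercises the isoform-dedup variant).
#' @param n_ischemia_samples Donors sampled per tissue.
#' @param ischemia_noise_sd SD of multiplicative log-normal measurement
#'   noise on ischemia samples.
#' @param seed Integer seed.
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(n_genes = 1000L, n_tissues = 13L,
                              lcr_fraction = 0.25,
                              lcr_effect_tab = 0, lcr_effect_pab = 0,
                              abundance_log_sd = 1.5, dropout_rate = 0.5,
                              protein_length_range = c(80L, 1000L),
                              lcr_length_range = c(15L, 45L),
                              homopolymer_fraction = 0.125,
                              n_anticodons = 48L,
                              trna_copy_range = c(15L, 25L),
                              codon_usage_bias = 0.95,
                              true_alpha = 0.0578, true_beta = 0.00064,
                              translation_noise_sd = 0.1,
                              ischemia_decay_range = c(0, 0.005),
                              isoform_fraction = 0,
                              n_ischemia_samples = 8L,
                              ischemia_noise_sd = 0.05,
                              seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_tissues = as.integer(n_tissues),
              lcr_fraction = lcr_fraction, lcr_effect_tab = lcr_effect_tab,
              lcr_effect_pab = lcr_effect_pab,
              abundance_log_sd = abundance_log_sd, dropout_rate = dropout_rate,
              protein_length_range = as.integer(protein_length_range),
              lcr_length_range = as.integer(lcr_length_range),
              homopolymer_fraction = homopolymer_fraction,
              n_anticodons = as.integer(n_anticodons),
              trna_copy_range = as.integer(trna_copy_range),
              codon_usage_bias = codon_usage_bias,
              true_alpha = true_alpha, true_beta = true_beta,
              translation_noise_sd = translation_noise_sd,
              ischemia_decay_range = ischemia_decay_range,
              isoform_fraction = isoform_fraction,
              n_ischemia_samples = as.integer(n_ischemia_samples),
              ischemia_noise_sd = ischemia_noise_sd,
              seed = as.integer(seed))
  props <- c(cfg$lcr_fraction, cfg$dropout_rate, cfg$homopolymer_fraction,
             cfg$isoform_fraction, cfg$codon_usage_bias,
             cfg$true_alpha, cfg$true_beta)
  stopifnot(cfg$n_genes >= 0L, cfg$n_tissues >= 1L,
            all(props >= 0), all(props <= 1),
            cfg$abundance_log_sd > 0, cfg$translation_noise_sd >= 0,
            cfg$ischemia_noise_sd >= 0,
            length(cfg$protein_length_range) == 2L,
            cfg$protein_length_range[1] >= 20L,
            diff(cfg$protein_length_range) >= 0L,
            length(cfg$lcr_length_range) == 2L,
            diff(cfg$lcr_length_range) >= 0L,
            length(cfg$ischemia_decay_range) == 2L,
            all(cfg$ischemia_decay_range >= 0),
            diff(cfg$ischemia_decay_range) >= 0,
            cfg$n_anticodons >= 1L, cfg$n_anticodons <= 61L,
            length(cfg$trna_copy_range) == 2L,
            cfg$trna_copy_range[1] >= 1L, diff(cfg$trna_copy_range) >= 0L,
            cfg$n_ischemia_samples >= 1L)
  if (cfg$lcr_length_range[1] < 15L)
    stop("lcr_length_range minimum must be >= 15 so injected segments span a detector window")
  structure(cfg, class = "simulation_config")
}

#' @export
print.simulation_config <- function(x, ...) {
  cat(sprintf(paste0(
    "Synthetic dataset config: %d genes x %d tissues, LCR fraction %.2f\n",
    "  effects (log2): TAb %+g, PAb %+g; abundance sd %g; dropout %.2f\n",
    "  translation truth: alpha %g, beta %g, noise sd %g; seed %d\n"),
    x$n_genes, x$n_tissues, x$lcr_fraction, x$lcr_effect_tab,
    x$lcr_effect_pab, x$abundance_log_sd, x$dropout_rate,
    x$true_alpha, x$true_beta, x$translation_noise_sd, x$seed))
  invisible(x)
}

# uniform-alphabet background sequence
.random_protein <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE),
                                     collapse = "")

# low-entropy segment: homopolymer or a 2-3 residue biased repeat; any
# 15-mer inside has entropy <= log2(3) < 1.9 bits
.random_lcr_segment <- function(len, homopolymer) {
  if (homopolymer) {
    strrep(sample(AA_ALPHABET, 1L), len)
  } else {
    k <- sample(2:3, 1L)
    unit <- sample(AA_ALPHABET, k)
    substr(strrep(paste(unit, collapse = ""), ceiling(len / k) + 1L), 1L, len)
  }
}

# rejection-sample an LCR-free background of length n: every window must
# sit at or above the trigger entropy
.random_lcr_free <- function(n, k1 = 1.9, window = 15L, max_attempts = 100L) {
  for (i in seq_len(max_attempts)) {
    s <- .random_protein(n)
    h <- window_entropy(s, window)
    if (length(h) == 0L || min(h) >= k1) return(s)
  }
  stop("could not sample an LCR-free sequence of length ", n, " in ",
       max_attempts, " attempts; config is infeasible")
}

# synonymous-codon lookup tables for fast reverse translation
.codon_tables <- function() {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), gc)
  by_aa <- by_aa[names(by_aa) %in% AA_ALPHABET]
  k <- lengths(by_aa)
  list(flat = unlist(by_aa, use.names = FALSE), k = k,
       offset = stats::setNames(cumsum(c(0, k[-length(k)])), names(k)))
}

# reverse-translate one protein under genome-wide codon adaptation: `pref`
# names one preferred synonymous codon per amino acid (shared across the
# genome, as real codon bias is), used with probability `bias` (the gene's
# adaptation intensity); remaining choices are uniform over synonymous
# codons. A random stop codon is appended.
.reverse_translate <- function(protein, tabs, pref, bias = 0) {
  res <- strsplit(protein, "", fixed = TRUE)[[1]]
  k <- tabs$k[res]
  pick <- ceiling(stats::runif(length(res)) * k)
  if (bias > 0) {
    use <- stats::runif(length(res)) < bias
    pick[use] <- pref[res[use]]
  }
  codons <- tabs$flat[tabs$offset[res] + pick]
  paste0(paste(codons, collapse = ""),
         sample(c("TAA", "TAG", "TGA"), 1L))
}

.runif_int <- function(n, range) {
  if (range[1] == range[2]) rep(range[1], n)
  else sample(seq(range[1], range[2]), n, replace = TRUE)
}

#' Generate a complete synthetic dataset
#'
#' Produces matched protein/CDS pairs (LCR-positive proteins receive an
#' inserted low-entropy segment; LCR-negative proteins are
#' rejection-sampled to contain no window below the trigger entropy, so
#' the injected labels and the detector agree by construction), per-tissue
#' log-normal transcript and protein abundance with the configured LCR
#' effects and Bernoulli dropout, a tRNA pool, degradation coefficients,
#' translation rates generated from the TWnTE model under the true
#' (alpha, beta) plus log-normal noise, and per-tissue ischemia decay
#' samples. Intrinsic-disorder labels are emulated as a copy of the LCR
#' labels.
#'
#' @param config A [simulation_config()].
#' @return An object of class `synthetic_dataset`: list with `proteins`
#'   (data frame: `id`, `gene`, `protein_seq`, `cds_seq`, `length`,
#'   `lcr_true`, `homopolymer_true`, `disorder_status`), `tab`, `pab`
#'   (matrices), `trna_counts`, `kdeg`, `translation_rates` (named
#'   vectors), `ischemia_samples` (long data frame), and `truth` (the
#'   injected parameters: LCR-positive ids, effects, true alpha/beta,
#'   per-gene decay constants, and the config).
#' @export
simulate_dataset <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  .with_seed(config$seed, {
    n <- config$n_genes
    base_ids <- if (n > 0) sprintf("G%05d", seq_len(n)) else character(0)
    n_lcr <- round(config$lcr_fraction * n)
    lcr_idx <- if (n_lcr > 0) sample.int(n, n_lcr) else integer(0)
    lcr_true <- seq_len(n) %in% lcr_idx
    homopolymer_true <- lcr_true &
      (stats::runif(max(n, 0)) < config$homopolymer_fraction)

    lengths0 <- .runif_int(n, config$protein_length_range)
    tabs <- .codon_tables()
    # genome-wide preferred codon per amino acid; per-gene adaptation
    # intensity is U-shaped over 0 .. codon_usage_bias (most genes weakly
    # biased or strongly adapted, as optimal-codon fractions are in vivo)
    pref <- stats::setNames(ceiling(stats::runif(length(tabs$k)) * tabs$k),
                            names(tabs$k))
    bias_g <- config$codon_usage_bias * stats::rbeta(n, 0.5, 0.5)
    prot <- character(n); cds <- character(n)
    for (i in seq_len(n)) {
      if (lcr_true[i]) {
        seg_len <- .runif_int(1L, config$lcr_length_range)
        seg <- .random_lcr_segment(seg_len, homopolymer_true[i])
        back_len <- max(lengths0[i] - seg_len, 20L)
        back <- .random_protein(back_len)
        at <- sample.int(back_len - 1L, 1L)   # insert strictly inside
        prot[i] <- paste0(substr(back, 1L, at), seg,
                          substr(back, at + 1L, back_len))
      } else {
        prot[i] <- .random_lcr_free(lengths0[i])
      }
      cds[i] <- .reverse_translate(prot[i], tabs, pref, bias_g[i])
    }

    # optional isoform duplicates (same gene, fresh abundance noise)
    n_iso <- round(config$isoform_fraction * n)
    iso_of <- if (n_iso > 0) sort(sample.int(n, n_iso)) else integer(0)
    ids <- c(base_ids, if (n_iso) paste0(base_ids[iso_of], ".2"))
    gene <- c(base_ids, base_ids[iso_of])
    src <- c(seq_len(n), iso_of)      # generating gene per record
    n_rec <- length(ids)

    tissues <- sprintf("tissue%02d", seq_len(config$n_tissues))
    make_abundance <- function(effect) {
      base <- stats::rnorm(n, mean = 5, sd = config$abundance_log_sd) +
        effect * lcr_true
      m <- matrix(2^(base[src] +
                       stats::rnorm(n_rec * config$n_tissues, sd = 1)),
                  n_rec, config$n_tissues, dimnames = list(ids, tissues))
      m[matrix(stats::runif(length(m)) < config$dropout_rate,
               n_rec, config$n_tissues)] <- 0
      m
    }
    tab <- make_abundance(config$lcr_effect_tab)
    pab <- make_abundance(config$lcr_effect_pab)

    # tRNA pool: distinct Watson-Crick anticodons of sense codons
    sense <- .sense_codons()
    wc_anticodons <- vapply(sense, function(cd)
      as.character(Biostrings::RNAString(
        Biostrings::reverseComplement(Biostrings::DNAString(cd)))), "")
    pool_ac <- sample(unname(wc_anticodons), config$n_anticodons)
    trna_counts <- stats::setNames(
      as.numeric(.runif_int(config$n_anticodons, config$trna_copy_range)),
      pool_ac)

    kdeg <- stats::setNames(
      stats::rlnorm(n_rec, meanlog = log(0.0242), sdlog = 0.5), ids)

    translation_rates <- stats::setNames(rep(NA_real_, n_rec), ids)
    if (n_rec > 0) {
      cds_all <- stats::setNames(cds[src], ids)
      tab_int <- integrate_abundance(tab)
      w <- tab_int$integrated_abundance[match(ids, tab_int$id)]
      w[is.na(w)] <- 0
      economy <- codon_economy(trna_counts, cds_all, w, wobble_rules())
      tw <- score_transcripts(
        cds_all, economy,
        translation_params(config$true_alpha, config$true_beta))$twnte
      translation_rates[] <- tw *
        stats::rlnorm(n_rec, 0, config$translation_noise_sd)
    }

    decay <- stats::setNames(
      stats::runif(n_rec, config$ischemia_decay_range[1],
                   config$ischemia_decay_range[2]), ids)
    ischemia_samples <- NULL
    if (n_rec > 0) {
      times <- matrix(stats::runif(config$n_tissues *
                                     config$n_ischemia_samples, 0, 720),
                      config$n_tissues, config$n_ischemia_samples)
      grid <- expand.grid(gene = ids, tissue = seq_len(config$n_tissues),
                          s = seq_len(config$n_ischemia_samples),
                          stringsAsFactors = FALSE)
      t_min <- times[cbind(grid$tissue, grid$s)]
      true_ab <- tab[cbind(match(grid$gene, ids), grid$tissue)]
      noise <- stats::rlnorm(nrow(grid), 0, config$ischemia_noise_sd)
      ischemia_samples <- data.frame(
        gene = grid$gene, tissue = tissues[grid$tissue],
        time_min = t_min,
        abundance = true_ab * exp(-decay[grid$gene] * t_min) * noise)
    } else {
      ischemia_samples <- data.frame(gene = character(0),
                                     tissue = character(0),
                                     time_min = numeric(0),
                                     abundance = numeric(0))
    }

    proteins <- data.frame(id = ids, gene = gene,
                           protein_seq = prot[src], cds_seq = cds[src],
                           length = nchar(prot[src]),
                           lcr_true = lcr_true[src],
                           homopolymer_true = homopolymer_true[src],
                           disorder_status = lcr_true[src],
                           row.names = NULL)
    structure(list(proteins = proteins, tab = tab, pab = pab,
                   trna_counts = trna_counts, kdeg = kdeg,
                   translation_rates = translation_rates,
                   ischemia_samples = ischemia_samples,
                   truth = list(lcr_ids = ids[proteins$lcr_true],
                                lcr_effect_tab = config$lcr_effect_tab,
                                lcr_effect_pab = config$lcr_effect_pab,
                                true_alpha = config$true_alpha,
                                true_beta = config$true_beta,
                                decay_per_min = decay,
                                config = config)),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf(paste0(
    "Synthetic dataset: %d records (%d LCR+), %d tissues, %d tRNA species\n"),
    nrow(x$proteins), sum(x$proteins$lcr_true), ncol(x$tab),
    length(x$trna_counts)))
  invisible(x)
}

#' Write a synthetic dataset to a directory
#'
#' Emits protein and CDS FASTA, TSV tables for abundance, tRNA counts,
#' degradation coefficients, translation rates, ischemia samples and the
#' ground truth, and a data dictionary describing every column. All
#' files are readable back with [read_dataset()] (numeric values
#' round-trip bit-identically).
#'
#' @param ds A `synthetic_dataset`.
#' @param dir Output directory (created if needed).
#' @return Manifest data frame with columns `file` and `n_rows` (records
#'   for FASTA, data rows for TSV), invisibly returned by value.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir)
  p <- function(f) file.path(dir, f)
  write_fasta(stats::setNames(ds$proteins$protein_seq, ds$proteins$id),
              p("proteins.fasta"), "protein")
  write_fasta(stats::setNames(ds$proteins$cds_seq, ds$proteins$id),
              p("cds.fasta"), "nucleotide")
  abundance_df <- function(m) {
    ids <- rownames(m)                # NULL for a zero-row matrix
    cbind(data.frame(id = if (is.null(ids)) character(0) else ids),
          as.data.frame(m))
  }
  write_tsv_strict(abundance_df(ds$tab), p("tab.tsv"))
  write_tsv_strict(abundance_df(ds$pab), p("pab.tsv"))
  write_tsv_strict(data.frame(anticodon = names(ds$trna_counts),
                              copies = as.numeric(ds$trna_counts)),
                   p("trna_counts.tsv"))
  write_tsv_strict(data.frame(id = names(ds$kdeg),
                              kdeg_per_hour = as.numeric(ds$kdeg)),
                   p("kdeg.tsv"))
  write_tsv_strict(data.frame(id = names(ds$translation_rates),
                              rate = as.numeric(ds$translation_rates)),
                   p("translation_rates.tsv"))
  write_tsv_strict(ds$ischemia_samples, p("ischemia_samples.tsv"))
  truth_df <- data.frame(id = ds$proteins$id, gene = ds$proteins$gene,
                         lcr_true = ds$proteins$lcr_true,
                         homopolymer_true = ds$proteins$homopolymer_true,
                         disorder_status = ds$proteins$disorder_status,
                         decay_per_min =
                           as.numeric(ds$truth$decay_per_min[ds$proteins$id]))
  write_tsv_strict(truth_df, p("truth.tsv"))
  dict <- data.frame(
    file = c("proteins.fasta", "cds.fasta", "tab.tsv", "pab.tsv",
             "trna_counts.tsv", "kdeg.tsv", "translation_rates.tsv",
             "ischemia_samples.tsv", "truth.tsv"),
    description = c(
      "Protein sequences; record id in header, one record per isoform",
      "In-frame coding sequences incl. stop; translates to proteins.fasta",
      "Transcript abundance, id column then one column per tissue (linear units)",
      "Protein abundance, id column then one column per tissue (linear units)",
      "Genomic tRNA copy number per RNA anticodon (5'->3')",
      "First-order protein degradation coefficient, per hour",
      "Measured translation rate per record (arbitrary units)",
      "Per-sample decayed abundance: gene, tissue, ischemia time (min), abundance",
      "Injected ground truth: LCR status, homopolymer status, disorder label, decay constant"))
  write_tsv_strict(dict, p("data_dictionary.tsv"))
  files <- c("proteins.fasta", "cds.fasta", "tab.tsv", "pab.tsv",
             "trna_counts.tsv", "kdeg.tsv", "translation_rates.tsv",
             "ischemia_samples.tsv", "truth.tsv", "data_dictionary.tsv")
  rows <- c(nrow(ds$proteins), nrow(ds$proteins), nrow(ds$tab), nrow(ds$pab),
            length(ds$trna_counts), length(ds$kdeg),
            length(ds$translation_rates), nrow(ds$ischemia_samples),
            nrow(ds$proteins), nrow(dict))
  invisible(data.frame(file = files, n_rows = rows))
}

#' Read a synthetic dataset back from a directory
#'
#' Counterpart of [write_dataset()]; ground-truth parameters that are not
#' serialized (effect sizes, true alpha/beta, the config) are restored
#' only if present, so a written-then-read dataset compares equal on all
#' data components.
#'
#' @param dir Directory written by [write_dataset()].
#' @return A `synthetic_dataset`.
#' @export
read_dataset <- function(dir) {
  p <- function(f) file.path(dir, f)
  prot <- read_fasta(p("proteins.fasta"), "protein")
  cds <- read_fasta(p("cds.fasta"), "nucleotide")
  truth_df <- read_tsv_strict(p("truth.tsv"))
  tab <- read_abundance(p("tab.tsv"))
  pab <- read_abundance(p("pab.tsv"))
  trna <- read_tsv_strict(p("trna_counts.tsv"))
  kdeg_df <- read_tsv_strict(p("kdeg.tsv"))
  rates_df <- read_tsv_strict(p("translation_rates.tsv"))
  isch <- read_tsv_strict(p("ischemia_samples.tsv"))
  ids <- truth_df$id
  proteins <- data.frame(id = ids, gene = truth_df$gene,
                         protein_seq = unname(prot[ids]),
                         cds_seq = unname(cds[ids]),
                         length = nchar(unname(prot[ids])),
                         lcr_true = truth_df$lcr_true,
                         homopolymer_true = truth_df$homopolymer_true,
                         disorder_status = truth_df$disorder_status,
                         row.names = NULL)
  structure(list(proteins = proteins, tab = tab, pab = pab,
                 trna_counts = stats::setNames(as.numeric(trna$copies),
                                               trna$anticodon),
                 kdeg = stats::setNames(as.numeric(kdeg_df$kdeg_per_hour),
                                        kdeg_df$id),
                 translation_rates = stats::setNames(as.numeric(rates_df$rate),
                                                     rates_df$id),
                 ischemia_samples = isch,
                 truth = list(lcr_ids = ids[truth_df$lcr_true],
                              decay_per_min =
                                stats::setNames(truth_df$decay_per_min, ids))),
            class = "synthetic_dataset")
}
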