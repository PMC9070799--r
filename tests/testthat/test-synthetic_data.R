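test_that("injected LCR labels round-trip exactly through the detector", {
  for (seed in c(1, 7, 19)) {
    ds <- simulate_dataset(simulation_config(n_genes = 120, seed = seed))
    ann <- annotate_lcrs(stats::setNames(ds$proteins$protein_seq,
                                         ds$proteins$id))
    expect_identical(ann$lcr_status, ds$proteins$lcr_true)
    expect_identical(sort(ds$truth$lcr_ids),
                     sort(ann$id[ann$lcr_status]))
  }
  expect_identical(sum(simulate_dataset(simulation_config(
    n_genes = 50, lcr_fraction = 0, seed = 2))$proteins$lcr_true), 0L)
})

test_that("the injected LCR fraction is honoured exactly", {
  ds <- simulate_dataset(simulation_config(n_genes = 200, lcr_fraction = 0.25,
                                           seed = 3))
  expect_identical(sum(ds$proteins$lcr_true), 50L)
})

test_that("identical config and seed give bit-identical datasets", {
  cfg <- simulation_config(n_genes = 40, seed = 13, isoform_fraction = 0.2)
  a <- simulate_dataset(cfg)
  b <- simulate_dataset(cfg)
  expect_identical(a$proteins, b$proteins)
  expect_identical(a$tab, b$tab)
  expect_identical(a$translation_rates, b$translation_rates)
  expect_identical(a$ischemia_samples, b$ischemia_samples)
  # a different seed changes the data
  c <- simulate_dataset(simulation_config(n_genes = 40, seed = 14,
                                          isoform_fraction = 0.2))
  expect_false(identical(a$tab, c$tab))
})

test_that("every CDS is in frame and translates back to its protein", {
  ds <- simulate_dataset(simulation_config(n_genes = 30, seed = 4))
  expect_true(all(nchar(ds$proteins$cds_seq) ==
                    3 * nchar(ds$proteins$protein_seq) + 3))
  back <- as.character(Biostrings::translate(
    Biostrings::DNAStringSet(ds$proteins$cds_seq), no.init.codon = TRUE))
  expect_identical(substr(back, 1, nchar(back) - 1), ds$proteins$protein_seq)
  expect_true(all(substr(back, nchar(back), nchar(back)) == "*"))
})

test_that("every record id appears in all abundance and rate components", {
  ds <- simulate_dataset(simulation_config(n_genes = 25, seed = 5,
                                           isoform_fraction = 0.2))
  ids <- ds$proteins$id
  expect_identical(length(ids), 30L)   # 25 genes + 5 isoforms
  expect_true(all(ids %in% rownames(ds$tab)))
  expect_true(all(ids %in% rownames(ds$pab)))
  expect_true(all(ids %in% names(ds$kdeg)))
  expect_true(all(ids %in% names(ds$translation_rates)))
  # isoform records share their gene with the parent
  iso <- grepl("\\.2$", ids)
  expect_identical(sum(dedup_isoforms(ids, ds$proteins$gene, rep(1, 30))), 25L)
})

test_that("abundance effects move the LCR+ group in the configured direction", {
  ds <- simulate_dataset(simulation_config(
    n_genes = 600, seed = 6, lcr_effect_tab = 1, lcr_effect_pab = -1))
  tabi <- integrate_abundance(ds$tab)
  pabi <- integrate_abundance(ds$pab)
  ok <- tabi$expressed & pabi$expressed
  lab <- ds$proteins$lcr_true[ok]
  sh_tab <- quartile_shift(tabi$integrated_abundance[ok], lab)
  sh_pab <- quartile_shift(pabi$integrated_abundance[ok], lab)
  expect_true(all(sh_tab > 0))
  expect_true(all(sh_pab < 0))
})

test_that("dropout produces the configured sparsity", {
  ds <- simulate_dataset(simulation_config(n_genes = 300, seed = 8,
                                           dropout_rate = 0.5))
  expect_equal(mean(ds$tab == 0), 0.5, tolerance = 0.03)
  ds0 <- simulate_dataset(simulation_config(n_genes = 50, seed = 8,
                                            dropout_rate = 0))
  expect_identical(sum(ds0$tab == 0), 0L)
})

test_that("translation rates follow the TWnTE truth as noise vanishes", {
  cfg <- simulation_config(n_genes = 80, seed = 9, translation_noise_sd = 1e-12)
  ds <- simulate_dataset(cfg)
  cds <- stats::setNames(ds$proteins$cds_seq, ds$proteins$id)
  w <- integrate_abundance(ds$tab)$integrated_abundance
  w[is.na(w)] <- 0
  ec <- codon_economy(ds$trna_counts, cds, w)
  tw <- score_transcripts(cds, ec,
                          translation_params(cfg$true_alpha, cfg$true_beta))
  expect_gt(cor(log(tw$twnte), log(ds$translation_rates)), 1 - 1e-9)
})

test_that("ischemia samples decay from the per-tissue truth", {
  ds <- simulate_dataset(simulation_config(n_genes = 20, seed = 10,
                                           ischemia_noise_sd = 0,
                                           dropout_rate = 0,
                                           ischemia_decay_range = c(0.002, 0.01)))
  s <- ds$ischemia_samples
  g <- s[s$gene == ds$proteins$id[1] & s$tissue == "tissue01", ]
  k <- ds$truth$decay_per_min[[ds$proteins$id[1]]]
  expect_equal(g$abundance,
               ds$tab[ds$proteins$id[1], "tissue01"] * exp(-k * g$time_min),
               tolerance = 1e-9)
  # the adjustment recovers the undecayed abundance
  fit <- ischemia_adjust(g$time_min, g$abundance)
  expect_equal(fit$adjusted, ds$tab[ds$proteins$id[1], "tissue01"],
               tolerance = 1e-6)
})

test_that("infeasible configs are rejected up front", {
  expect_error(simulation_config(lcr_length_range = c(10, 20)), ">= 15")
  expect_error(simulation_config(lcr_fraction = 1.2))
  expect_error(simulation_config(trna_copy_range = c(5, 2)))
})

test_that("write/read round-trips a dataset including exact numerics", {
  ds <- simulate_dataset(simulation_config(n_genes = 15, seed = 12,
                                           isoform_fraction = 0.2))
  dir <- withr::local_tempdir()
  manifest <- write_dataset(ds, dir)
  expect_identical(manifest$n_rows[manifest$file == "proteins.fasta"],
                   nrow(ds$proteins))
  expect_true(file.exists(file.path(dir, "data_dictionary.tsv")))
  ds2 <- read_dataset(dir)
  expect_identical(ds$proteins, ds2$proteins)
  expect_identical(ds$tab, ds2$tab)
  expect_identical(ds$pab, ds2$pab)
  expect_identical(ds$trna_counts, ds2$trna_counts)
  expect_identical(unname(ds$kdeg), unname(ds2$kdeg))
  expect_identical(unname(ds$translation_rates),
                   unname(ds2$translation_rates))
  expect_identical(ds$ischemia_samples, ds2$ischemia_samples)
})

test_that("an empty dataset writes zero-row files without error", {
  ds <- simulate_dataset(simulation_config(n_genes = 0, seed = 1))
  dir <- withr::local_tempdir()
  manifest <- write_dataset(ds, dir)
  gene_files <- setdiff(manifest$file, c("data_dictionary.tsv", "trna_counts.tsv"))
  expect_true(all(manifest$n_rows[manifest$file %in% gene_files] == 0))
  ds2 <- read_dataset(dir)
  expect_identical(nrow(ds2$proteins), 0L)
  expect_identical(dim(ds2$tab), c(0L, 13L))
})

test_that("a 10-gene dataset writes a 10-record protein FASTA", {
  ds <- simulate_dataset(simulation_config(n_genes = 10, seed = 20))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  fa <- read_fasta(file.path(dir, "proteins.fasta"), "protein")
  expect_length(fa, 10)
  expect_identical(unname(fa), ds$proteins$protein_seq)
})
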