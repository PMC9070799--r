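test_that("isoacceptor supply sums wobble-weighted copies and self-normalizes", {
  rules <- wobble_rules(s_AA = 0.9, s_UG = 0.7, s_GU = 0.5, s_AC = 0.3)
  # CGC reads GCG (WC) and GCA via A:C; UGC reads GCA (WC) and GCG via G:U;
  # UUU reads AAA (WC) and AAG via G:U
  pool <- c(CGC = 10, UGC = 5, UUU = 20)
  s <- isoacceptor_supply(pool, rules)
  expect_equal(unname(s["AAA"]), 1)                  # the maximum
  expect_equal(unname(s["GCG"]), (10 + 5 * 0.5) / 20)  # 12.5 raw
  expect_equal(unname(s["GCA"]), (5 + 10 * (1 - 0.3)) / 20)
  expect_equal(unname(s["AAG"]), 20 * 0.5 / 20)
})

test_that("an intolerant pairing (s = 1) excludes the tRNA and floors the codon", {
  rules <- wobble_rules(s_AA = 1, s_UG = 1, s_GU = 1, s_AC = 1)
  s <- isoacceptor_supply(c(CGC = 10), rules, floor_frac = 0.5)
  expect_equal(unname(s["GCG"]), 1)       # exact match unaffected
  expect_equal(unname(s["GCA"]), 0.5)     # wobble-only codon floored
  expect_true("GCA" %in% attr(s, "floored"))
  expect_error(isoacceptor_supply(c(CGC = 0), rules), "no sense codon")
})

test_that("codon demand is the abundance-weighted count, max-normalized", {
  # hand-countable: t1 = AAA GCG, t2 = AAA AAA, TAb (1, 3)
  cds <- c("AAAGCGTAA", "AAAAAATAA")
  d <- codon_demand(cds, c(1, 3))
  expect_equal(unname(d["AAA"]), 1)            # weighted count 1 + 6 = 7 -> max
  expect_equal(unname(d["GCG"]), 1 / 7)
  expect_equal(unname(d["TTT"]), 0)
  # scale invariance
  expect_equal(d, codon_demand(cds, c(2, 6)))
  # single transcript: proportional to its codon counts
  d1 <- codon_demand("AAAAAAGCGTAA", 5)
  expect_equal(unname(d1["GCG"]), 0.5)
  expect_error(codon_demand("AAAA", 1), "divisible")
  expect_warning(codon_demand("AAATAAGCG", 1), "internal stop")
})

test_that("nTE is the geometric mean of static supply/demand", {
  ec <- toy_economy(c("AAA", "GCG", "TGC"), c(1, 0.5, 0.25), c(1, 0.5, 1))
  expect_equal(nte("AAA", ec), 1)
  expect_equal(nte("TGC", ec), 0.25)
  expect_equal(nte("AAAGCGTGC", ec), (1 * 1 * 0.25)^(1 / 3))
})

test_that("TWnTE collapses to nTE at alpha = 0 or beta = 1", {
  set.seed(21)
  codons <- sample(lcrab:::.sense_codons(), 12)
  ec <- toy_economy(codons, runif(12, 0.1, 1), runif(12, 0.1, 1))
  for (i in 1:10) {
    cds <- paste(sample(codons, 40, replace = TRUE), collapse = "")
    v <- nte(cds, ec)
    expect_equal(twnte(cds, ec, translation_params(0, runif(1))), v,
                 tolerance = 1e-12)
    expect_equal(twnte(cds, ec, translation_params(runif(1), 1)), v,
                 tolerance = 1e-12)
    # and with depletion active it can only fall below nTE
    expect_lte(twnte(cds, ec, translation_params(0.3, 0.05)), v + 1e-12)
  }
})

test_that("one elongation step updates local supply exactly as the recurrence", {
  # single species, S0 = 1, alpha_i = 0.1, beta = 0.01:
  # after one translation S = 0.01*1 + 0.99*0.9*1 = 0.901
  ec <- toy_economy("AAA", 1, 0.5)
  out <- twnte("AAAAAA", ec, translation_params(0.1, 0.01), details = TRUE)
  expect_equal(out$step_efficiency[1], 1 / 0.5)
  expect_equal(out$step_efficiency[2], 0.901 / 0.5, tolerance = 1e-12)
})

test_that("lazy-relaxation TWnTE matches the full-state simulation oracle", {
  set.seed(22)
  for (i in 1:100) {
    K <- sample(4:15, 1)
    codons <- sample(lcrab:::.sense_codons(), K)
    S0 <- runif(K, 0.05, 1); D <- runif(K, 0.05, 1)
    ec <- toy_economy(codons, S0, D)
    a <- runif(1); b <- runif(1)
    alpha_i <- pmin(1, a * min(S0) / S0)
    idx <- sample(K, sample(10:80, 1), replace = TRUE)
    cds <- paste(codons[idx], collapse = "")
    got <- twnte(cds, ec, translation_params(a, b), details = TRUE)
    want <- naive_twnte(idx, S0, D, alpha_i, b)
    expect_equal(got$step_efficiency, want$step_efficiency, tolerance = 1e-10)
    expect_equal(got$twnte, want$twnte, tolerance = 1e-10)
  }
})

test_that("efficiency is non-increasing along a homopolymer codon run", {
  set.seed(23)
  for (i in 1:20) {
    codons <- sample(lcrab:::.sense_codons(), 5)
    ec <- toy_economy(codons, runif(5, 0.1, 1), runif(5, 0.1, 1))
    run <- paste(rep(codons[1], 30), collapse = "")
    out <- twnte(run, ec, translation_params(runif(1, 0.01, 1),
                                             runif(1, 0, 0.99)),
                 details = TRUE)
    expect_true(all(diff(out$step_efficiency) <= 1e-12))
  }
})

test_that("supply state stays bounded and converges to the fixed point", {
  # repeated translation of one codon: S* = beta*S0 / (1 - (1-beta)(1-alpha))
  S0 <- 0.8; D <- 0.6; a <- 0.3; b <- 0.2
  ec <- toy_economy("GGC", S0, D)
  out <- twnte(paste(rep("GGC", 400), collapse = ""), ec,
               translation_params(a, b), details = TRUE)
  S_star <- b * S0 / (1 - (1 - b) * (1 - a))
  expect_equal(out$step_efficiency[400] * D, S_star, tolerance = 1e-8)
  S_t <- out$step_efficiency * D
  expect_true(all(S_t >= 0 & S_t <= S0 + 1e-12))
  # once translation of the species stops it relaxes back toward S0
  two <- toy_economy(c("GGC", "AAA"), c(S0, 1), c(D, 1))
  cds <- paste(c(rep("GGC", 20), rep("AAA", 60), "GGC"), collapse = "")
  o2 <- twnte(cds, two, translation_params(a, b), details = TRUE)
  depleted <- o2$step_efficiency[20]
  recovered <- o2$step_efficiency[81]
  expect_gt(recovered, depleted)
  expect_lte(recovered, S0 / D + 1e-12)
})

test_that("wobble constraints are recovered when demand mirrors a known supply", {
  set.seed(24)
  s_true <- c(0.7, 0.6, 0.4, 0.3)
  rules_true <- wobble_rules(s_true[1], s_true[2], s_true[3], s_true[4])
  sense <- lcrab:::.sense_codons()
  # full pool of Watson-Crick anticodons with spread-out copy numbers
  wc <- vapply(sense, function(cd) chartr("ATGC", "UACG",
                                          paste(rev(strsplit(cd, "")[[1]]),
                                                collapse = "")), "")
  pool <- stats::setNames(sample(5:60, length(wc), replace = TRUE), unname(wc))
  supply_true <- isoacceptor_supply(pool, rules_true)
  # one transcript per codon; abundance proportional to the true supply
  cds <- paste0(sense, "TAA")
  fit <- fit_wobble(pool, cds, as.numeric(supply_true))
  expect_gt(fit$correlation, 0.999)
  got <- unlist(fit$rules)
  expect_lt(max(abs(got - s_true)), 0.05)
  # starting at the optimum converges immediately
  fit0 <- fit_wobble(pool, cds, as.numeric(supply_true), init = rules_true)
  expect_gt(fit0$correlation, 0.9999)
})

test_that("demand unrelated to supply gives an uninformative wobble fit", {
  set.seed(25)
  sense <- lcrab:::.sense_codons()
  wc <- vapply(sense, function(cd) chartr("ATGC", "UACG",
                                          paste(rev(strsplit(cd, "")[[1]]),
                                                collapse = "")), "")
  pool <- stats::setNames(sample(5:60, length(wc), replace = TRUE), unname(wc))
  fit <- fit_wobble(pool, paste0(sense, "TAA"), rlnorm(length(sense)))
  expect_lt(fit$correlation, 0.5)
})

test_that("permuted rates destroy the translation-parameter signal", {
  set.seed(26)
  ds <- simulate_dataset(simulation_config(n_genes = 80, seed = 31))
  cds <- stats::setNames(ds$proteins$cds_seq, ds$proteins$id)
  w <- integrate_abundance(ds$tab)$integrated_abundance
  w[is.na(w)] <- 0
  ec <- codon_economy(ds$trna_counts, cds, w)
  shuffled <- stats::setNames(sample(ds$translation_rates), names(cds))
  fit <- suppressWarnings(fit_translation_params(cds, ec, shuffled))
  expect_lt(fit$correlation, 0.4)
})

test_that("rates equal to nTE push the fit onto the no-depletion ridge", {
  set.seed(27)
  ds <- simulate_dataset(simulation_config(n_genes = 80, seed = 32))
  cds <- stats::setNames(ds$proteins$cds_seq, ds$proteins$id)
  w <- integrate_abundance(ds$tab)$integrated_abundance
  w[is.na(w)] <- 0
  ec <- codon_economy(ds$trna_counts, cds, w)
  sc <- score_transcripts(cds, ec, translation_params(0, 0.5))
  fit <- suppressWarnings(
    fit_translation_params(cds, ec, stats::setNames(sc$nte, sc$id)))
  expect_gt(fit$correlation, 0.999)
  # the optimum lies where dynamics vanish: alpha ~ 0 or beta ~ 1
  expect_true(fit$params$alpha < 0.05 || fit$params$beta > 0.95)
})

test_that("scoring errors are raised for malformed input", {
  ec <- toy_economy(c("AAA", "GCG"), c(1, 0.5), c(1, 0.5))
  expect_error(nte("TTT", ec), "absent from economy")
  ec0 <- toy_economy(c("AAA", "GCG"), c(1, 0.5), c(1, 0))
  expect_error(twnte("GCG", ec0), "zero demand")
  expect_error(translation_params(1.2, 0.5))
  expect_error(wobble_rules(s_AA = -0.1))
})
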