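# simulate per-protein data with a known per-doubling effect structure
sim_logistic <- function(n, b0 = -1, b_tab = 0, b_pab = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tab <- 2^rnorm(n, 5, 2)
  pab <- 2^rnorm(n, 5, 2)
  eta <- b0 + b_tab * log2(tab) + b_pab * log2(pab)
  data.frame(lcr_status = runif(n) < plogis(eta), tab = tab, pab = pab,
             length = round(runif(n, 100, 500)))
}

test_that("a known per-doubling TAb effect is recovered with a covering CI", {
  d <- sim_logistic(5000, b_tab = log(1.1), seed = 51)
  fit <- fit_lcr_logistic(d, regression_spec(c("tab", "pab")))
  cf <- fit$coefficients
  tab_row <- cf[cf$regressor == "tab", ]
  expect_equal(tab_row$odds_per_doubling, 1.1, tolerance = 0.05)
  expect_gt(1.1, tab_row$odds_ci_lo)
  expect_lt(1.1, tab_row$odds_ci_hi)
  # pab carries no signal: its CI covers zero effect
  pab_row <- cf[cf$regressor == "pab", ]
  expect_gt(1, pab_row$odds_ci_lo)
  expect_lt(1, pab_row$odds_ci_hi)
  expect_true(fit$converged)
})

test_that("per-doubling odds agree between standardized and log2 fits", {
  d <- sim_logistic(2000, b_tab = log(1.15), b_pab = log(0.9), seed = 52)
  fit <- fit_lcr_logistic(d, regression_spec(c("tab", "pab", "length")))
  cf <- fit$coefficients
  expect_equal(exp(cf$coef_std / cf$sd_log2), cf$odds_per_doubling,
               tolerance = 1e-8)
  # standardization changes coefficient scale, not the fit itself
  expect_equal(as.numeric(stats::logLik(fit$fit_std)),
               as.numeric(stats::logLik(fit$fit_log2)), tolerance = 1e-8)
  expect_equal(stats::fitted(fit$fit_std), stats::fitted(fit$fit_log2),
               tolerance = 1e-8)
  # the documented reporting convention: coefficient ln(1.089) -> +8.9%/doubling
  expect_equal(exp(log(1.089)), 1.089, tolerance = 1e-12)
})

test_that("degenerate inputs are rejected", {
  d <- sim_logistic(100, seed = 53)
  d$lcr_status <- TRUE
  expect_error(fit_lcr_logistic(d, regression_spec(c("tab"))), "single class")
  expect_error(fit_lcr_logistic(sim_logistic(30, seed = 54),
                                regression_spec("tab")), "complete cases")
  expect_error(fit_lcr_logistic(sim_logistic(100, seed = 55),
                                regression_spec("nope")), "missing column")
})

test_that("the reduced transcript model runs independently per species", {
  set.seed(56)
  sp <- do.call(rbind, lapply(c("human", "mouse", "rat"), function(s) {
    d <- sim_logistic(800, b_tab = log(1.2))
    d$species <- s
    d$twnte <- rlnorm(800, -1, 0.3)
    d
  }))
  fits <- fit_mammal_tab_model(sp)
  expect_named(fits, c("human", "mouse", "rat"))
  tab_coefs <- vapply(fits, function(f)
    f$coefficients$coef_log2[f$coefficients$regressor == "tab"], 0)
  expect_true(all(tab_coefs > 0))
  # single table without species equals a plain reduced fit
  one <- sp[sp$species == "human", ]
  f1 <- fit_mammal_tab_model(one[, setdiff(names(one), "species")])
  expect_equal(f1$coefficients$coef_log2,
               fits$human$coefficients$coef_log2, tolerance = 1e-10)
  # dropping TWnTE must not flip the abundance relationship
  f_no <- fit_mammal_tab_model(one[, setdiff(names(one), "species")],
                               include_twnte = FALSE)
  expect_identical(sign(f_no$coefficients$coef_log2[1]),
                   sign(f1$coefficients$coef_log2[1]))
})

test_that("stratified residue fits recover class-specific abundance effects", {
  set.seed(57)
  n_pos <- 600; n_neg <- 1200
  pab <- 2^rnorm(n_pos + n_neg, 5, 2)
  tab <- 2^rnorm(n_pos + n_neg, 5, 2)
  residue <- sample(c("G", "Q", "S"), n_pos, replace = TRUE)
  # G-class LCRs enriched at high PAb, all others depleted
  b_pab <- ifelse(residue == "G", log(1.5), log(0.6))
  eta <- -0.5 + b_pab * (log2(pab[1:n_pos]) - 5)
  keep_pos <- runif(n_pos) < plogis(eta)
  d <- data.frame(
    lcr_status = c(rep(TRUE, n_pos), rep(FALSE, n_neg))[c(which(keep_pos),
                                                          n_pos + 1:n_neg)],
    primary_aa = c(residue[keep_pos], rep(NA, n_neg)),
    pab = pab[c(which(keep_pos), n_pos + 1:n_neg)],
    tab = tab[c(which(keep_pos), n_pos + 1:n_neg)])
  res <- fit_interaction_model(d)
  g_pab <- res$coef_log2[res$residue == "G" & res$regressor == "pab"]
  other_pab <- res$coef_log2[res$residue != "G" & res$regressor == "pab"]
  expect_gt(g_pab, 0)
  expect_true(all(other_pab < 0))
  # a single residue level reduces to a main-effects comparison
  d1 <- d
  d1$primary_aa[d1$lcr_status] <- "Q"
  res1 <- fit_interaction_model(d1)
  expect_identical(unique(res1$residue), "Q")
  # rare levels pool into "other"
  d2 <- d
  d2$primary_aa[d2$lcr_status][1:5] <- "W"
  res2 <- fit_interaction_model(d2, min_cases = 20)
  expect_false("W" %in% res2$residue)
})

test_that("sensitivity grid covers 26 fits and keeps abundance signs stable", {
  set.seed(58)
  ds <- simulate_dataset(simulation_config(
    n_genes = 400, seed = 61, lcr_effect_tab = 1, lcr_effect_pab = -1,
    dropout_rate = 0.3))
  cds <- stats::setNames(ds$proteins$cds_seq, ds$proteins$id)
  tabi <- integrate_abundance(ds$tab)
  pabi <- integrate_abundance(ds$pab)
  w <- tabi$integrated_abundance; w[is.na(w)] <- 0
  ec <- codon_economy(ds$trna_counts, cds, w)
  d <- data.frame(id = ds$proteins$id,
                  lcr_status = ds$proteins$lcr_true,
                  tab = tabi$integrated_abundance,
                  pab = pabi$integrated_abundance,
                  length = ds$proteins$length,
                  twnte = NA_real_)
  grid <- twnte_sensitivity(d, cds, ec,
                            regression_spec(c("pab", "tab", "twnte", "length")),
                            grid_points = seq(0, 1, length.out = 5))
  expect_identical(nrow(grid), 26L)
  expect_identical(sum(!grid$include_twnte), 1L)
  expect_true(attr(grid, "sign_stable"))
  # degenerate corners (e.g. alpha = 1, beta = 0) may zero out TWnTE and
  # be reported as NA; every feasible fit keeps the injected signs
  expect_gte(sum(is.finite(grid$coef_tab)), 20L)
  expect_true(all(grid$coef_tab > 0, na.rm = TRUE))
  expect_true(all(grid$coef_pab < 0, na.rm = TRUE))
  # the alpha = 0 rows use dynamics-free TWnTE, i.e. plain nTE
  sc <- score_transcripts(cds, ec, translation_params(0, 0.5))
  d_nte <- d; d_nte$twnte <- sc$nte
  f_nte <- fit_lcr_logistic(d_nte,
                            regression_spec(c("pab", "tab", "twnte", "length")))
  a0 <- grid[!is.na(grid$alpha) & grid$alpha == 0 & grid$beta == 0.5, ]
  expect_equal(a0$coef_tab,
               f_nte$coefficients$coef_log2[f_nte$coefficients$regressor == "tab"],
               tolerance = 1e-8)
})
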