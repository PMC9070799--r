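# Logistic regression of LCR status on abundance and covariates:
# standardized coefficients, per-doubling odds, per-residue stratified
# fits, and TWnTE-parameter sensitivity refits.

#' Specification of an LCR logistic regression
#'
#' @param regressors Character vector naming columns to use as regressors
#'   (conventionally among `pab`, `tab`, `kdeg`, `twnte`, `length`).
#' @param standardize Also report coefficients on standardized (mean 0,
#'   sd 1) log2 regressors, for cross-regressor comparison.
#' @return An object of class `regression_spec`.
#' @export
regression_spec <- function(regressors = c("pab", "tab", "kdeg", "twnte", "length"),
                            standardize = TRUE) {
  stopifnot(is.character(regressors), length(regressors) >= 1L)
  structure(list(regressors = regressors, standardize = standardize),
            class = "regression_spec")
}

.wald_ci <- function(coef, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  cbind(lo = coef - z * se, hi = coef + z * se)
}

#' Logistic regression of LCR status
#'
#' Maximum-likelihood logistic fit of LCR status on log2-transformed
#' regressors, complete cases only. Coefficients are reported both on the
#' log2 scale (so the odds fold-change per doubling of a regressor is the
#' natural exponential of its coefficient) and standardized (regressors
#' scaled to unit variance) for comparison across regressors.
#'
#' @param data Data frame with a logical/0-1 column `lcr_status` and the
#'   regressor columns named in `spec` (all positive; log2 is applied
#'   internally).
#' @param spec A [regression_spec()].
#' @param min_cases Minimum complete cases required (default 50).
#' @return An object of class `lcr_logistic`: list with `coefficients`
#'   (data frame: `regressor`, `coef_std`, `se_std`, `ci_lo`, `ci_hi`,
#'   `coef_log2`, `se_log2`, `sd_log2`, `odds_per_doubling`,
#'   `odds_ci_lo`, `odds_ci_hi`, `p_value`), `n`, `converged`,
#'   `separation`, `log_lik`, and the underlying `glm` fits.
#' @export
fit_lcr_logistic <- function(data, spec = regression_spec(), min_cases = 50L) {
  regs <- spec$regressors
  missing_cols <- setdiff(c("lcr_status", regs), names(data))
  if (length(missing_cols))
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  y <- as.logical(data$lcr_status)
  x <- log2(as.matrix(data[, regs, drop = FALSE]))
  ok <- !is.na(y) & apply(is.finite(x), 1L, all)
  y <- y[ok]; x <- x[ok, , drop = FALSE]
  if (length(y) < min_cases)
    stop("only ", length(y), " complete cases; need at least ", min_cases)
  if (length(unique(y)) < 2L)
    stop("response has a single class; logistic fit undefined")
  df_log2 <- data.frame(y = y, x)
  fit_log2 <- stats::glm(y ~ ., family = stats::binomial(), data = df_log2)
  sds <- apply(x, 2L, stats::sd)
  df_std <- data.frame(y = y, scale(x))
  fit_std <- stats::glm(y ~ ., family = stats::binomial(), data = df_std)
  sm_log2 <- summary(fit_log2)$coefficients
  sm_std <- summary(fit_std)$coefficients
  b_log2 <- sm_log2[regs, "Estimate"]; se_log2 <- sm_log2[regs, "Std. Error"]
  b_std <- sm_std[regs, "Estimate"]; se_std <- sm_std[regs, "Std. Error"]
  ci_std <- .wald_ci(b_std, se_std)
  ci_odds <- exp(.wald_ci(b_log2, se_log2))
  fitted <- stats::fitted(fit_log2)
  coefs <- data.frame(
    regressor = regs,
    coef_std = unname(b_std), se_std = unname(se_std),
    ci_lo = unname(ci_std[, "lo"]), ci_hi = unname(ci_std[, "hi"]),
    coef_log2 = unname(b_log2), se_log2 = unname(se_log2),
    sd_log2 = unname(sds),
    odds_per_doubling = unname(exp(b_log2)),
    odds_ci_lo = unname(ci_odds[, "lo"]), odds_ci_hi = unname(ci_odds[, "hi"]),
    p_value = unname(sm_log2[regs, "Pr(>|z|)"]),
    row.names = NULL)
  structure(list(coefficients = coefs, n = length(y),
                 converged = fit_log2$converged && fit_std$converged,
                 separation = any(fitted > 1 - 1e-8) || any(fitted < 1e-8),
                 log_lik = as.numeric(stats::logLik(fit_log2)),
                 fit_log2 = fit_log2, fit_std = fit_std),
            class = "lcr_logistic")
}

#' @export
print.lcr_logistic <- function(x, ...) {
  cat(sprintf("Logistic regression of LCR status (n = %d complete cases%s)\n",
              x$n, if (!x$converged) ", NOT converged"
              else if (x$separation) ", possible separation" else ""))
  df <- x$coefficients
  df$pct_per_doubling <- sprintf("%+.1f%%", 100 * (df$odds_per_doubling - 1))
  print(df[, c("regressor", "coef_std", "se_std", "odds_per_doubling",
               "pct_per_doubling", "p_value")],
        row.names = FALSE, digits = 4)
  invisible(x)
}

#' Reduced transcript-abundance model, per species
#'
#' The reduced regressor set used for RNA-Seq-only data: transcript
#' abundance and protein length, optionally translation efficiency. When
#' `data` has a `species` column the model is fitted independently per
#' species.
#'
#' @param data As in [fit_lcr_logistic()], with columns `tab`, `length`,
#'   optionally `twnte` and `species`.
#' @param include_twnte Include `twnte` as a regressor.
#' @param min_cases Passed to [fit_lcr_logistic()].
#' @return A single `lcr_logistic` object, or a named list of them (one
#'   per species).
#' @export
fit_mammal_tab_model <- function(data, include_twnte = TRUE, min_cases = 50L) {
  regs <- c("tab", "length", if (include_twnte) "twnte")
  spec <- regression_spec(regs)
  if ("species" %in% names(data)) {
    lapply(split(data, data$species), fit_lcr_logistic, spec = spec,
           min_cases = min_cases)
  } else {
    fit_lcr_logistic(data, spec, min_cases = min_cases)
  }
}

#' Per-residue abundance effects for LCR classes
#'
#' Estimates how the association of abundance with LCR status depends on
#' the primary amino acid of the low-entropy region. Because that residue
#' is only defined for LCR-positive proteins, the interaction is fitted
#' stratified: for each residue level (levels with fewer than `min_cases`
#' LCR-positive proteins pooled into `"other"`), the level's LCR-positive
#' proteins are compared against all LCR-negative proteins in a logistic
#' fit on log2 `pab` and `tab`, giving the per-residue marginal abundance
#' effects.
#'
#' @param data Data frame with columns `lcr_status`, `primary_aa` (NA for
#'   LCR-negative proteins), `pab`, `tab`.
#' @param min_cases Minimum LCR-positive proteins per residue level
#'   (default 20).
#' @param min_fit_cases Passed to [fit_lcr_logistic()] per stratum.
#' @return Data frame with one row per residue level and regressor:
#'   `residue`, `n_pos`, `regressor`, `coef_log2`, `odds_per_doubling`,
#'   `odds_ci_lo`, `odds_ci_hi`, `p_value`.
#' @export
fit_interaction_model <- function(data, min_cases = 20L, min_fit_cases = 50L) {
  stopifnot(all(c("lcr_status", "primary_aa", "pab", "tab") %in% names(data)))
  pos <- data[as.logical(data$lcr_status), , drop = FALSE]
  neg <- data[!as.logical(data$lcr_status), , drop = FALSE]
  if (nrow(pos) == 0L || nrow(neg) == 0L)
    stop("need both LCR-positive and LCR-negative proteins")
  counts <- table(pos$primary_aa)
  keep_levels <- names(counts)[counts >= min_cases]
  residue <- ifelse(pos$primary_aa %in% keep_levels, pos$primary_aa, "other")
  if (sum(residue == "other") > 0L && sum(residue == "other") < min_cases) {
    # too few pooled cases to fit; merge them into nothing rather than fail
    keep <- residue != "other"
    pos <- pos[keep, , drop = FALSE]; residue <- residue[keep]
  }
  levels_use <- unique(residue)
  if (length(levels_use) == 0L)
    stop("no residue level has at least ", min_cases, " LCR-positive proteins")
  spec <- regression_spec(c("pab", "tab"))
  out <- lapply(levels_use, function(lv) {
    sub <- rbind(pos[residue == lv, c("lcr_status", "pab", "tab")],
                 neg[, c("lcr_status", "pab", "tab")])
    fit <- fit_lcr_logistic(sub, spec, min_cases = min_fit_cases)
    cf <- fit$coefficients
    data.frame(residue = lv, n_pos = sum(residue == lv),
               regressor = cf$regressor, coef_log2 = cf$coef_log2,
               odds_per_doubling = cf$odds_per_doubling,
               odds_ci_lo = cf$odds_ci_lo, odds_ci_hi = cf$odds_ci_hi,
               p_value = cf$p_value, row.names = NULL)
  })
  out <- do.call(rbind, out)
  out[order(out$residue, out$regressor), ]
}

#' Sensitivity of the regression to translation parameters
#'
#' Refits the LCR logistic regression with TWnTE recomputed over an
#' evenly spaced grid of (alpha, beta) pairs on the unit square, plus one
#' fit excluding translation efficiency entirely, and summarizes whether
#' the signs of the abundance coefficients are stable.
#'
#' @param data Data frame with `lcr_status` and the non-TWnTE regressor
#'   columns.
#' @param cds Named vector of in-frame CDS sequences; names must match
#'   `data$id`.
#' @param economy A [codon_economy()] object.
#' @param spec A [regression_spec()] whose regressors include `"twnte"`.
#' @param grid_points Marginal grid values for alpha and beta (default 5
#'   points evenly spaced over \[0, 1\], giving 25 pairs + 1 exclusion
#'   fit).
#' @param min_cases Passed to [fit_lcr_logistic()].
#' @return Data frame with one row per fit: `alpha`, `beta`,
#'   `include_twnte`, `coef_tab`, `coef_pab` (log2-scale coefficients,
#'   `NA` when that regressor is not in the model) plus sign columns;
#'   attribute `sign_stable` is TRUE when tab and pab coefficient signs
#'   agree across all fits.
#' @export
twnte_sensitivity <- function(data, cds, economy, spec = regression_spec(),
                              grid_points = seq(0, 1, length.out = 5),
                              min_cases = 50L) {
  stopifnot("twnte" %in% spec$regressors, "id" %in% names(data),
            all(data$id %in% names(cds)))
  cds <- cds[data$id]
  grid <- expand.grid(alpha = grid_points, beta = grid_points)
  # a degenerate grid point (e.g. alpha = 1, beta = 0) can zero out TWnTE
  # for most transcripts and leave too few complete cases; report NA
  # coefficients for that point instead of aborting the grid
  one_fit <- function(d, regs) {
    tryCatch({
      fit <- fit_lcr_logistic(d, regression_spec(regs), min_cases = min_cases)
      cf <- fit$coefficients
      get <- function(r) if (r %in% cf$regressor) cf$coef_log2[cf$regressor == r] else NA_real_
      c(coef_tab = get("tab"), coef_pab = get("pab"))
    }, error = function(e) c(coef_tab = NA_real_, coef_pab = NA_real_))
  }
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    pars <- translation_params(grid$alpha[i], grid$beta[i])
    d <- data
    d$twnte <- score_transcripts(cds, economy, pars)$twnte
    cbind(data.frame(alpha = grid$alpha[i], beta = grid$beta[i],
                     include_twnte = TRUE),
          as.data.frame(as.list(one_fit(d, spec$regressors))))
  })
  no_tw <- cbind(data.frame(alpha = NA_real_, beta = NA_real_,
                            include_twnte = FALSE),
                 as.data.frame(as.list(
                   one_fit(data, setdiff(spec$regressors, "twnte")))))
  out <- rbind(do.call(rbind, rows), no_tw)
  out$sign_tab <- sign(out$coef_tab)
  out$sign_pab <- sign(out$coef_pab)
  stable <- function(s) length(unique(s[!is.na(s)])) <= 1L
  attr(out, "sign_stable") <- stable(out$sign_tab) && stable(out$sign_pab)
  out
}
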