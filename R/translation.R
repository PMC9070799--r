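# Codon supply/demand economy and the Time-Weighted normalized Translation
# Efficiency (TWnTE) model: tRNA isoacceptor supply under wobble constraints,
# abundance-weighted codon demand, per-elongation-step local supply dynamics,
# and Nelder-Mead fitting of the wobble and perturbability/resupply
# parameters.

# DNA base complementary to an RNA anticodon base
.anticodon_comp <- c(A = "T", U = "A", G = "C", C = "G")

.sense_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  names(gc)[gc != "*"]
}

#' Wobble pairing constraints
#'
#' Selective constraints on third-position codon:anticodon pairing.
#' Watson-Crick pairs carry no penalty (s = 0); the four tolerated
#' mismatches (codon base : anticodon wobble base) A:A, U:G, G:U and A:C
#' carry penalties in \[0, 1\] where 0 is fully tolerated and 1 excludes
#' the pairing; all other pairings are excluded. Defaults are
#' yeast-derived starting estimates customarily used to initialise the
#' per-organism fit.
#'
#' @param s_AA,s_UG,s_GU,s_AC Penalties in \[0, 1\] for the four tolerated
#'   third-position mismatches.
#' @return An object of class `wobble_rules`.
#' @export
wobble_rules <- function(s_AA = 0.9999, s_UG = 0.68, s_GU = 0.41, s_AC = 0.28) {
  s <- c(s_AA = s_AA, s_UG = s_UG, s_GU = s_GU, s_AC = s_AC)
  stopifnot(all(is.finite(s)), all(s >= 0), all(s <= 1))
  structure(as.list(s), class = "wobble_rules")
}

#' @export
print.wobble_rules <- function(x, ...) {
  cat(sprintf(
    "Wobble constraints (0 tolerant, 1 intolerant): A:A %.4f, U:G %.4f, G:U %.4f, A:C %.4f\n",
    x$s_AA, x$s_UG, x$s_GU, x$s_AC))
  invisible(x)
}

#' Translation dynamics parameters
#'
#' Base perturbability `alpha` (the proportion of local tRNA supply a
#' single elongation step consumes, calibrated on the least supplied
#' codon) and resupply coefficient `beta` (the portion of the deficit
#' between local and global supply restored per step). Defaults are the
#' mouse estimates: one step consumes 5.78% of the least supplied codon's
#' isoacceptor pool while 0.064% of the deficit is restored.
#'
#' @param alpha,beta Values in \[0, 1\].
#' @return An object of class `translation_params`.
#' @export
translation_params <- function(alpha = 0.0578, beta = 0.00064) {
  stopifnot(length(alpha) == 1L, length(beta) == 1L,
            is.finite(alpha), is.finite(beta),
            alpha >= 0, alpha <= 1, beta >= 0, beta <= 1)
  structure(list(alpha = alpha, beta = beta), class = "translation_params")
}

#' @export
print.translation_params <- function(x, ...) {
  cat(sprintf("Translation parameters: perturbability alpha = %g, resupply beta = %g\n",
              x$alpha, x$beta))
  invisible(x)
}

# codons (DNA) readable by one anticodon (RNA, 5'->3'), with weights (1 - s)
.anticodon_decodes <- function(anticodon, rules) {
  b <- strsplit(anticodon, "", fixed = TRUE)[[1]]
  if (length(b) != 3L || !all(b %in% names(.anticodon_comp)))
    stop("invalid RNA anticodon: ", anticodon)
  stem <- paste0(.anticodon_comp[[b[3]]], .anticodon_comp[[b[2]]])
  # third codon base options for this wobble base: Watson-Crick plus
  # tolerated mismatches
  third <- switch(b[1],
    A = c(T = 1, A = 1 - rules$s_AA),
    G = c(C = 1, T = 1 - rules$s_UG),
    U = c(A = 1, G = 1 - rules$s_GU),
    C = c(G = 1, A = 1 - rules$s_AC))
  data.frame(codon = paste0(stem, names(third)), weight = unname(third))
}

#' Codon supply from a tRNA pool under wobble constraints
#'
#' Raw supply of a sense codon is the sum over tRNA isoacceptors able to
#' read it of the genomic copy number weighted by one minus the wobble
#' penalty; positions 1-2 must pair Watson-Crick and position 3 by
#' Watson-Crick or a tolerated mismatch. Supplies are normalized by the
#' maximum, and codons with zero raw supply are floored to a fraction of
#' the minimum nonzero normalized supply so downstream geometric means
#' stay defined.
#'
#' @param trna_counts Named nonnegative numeric vector: RNA anticodon
#'   (5'->3') to genomic copy number.
#' @param rules A [wobble_rules()] object.
#' @param floor_frac Zero-supply codons are set to `floor_frac` times the
#'   minimum nonzero normalized supply (default 0.5).
#' @return Named numeric vector of normalized supplies over the 61 sense
#'   codons (DNA spelling), maximum 1, with attribute `floored` naming the
#'   codons that received the floor.
#' @export
isoacceptor_supply <- function(trna_counts, rules = wobble_rules(),
                               floor_frac = 0.5) {
  stopifnot(is.numeric(trna_counts), !is.null(names(trna_counts)),
            all(trna_counts >= 0), floor_frac > 0, floor_frac <= 1)
  sense <- .sense_codons()
  raw <- stats::setNames(numeric(length(sense)), sense)
  for (ac in names(trna_counts)) {
    dec <- .anticodon_decodes(ac, rules)
    hit <- dec$codon %in% sense
    raw[dec$codon[hit]] <- raw[dec$codon[hit]] + dec$weight[hit] * trna_counts[[ac]]
  }
  if (all(raw == 0)) stop("tRNA pool supplies no sense codon")
  s <- raw / max(raw)
  zero <- s == 0
  if (any(zero)) s[zero] <- floor_frac * min(s[!zero])
  attr(s, "floored") <- sense[zero]
  s
}

# split an in-frame CDS into codons, dropping a trailing stop
.codon_split <- function(cds, on_internal_stop = c("warn", "error", "ignore")) {
  on_internal_stop <- match.arg(on_internal_stop)
  n <- nchar(cds)
  if (n %% 3 != 0) stop("CDS length not divisible by 3 (", n, " nt)")
  codons <- substring(toupper(cds), seq(1, n - 2, 3), seq(3, n, 3))
  stops <- c("TAA", "TAG", "TGA")
  if (length(codons) && codons[length(codons)] %in% stops)
    codons <- codons[-length(codons)]
  internal <- codons %in% stops
  if (any(internal)) {
    msg <- sprintf("%d internal stop codon(s) in CDS", sum(internal))
    if (on_internal_stop == "error") stop(msg)
    if (on_internal_stop == "warn") warning(msg)
    codons <- codons[!internal]
  }
  codons
}

#' Abundance-weighted codon demand
#'
#' Demand for codon i is proportional to the transcript-abundance-weighted
#' count of i across the transcriptome, normalized by the maximum. Stop
#' codons are excluded.
#'
#' @param cds List or character vector of in-frame CDS sequences.
#' @param tab Matching transcript abundances (nonnegative).
#' @param on_internal_stop How to treat internal stop codons: `"warn"`
#'   (default, codon dropped), `"error"`, or `"ignore"` (dropped silently).
#' @return Named numeric vector of demands over the 61 sense codons
#'   (0 for codons absent from the weighted transcriptome), maximum 1.
#' @export
codon_demand <- function(cds, tab, on_internal_stop = "warn") {
  cds <- as.character(cds)
  stopifnot(length(cds) == length(tab), all(tab >= 0))
  sense <- .sense_codons()
  counts <- stats::setNames(numeric(length(sense)), sense)
  for (i in seq_along(cds)) {
    if (tab[i] == 0) next
    tb <- table(.codon_split(cds[i], on_internal_stop))
    idx <- names(tb) %in% sense
    counts[names(tb)[idx]] <- counts[names(tb)[idx]] + tab[i] * as.numeric(tb)[idx]
  }
  if (max(counts) == 0) stop("no codon has positive weighted count")
  counts / max(counts)
}

#' Build a codon economy (supply and demand)
#'
#' Combines [isoacceptor_supply()] and [codon_demand()] into one table per
#' sense codon, with the static per-codon efficiency supply/demand.
#'
#' @inheritParams isoacceptor_supply
#' @inheritParams codon_demand
#' @return An object of class `codon_economy`: a data frame with columns
#'   `codon`, `supply`, `demand`, `nte_codon` (supply/demand, `NA` where
#'   demand is 0), carrying the wobble rules and floored codons as
#'   attributes.
#' @export
codon_economy <- function(trna_counts, cds, tab, rules = wobble_rules(),
                          floor_frac = 0.5, on_internal_stop = "warn") {
  s <- isoacceptor_supply(trna_counts, rules, floor_frac)
  d <- codon_demand(cds, tab, on_internal_stop)
  out <- data.frame(codon = names(s), supply = as.numeric(s),
                    demand = as.numeric(d[names(s)]))
  out$nte_codon <- ifelse(out$demand > 0, out$supply / out$demand, NA_real_)
  structure(out, floored = attr(s, "floored"), rules = rules,
            class = c("codon_economy", "data.frame"))
}

# economy lookups shared by nte/twnte
.economy_vectors <- function(economy) {
  stopifnot(inherits(economy, "codon_economy"))
  list(codon = economy$codon,
       S0 = stats::setNames(economy$supply, economy$codon),
       D = stats::setNames(economy$demand, economy$codon))
}

.codon_indices <- function(cds, economy_codons, on_internal_stop = "warn") {
  codons <- .codon_split(cds, on_internal_stop)
  idx <- match(codons, economy_codons)
  if (anyNA(idx))
    stop("codon absent from economy: ",
         paste(unique(codons[is.na(idx)]), collapse = ", "))
  idx
}

#' Normalized translation efficiency (nTE) of a transcript
#'
#' Geometric mean over the transcript's codons of the static per-codon
#' supply/demand ratio; no local-supply dynamics. The trailing stop codon
#' is excluded.
#'
#' @param cds In-frame CDS sequence.
#' @param economy A [codon_economy()] object.
#' @return Positive scalar.
#' @export
nte <- function(cds, economy) {
  ev <- .economy_vectors(economy)
  idx <- .codon_indices(cds, ev$codon)
  d <- ev$D[idx]
  if (any(d == 0)) stop("transcript uses codon(s) with zero demand")
  exp(mean(log(ev$S0[idx] / d)))
}

# per-step TWnTE efficiencies; the heavy per-elongation-step loop lives in
# compiled code (src/twnte.cpp) with lazy geometric relaxation of
# untranslated species toward their global supply
.twnte_steps <- function(idx, S0, D, alpha_i, beta) {
  .twnte_steps_cpp(as.integer(idx), as.numeric(S0), as.numeric(D),
                   as.numeric(alpha_i), beta)
}

#' Time-weighted normalized translation efficiency (TWnTE)
#'
#' Extends [nte()] with a local tRNA supply state per codon species.
#' Supplies start at the normalized global supply; each elongation step
#' scores the current codon as local supply over demand (before that
#' step's update), then depletes the translated species by its
#' perturbability and restores every species a fraction `beta` of the way
#' back toward its global supply:
#' \deqn{S_{i,t} = \beta S_{i,0} + (1-\beta)(1-\alpha_i) S_{i,t-1}}
#' with \eqn{\alpha_i = 0} for species not translated at step t. The
#' per-codon perturbability is the base rate scaled to the least supplied
#' codon, \eqn{\alpha_i = \alpha S_{min,0} / S_{i,0}}, capped at 1. TWnTE
#' is the geometric mean of the per-step efficiencies; repeated use of a
#' scarce codon therefore scores lower than the same codons dispersed.
#'
#' @param cds In-frame CDS sequence (trailing stop excluded from scoring).
#' @param economy A [codon_economy()] object.
#' @param params A [translation_params()] object.
#' @param details Also return the per-step efficiencies.
#' @return Positive scalar, or with `details = TRUE` a list with elements
#'   `twnte` and `step_efficiency`.
#' @export
twnte <- function(cds, economy, params = translation_params(), details = FALSE) {
  ev <- .economy_vectors(economy)
  idx <- .codon_indices(cds, ev$codon)
  if (any(ev$D[idx] == 0)) stop("transcript uses codon(s) with zero demand")
  alpha_i <- pmin(1, params$alpha * min(ev$S0) / ev$S0)
  eff <- .twnte_steps(idx, ev$S0, ev$D, alpha_i, params$beta)
  val <- if (any(eff <= 0)) 0 else exp(mean(log(eff)))
  if (details) list(twnte = val, step_efficiency = eff) else val
}

#' Score many transcripts with nTE and TWnTE
#'
#' @param cds Named list/vector of in-frame CDS sequences.
#' @param economy A [codon_economy()] object.
#' @param params A [translation_params()] object.
#' @return Data frame with columns `id`, `nte`, `twnte`.
#' @export
score_transcripts <- function(cds, economy, params = translation_params()) {
  ids <- names(cds)
  cds <- stats::setNames(as.character(cds), ids)
  stopifnot(!is.null(names(cds)))
  ev <- .economy_vectors(economy)
  alpha_i <- pmin(1, params$alpha * min(ev$S0) / ev$S0)
  logS0D <- log(ev$S0) - log(ev$D)
  res <- vapply(cds, function(x) {
    idx <- .codon_indices(x, ev$codon)
    eff <- .twnte_steps(idx, ev$S0, ev$D, alpha_i, params$beta)
    c(nte = exp(mean(logS0D[idx])),
      twnte = if (any(eff <= 0)) 0 else exp(mean(log(eff))))
  }, c(nte = 0, twnte = 0))
  data.frame(id = names(cds), nte = res["nte", ], twnte = res["twnte", ],
             row.names = NULL)
}

# correlation used by both optimizers; log variant drops nonpositive pairs
.fit_cor <- function(x, y, method) {
  if (method == "pearson-log") {
    ok <- is.finite(x) & is.finite(y) & x > 0 & y > 0
    if (sum(ok) < 3L) return(NA_real_)
    stats::cor(log(x[ok]), log(y[ok]))
  } else {
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L) return(NA_real_)
    stats::cor(x[ok], y[ok], method = method)
  }
}

.qlogis_safe <- function(p, eps = 1e-6) stats::qlogis(pmin(1 - eps, pmax(eps, p)))

#' Fit wobble constraints to a transcriptome
#'
#' Finds the four mismatch penalties maximizing the correlation between
#' normalized codon supply and abundance-weighted codon demand across
#' sense codons, by Nelder-Mead on a logit parameterization of the unit
#' box, starting from yeast-derived estimates.
#'
#' @inheritParams codon_economy
#' @param init A [wobble_rules()] object of starting values.
#' @param corr Correlation flavour: `"pearson-log"` (default, Pearson on
#'   log values), `"pearson"`, or `"spearman"`.
#' @return List with `rules` (fitted [wobble_rules()]), `correlation`
#'   (achieved), `convergence` (0 = converged), and `uninformative`
#'   (TRUE when the achieved correlation is negligible, |r| < 0.05).
#' @export
fit_wobble <- function(trna_counts, cds, tab, init = wobble_rules(),
                       floor_frac = 0.5,
                       corr = c("pearson-log", "pearson", "spearman")) {
  corr <- match.arg(corr)
  demand <- codon_demand(cds, tab, on_internal_stop = "ignore")
  pos <- demand > 0
  obj <- function(z) {
    s <- stats::plogis(z)
    rules <- wobble_rules(s[1], s[2], s[3], s[4])
    sup <- isoacceptor_supply(trna_counts, rules, floor_frac)
    r <- .fit_cor(sup[pos], demand[pos], corr)
    if (is.na(r)) 1 else -r
  }
  z0 <- .qlogis_safe(c(init$s_AA, init$s_UG, init$s_GU, init$s_AC))
  opt <- stats::optim(z0, obj, method = "Nelder-Mead",
                      control = list(maxit = 2000, reltol = 1e-10))
  if (opt$convergence != 0)
    warning("wobble fit did not fully converge; returning best found")
  s <- stats::plogis(opt$par)
  list(rules = wobble_rules(s[1], s[2], s[3], s[4]),
       correlation = -opt$value,
       convergence = opt$convergence,
       uninformative = abs(opt$value) < 0.05)
}

#' Fit perturbability and resupply to measured translation rates
#'
#' Finds `(alpha, beta)` maximizing the correlation between TWnTE and
#' measured per-protein translation rates, by Nelder-Mead from (0.5, 0.5)
#' on a logit parameterization of the unit square.
#'
#' @param cds Named list/vector of in-frame CDS sequences.
#' @param economy A [codon_economy()] object.
#' @param rates Named positive vector of measured translation rates; names
#'   must match `cds`.
#' @param init Numeric length-2 starting values for `(alpha, beta)`.
#' @param corr As in [fit_wobble()]; default Pearson on log values since
#'   both quantities span decades.
#' @return List with `params` (fitted [translation_params()]),
#'   `correlation`, and `convergence`.
#' @export
fit_translation_params <- function(cds, economy, rates, init = c(0.5, 0.5),
                                   corr = c("pearson-log", "pearson", "spearman")) {
  corr <- match.arg(corr)
  cds <- stats::setNames(as.character(cds), names(cds))
  stopifnot(!is.null(names(cds)), all(names(cds) %in% names(rates)))
  rates <- rates[names(cds)]
  if (length(cds) < 2L) stop("need at least 2 transcripts with rates")
  if (stats::sd(rates) == 0) stop("constant rates: correlation undefined")
  ev <- .economy_vectors(economy)
  idx_list <- lapply(cds, .codon_indices, economy_codons = ev$codon)
  smin <- min(ev$S0)
  obj <- function(z) {
    a <- stats::plogis(z[1]); b <- stats::plogis(z[2])
    alpha_i <- pmin(1, a * smin / ev$S0)
    tw <- vapply(idx_list, function(idx) {
      eff <- .twnte_steps(idx, ev$S0, ev$D, alpha_i, b)
      if (any(eff <= 0)) 0 else exp(mean(log(eff)))
    }, 0)
    r <- .fit_cor(tw, rates, corr)
    if (is.na(r)) 1 else -r
  }
  opt <- stats::optim(.qlogis_safe(init), obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-8))
  if (opt$convergence != 0)
    warning("translation-parameter fit did not fully converge; returning best found")
  list(params = translation_params(stats::plogis(opt$par[1]),
                                   stats::plogis(opt$par[2])),
       correlation = -opt$value,
       convergence = opt$convergence)
}
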