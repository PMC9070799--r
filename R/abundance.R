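# Per-gene abundance integration across tissues, tissue specificity (tau),
# post-mortem ischemia-time adjustment, and degradation-rate aggregation.

#' Tau tissue-specificity index
#'
#' \deqn{\tau = \sum_i (1 - x_i / x_{max}) / (N - 1)}
#' over the `N` tissue values. Tau is 0 for a gene expressed equally in all
#' tissues and 1 for a gene expressed in exactly one tissue. Computed on
#' linear-scale values by default; `log2 = TRUE` uses `log2(x + 1)`.
#'
#' @param x Nonnegative expression vector over at least two tissues with a
#'   positive maximum.
#' @param log2 Compute tau on `log2(x + 1)` instead of linear values.
#' @return Tau in \[0, 1\].
#' @examples
#' tau_index(rep(7, 13))          # 0: uniform expression
#' tau_index(c(5, rep(0, 12)))    # 1: single-tissue expression
#' tau_index(c(4, 1, 1, 1, 1))    # 0.75
#' @export
tau_index <- function(x, log2 = FALSE) {
  stopifnot(is.numeric(x), length(x) >= 2L, all(is.finite(x)))
  if (any(x < 0)) stop("expression values must be nonnegative")
  if (max(x) <= 0) stop("tau is undefined for an all-zero expression vector")
  if (log2) x <- base::log2(x + 1)
  sum(1 - x / max(x)) / (length(x) - 1L)
}

#' Integrate per-tissue abundance into per-gene summaries
#'
#' Each gene's integrated abundance is the median over tissues in which it
#' is expressed (strictly positive entries); tissues with zero measurement
#' are excluded. Genes with all-zero rows are flagged unexpressed and get
#' `NA` summaries. Tissue specificity is quantified with [tau_index()]
#' over all tissues (zeros included).
#'
#' @param mat Numeric matrix of nonnegative abundances, genes in rows
#'   (rownames are gene ids), tissues in columns.
#' @param tau_log2 Passed to [tau_index()] as `log2`.
#' @return Data frame with columns `id`, `integrated_abundance`,
#'   `n_expressed_tissues`, `tau`, `expressed`.
#' @examples
#' m <- rbind(g1 = c(0, 2, 8), g2 = c(3, 3, 3), g3 = c(0, 0, 0))
#' integrate_abundance(m)
#' @export
integrate_abundance <- function(mat, tau_log2 = FALSE) {
  stopifnot(is.matrix(mat), ncol(mat) >= 1L, !is.null(rownames(mat)))
  if (any(mat < 0)) stop("abundance values must be nonnegative")
  n_pos <- rowSums(mat > 0)
  med <- apply(mat, 1L, function(r) if (any(r > 0)) stats::median(r[r > 0]) else NA_real_)
  tau <- apply(mat, 1L, function(r)
    if (length(r) >= 2L && max(r) > 0) tau_index(r, log2 = tau_log2) else NA_real_)
  data.frame(id = rownames(mat),
             integrated_abundance = unname(med),
             n_expressed_tissues = unname(as.integer(n_pos)),
             tau = unname(tau),
             expressed = unname(n_pos > 0L),
             row.names = NULL)
}

#' Adjust abundance for post-mortem ischemia time
#'
#' Fits an exponential decay \eqn{A e^{-kt}} to abundance as a function of
#' ischemia time by ordinary least squares on the log scale, and returns
#' the fitted abundance at time zero (the intercept `A`). The decay
#' constant `k` is unconstrained in sign. Samples with nonpositive
#' abundance are dropped from the fit; with fewer than `min_samples`
#' positive samples, or degenerate (all-identical) times, the function
#' falls back to the unadjusted median of the positive observations.
#'
#' @param time Ischemia times in minutes.
#' @param abundance Matching abundance measurements.
#' @param min_samples Minimum positive samples required for a fit
#'   (default 3).
#' @return List with `adjusted` (abundance extrapolated to t = 0), `k`
#'   (per-minute decay constant, `NA` on fallback), `fitted` (logical:
#'   was an exponential fit used), `n_used`.
#' @examples
#' t <- c(0, 60, 120, 240)
#' ischemia_adjust(t, 100 * exp(-0.01 * t))$adjusted  # ~100
#' @export
ischemia_adjust <- function(time, abundance, min_samples = 3L) {
  stopifnot(length(time) == length(abundance))
  ok <- is.finite(time) & is.finite(abundance) & abundance > 0
  t_u <- time[ok]; a_u <- abundance[ok]
  fallback <- function(warn = NULL) {
    if (!is.null(warn)) warning(warn)
    list(adjusted = if (length(a_u)) stats::median(a_u) else NA_real_,
         k = NA_real_, fitted = FALSE, n_used = length(a_u))
  }
  if (length(a_u) < min_samples) return(fallback())
  if (length(unique(t_u)) < 2L)
    return(fallback("degenerate ischemia fit: all sample times identical"))
  fit <- stats::lm.fit(cbind(1, t_u), log(a_u))
  list(adjusted = exp(fit$coefficients[[1]]),
       k = -fit$coefficients[[2]],
       fitted = TRUE, n_used = length(a_u))
}

#' Ischemia-adjusted abundance matrix from per-sample measurements
#'
#' Applies [ischemia_adjust()] per gene and tissue to long-format sample
#' data, rebuilding a genes-by-tissues matrix of abundances extrapolated
#' to zero ischemia time.
#'
#' @param samples Data frame with columns `gene`, `tissue`, `time_min`,
#'   `abundance` (one row per gene, tissue and sample).
#' @param min_samples Passed to [ischemia_adjust()].
#' @return Numeric matrix, genes by tissues; cells with no positive
#'   observations are 0.
#' @export
ischemia_adjusted_tab <- function(samples, min_samples = 3L) {
  need <- c("gene", "tissue", "time_min", "abundance")
  stopifnot(all(need %in% names(samples)))
  genes <- unique(samples$gene); tissues <- unique(samples$tissue)
  out <- matrix(0, length(genes), length(tissues),
                dimnames = list(genes, tissues))
  split_idx <- split(seq_len(nrow(samples)),
                     list(gene = samples$gene, tissue = samples$tissue),
                     drop = TRUE)
  for (key in names(split_idx)) {
    idx <- split_idx[[key]]
    g <- samples$gene[idx[1]]; ti <- samples$tissue[idx[1]]
    adj <- ischemia_adjust(samples$time_min[idx], samples$abundance[idx],
                           min_samples = min_samples)
    out[g, ti] <- if (is.na(adj$adjusted)) 0 else adj$adjusted
  }
  out
}

#' Aggregate protein degradation coefficients across studies
#'
#' Converts reported values to first-order degradation coefficients
#' (half-lives via \eqn{k_{deg} = \ln 2 / t_{1/2}}) and takes the
#' per-protein geometric mean across studies.
#'
#' @param id Protein identifier per measurement.
#' @param value Positive reported value per measurement.
#' @param kind `"kdeg"` (per hour) or `"half_life"` (hours), recycled.
#' @return Named numeric vector of per-protein kdeg (per hour).
#' @examples
#' aggregate_kdeg("p1", 6.93, "half_life")            # ~0.1 per hour
#' aggregate_kdeg(c("p2", "p2"), c(0.01, 0.04), "kdeg")  # 0.02
#' @export
aggregate_kdeg <- function(id, value, kind = "kdeg") {
  stopifnot(length(id) == length(value))
  kind <- match.arg(rep(kind, length.out = length(value)),
                    c("kdeg", "half_life"), several.ok = TRUE)
  if (any(!is.finite(value) | value <= 0))
    stop("degradation values must be positive")
  k <- ifelse(kind == "half_life", log(2) / value, value)
  vapply(split(k, id), function(v) exp(mean(log(v))), 0)
}

#' Keep one transcript-protein pair per gene
#'
#' When a gene has several isoforms, retains the pair with the highest
#' integrated protein abundance, breaking ties by record id order.
#'
#' @param id Record (isoform) identifiers.
#' @param gene Gene identifier per record.
#' @param pab Integrated protein abundance per record.
#' @return Logical keep vector aligned with `id`.
#' @export
dedup_isoforms <- function(id, gene, pab) {
  stopifnot(length(id) == length(gene), length(id) == length(pab))
  keep <- logical(length(id))
  for (idx in split(seq_along(id), gene)) {
    ord <- idx[order(-pab[idx], id[idx])]
    keep[ord[1]] <- TRUE
  }
  keep
}
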