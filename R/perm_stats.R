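# Quartile-shift permutation tests between LCR+ and LCR- groups, labelled
# variants, and the Mann-Whitney rank-sum verification.

# evaluate `code` under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  code
}

.quartiles <- function(x) stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE,
                                          type = 7)

#' Observed quartile shifts between two groups
#'
#' For the first quartile, median and third quartile, the shift is the
#' quantile of the positive-label group minus the same quantile of the
#' negative-label group. Abundances are log2-transformed by default, so
#' shifts are in log2 units.
#'
#' @param values Positive per-protein abundances.
#' @param labels Logical vector; `TRUE` marks the LCR-positive group.
#' @param log2 Transform values with log2 before taking quantiles.
#' @return Named numeric vector `c(q1, median, q3)`.
#' @examples
#' quartile_shift(1:8, c(TRUE, TRUE, rep(FALSE, 6)), log2 = FALSE)
#' @export
quartile_shift <- function(values, labels, log2 = TRUE) {
  stopifnot(is.numeric(values), is.logical(labels),
            length(values) == length(labels))
  if (!any(labels) || all(labels)) stop("both label groups must be nonempty")
  if (log2) {
    if (any(values <= 0)) stop("values must be positive for log2 transform")
    values <- base::log2(values)
  }
  out <- .quartiles(values[labels]) - .quartiles(values[!labels])
  names(out) <- c("q1", "median", "q3")
  out
}

#' Permutation test of quartile shifts
#'
#' Builds a null distribution for each quartile shift by repeatedly
#' shuffling the group labels (preserving group sizes), and reports the
#' empirical p-value as the proportion of permutations with a shift at
#' least as extreme as observed, one-sided in the observed direction by
#' default (a shift of exactly zero is reported with p = 1 one-sided).
#'
#' @inheritParams quartile_shift
#' @param n_perm Number of label permutations (>= 1; >= 100 recommended).
#' @param seed Optional integer seed; the caller's RNG state is restored
#'   afterwards.
#' @param two_sided Use `|shift| >= |observed|` instead of the one-sided
#'   rule.
#' @param plus_one Report `(k + 1) / (n_perm + 1)` instead of the raw
#'   proportion `k / n_perm`.
#' @param keep_null Retain the full null shift matrix (for plotting).
#' @return An object of class `permutation_result`: list with `observed`,
#'   `p`, `direction` (sign of observed shift), `null_mean`, `null_sd`,
#'   `n_perm`, `seed`, `n_pos`, `n_neg`, and optionally `null` (an
#'   `n_perm` by 3 matrix).
#' @export
permutation_test <- function(values, labels, n_perm = 10000L, seed = NULL,
                             log2 = TRUE, two_sided = FALSE,
                             plus_one = FALSE, keep_null = FALSE) {
  n_perm <- as.integer(n_perm)
  stopifnot(n_perm >= 1L)
  observed <- quartile_shift(values, labels, log2 = log2)
  v <- if (log2) base::log2(values) else values
  if (stats::var(v) == 0) stop("degenerate input: all values identical")
  n <- length(v)
  n_pos <- sum(labels)
  null <- .with_seed(seed, {
    m <- matrix(0, n_perm, 3L)
    for (b in seq_len(n_perm)) {
      pos <- sample.int(n, n_pos)
      m[b, ] <- .quartiles(v[pos]) - .quartiles(v[-pos])
    }
    m
  })
  k <- vapply(1:3, function(j) {
    if (two_sided) sum(abs(null[, j]) >= abs(observed[j]))
    else if (observed[j] > 0) sum(null[, j] >= observed[j])
    else if (observed[j] < 0) sum(null[, j] <= observed[j])
    else n_perm
  }, 0)
  p <- if (plus_one) (k + 1) / (n_perm + 1) else k / n_perm
  names(p) <- names(observed)
  out <- list(observed = observed, p = p, direction = sign(observed),
              null_mean = colMeans(null), null_sd = apply(null, 2, stats::sd),
              n_perm = n_perm, seed = seed, n_pos = n_pos, n_neg = n - n_pos)
  if (keep_null) out$null <- null
  structure(out, class = "permutation_result")
}

#' @export
print.permutation_result <- function(x, ...) {
  cat(sprintf("Quartile-shift permutation test (%d LCR+, %d LCR-, %d permutations)\n",
              x$n_pos, x$n_neg, x$n_perm))
  df <- data.frame(quantile = names(x$observed),
                   observed_shift = round(unname(x$observed), 4),
                   p = unname(x$p), direction = unname(x$direction))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Mann-Whitney rank-sum verification
#'
#' Two-sided Wilcoxon rank-sum test (normal approximation with tie and
#' continuity correction) between the two label groups, used to verify
#' the permutation test of the median shift.
#'
#' @inheritParams quartile_shift
#' @return Two-sided p-value.
#' @export
ranksum_check <- function(values, labels) {
  stopifnot(length(values) == length(labels))
  if (!any(labels) || all(labels)) stop("both label groups must be nonempty")
  stats::wilcox.test(values[labels], values[!labels],
                     exact = FALSE, correct = TRUE)$p.value
}

#' Labelled variants of the permutation analysis
#'
#' Runs the quartile-shift permutation test under one of the study's
#' robustness conditions, on transcript and protein abundance.
#'
#' Variants: `"baseline"` permutes LCR status; `"disorder-label"` permutes
#' intrinsic-disorder status instead; `"ischemia-adjusted"` substitutes
#' ischemia-time-adjusted transcript abundance; `"homopolymer-only"` and
#' `"heteropolymer-only"` compare only that LCR class against LCR-negative
#' proteins; `"isoform-dedup"` first keeps one transcript-protein pair per
#' gene via [dedup_isoforms()].
#'
#' @param data Per-protein data frame with columns `id`, `lcr_status`,
#'   `tab`, `pab`, and, as the variant requires, `disorder_status`,
#'   `tab_adjusted`, `has_homopolymer`, `gene`. Rows without positive
#'   values for both abundance types are dropped first.
#' @param variant One of the variant names above.
#' @param n_perm,seed,... Passed to [permutation_test()].
#' @return Data frame with one row per abundance type and quantile:
#'   `variant`, `abundance_type`, `quantile`, `observed_shift`, `p`,
#'   `direction`, `n_perm`, `seed`.
#' @export
run_variants <- function(data, variant = c("baseline", "disorder-label",
                                           "ischemia-adjusted",
                                           "homopolymer-only",
                                           "heteropolymer-only",
                                           "isoform-dedup"),
                         n_perm = 10000L, seed = NULL, ...) {
  variant <- match.arg(variant)
  need <- switch(variant,
                 "disorder-label" = "disorder_status",
                 "ischemia-adjusted" = "tab_adjusted",
                 "homopolymer-only" = "has_homopolymer",
                 "heteropolymer-only" = "has_homopolymer",
                 "isoform-dedup" = "gene",
                 character(0))
  missing_cols <- setdiff(c("id", "lcr_status", "tab", "pab", need), names(data))
  if (length(missing_cols))
    stop("variant '", variant, "' needs missing column(s): ",
         paste(missing_cols, collapse = ", "))
  keep <- is.finite(data$tab) & data$tab > 0 & is.finite(data$pab) & data$pab > 0
  if (variant == "ischemia-adjusted")
    keep <- keep & is.finite(data$tab_adjusted) & data$tab_adjusted > 0
  data <- data[keep, , drop = FALSE]
  if (variant == "isoform-dedup")
    data <- data[dedup_isoforms(data$id, data$gene, data$pab), , drop = FALSE]
  if (variant == "homopolymer-only")
    data <- data[!data$lcr_status | data$has_homopolymer, , drop = FALSE]
  if (variant == "heteropolymer-only")
    data <- data[!data$lcr_status | !data$has_homopolymer, , drop = FALSE]
  labels <- if (variant == "disorder-label") data$disorder_status else data$lcr_status
  labels <- as.logical(labels)
  tab_values <- if (variant == "ischemia-adjusted") data$tab_adjusted else data$tab
  res <- list(tab = permutation_test(tab_values, labels, n_perm = n_perm,
                                     seed = seed, ...),
              pab = permutation_test(data$pab, labels, n_perm = n_perm,
                                     seed = seed, ...))
  do.call(rbind, lapply(names(res), function(ab) {
    r <- res[[ab]]
    data.frame(variant = variant, abundance_type = ab,
               quantile = names(r$observed),
               observed_shift = unname(r$observed), p = unname(r$p),
               direction = unname(r$direction), n_perm = r$n_perm,
               seed = if (is.null(seed)) NA_integer_ else seed,
               row.names = NULL)
  }))
}
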