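# LCR detection by windowed Shannon entropy with SEG-style two-threshold
# trigger/extend regions. Coordinates are 0-based half-open throughout.

AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' LCR detection parameters
#'
#' Parameters of the entropy-based low-complexity region detector: the
#' window length in residues, the trigger (lower complexity) bound below
#' which a window starts a region, and the extension (higher complexity)
#' bound below which neighbouring windows are absorbed into the region.
#'
#' @param window Window length in residues (default 15).
#' @param k1 Trigger entropy in bits; a window with entropy strictly below
#'   `k1` marks its protein as LCR-positive (default 1.9).
#' @param k2 Extension entropy in bits; contiguous windows with entropy
#'   below `k2` extend a triggered region (default 2.5).
#' @return An object of class `lcr_params`.
#' @examples
#' lcr_params()
#' lcr_params(window = 12, k1 = 1.8, k2 = 2.2)
#' @export
lcr_params <- function(window = 15L, k1 = 1.9, k2 = 2.5) {
  window <- as.integer(window)
  stopifnot(length(window) == 1L, window >= 2L,
            length(k1) == 1L, length(k2) == 1L,
            is.finite(k1), is.finite(k2), k1 <= k2)
  structure(list(window = window, k1 = k1, k2 = k2), class = "lcr_params")
}

#' @export
print.lcr_params <- function(x, ...) {
  cat(sprintf("LCR parameters: window = %d residues, K1 = %g bits, K2 = %g bits\n",
              x$window, x$k1, x$k2))
  invisible(x)
}

# integer codes 1..20 for standard residues, NA otherwise
.aa_codes <- function(seq) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  match(chars, AA_ALPHABET)
}

#' Sliding-window Shannon entropy of a protein sequence
#'
#' Computes, for every window start position, the Shannon entropy
#' \eqn{H = -\sum_a f_a \log_2 f_a} of the residue frequencies within the
#' window. Counts are maintained incrementally so the scan is linear in
#' sequence length.
#'
#' @param seq Character scalar, a protein sequence over the 20-letter
#'   amino-acid alphabet.
#' @param window Window length in residues.
#' @param on_nonstandard How to treat windows containing a non-standard
#'   residue (X, U, B, ...): `"skip"` returns `NA` for those windows,
#'   `"error"` aborts.
#' @return Numeric vector of length `max(0, nchar(seq) - window + 1)`, one
#'   entropy (bits) per window start; empty for sequences shorter than the
#'   window.
#' @examples
#' window_entropy(strrep("A", 15), 15)          # 0 bits
#' window_entropy("ACDEFGHIKLMNPQR", 15)        # log2(15) bits
#' @export
window_entropy <- function(seq, window = 15L,
                           on_nonstandard = c("skip", "error")) {
  on_nonstandard <- match.arg(on_nonstandard)
  stopifnot(is.character(seq), length(seq) == 1L)
  window <- as.integer(window)
  n <- nchar(seq)
  if (n < window) return(numeric(0))
  codes <- .aa_codes(seq)
  if (anyNA(codes) && on_nonstandard == "error") {
    bad <- which(is.na(codes))
    stop("non-standard residue at position(s) ",
         paste(utils::head(bad, 5L), collapse = ", "),
         " in sequence")
  }
  n_win <- n - window + 1L
  out <- numeric(n_win)
  counts <- integer(21L)           # slot 21 collects non-standard residues
  codes[is.na(codes)] <- 21L
  # running sum of c*log2(c) over occupied slots; H = log2(w) - sum/w
  xlog2x <- c(0, vapply(1:window, function(k) k * log2(k), 0))
  s <- 0
  for (i in seq_len(window)) {
    a <- codes[i]
    s <- s - xlog2x[counts[a] + 1L] + xlog2x[counts[a] + 2L]
    counts[a] <- counts[a] + 1L
  }
  out[1L] <- if (counts[21L] > 0L) NA_real_ else log2(window) - s / window
  if (n_win > 1L) {
    for (i in 2:n_win) {
      old <- codes[i - 1L]
      new <- codes[i + window - 1L]
      if (old != new) {
        s <- s - xlog2x[counts[old] + 1L] + xlog2x[counts[old]]
        counts[old] <- counts[old] - 1L
        s <- s - xlog2x[counts[new] + 1L] + xlog2x[counts[new] + 2L]
        counts[new] <- counts[new] + 1L
      }
      out[i] <- if (counts[21L] > 0L) NA_real_ else log2(window) - s / window
    }
  }
  # clamp tiny negative rounding error
  out[!is.na(out) & out < 0] <- 0
  out
}

# most frequent residue in a window, ties broken alphabetically
.window_primary_aa <- function(seq, start0, window) {
  sub <- substr(seq, start0 + 1L, start0 + window)
  tab <- table(factor(strsplit(sub, "", fixed = TRUE)[[1]], levels = AA_ALPHABET))
  names(tab)[which.max(tab)]      # which.max takes first max; levels are alphabetical
}

# longest single-residue run within [start0, end0) of seq
.max_tract <- function(seq, start0, end0) {
  sub <- substr(seq, start0 + 1L, end0)
  r <- rle(strsplit(sub, "", fixed = TRUE)[[1]])
  list(length = max(r$lengths), residue = r$values[which.max(r$lengths)])
}

#' Classify an LCR as homopolymer or heteropolymer
#'
#' An LCR counts as a homopolymer when a contiguous tract of a single amino
#' acid makes up at least half the length of the region.
#'
#' @param seq Protein sequence containing the region.
#' @param start,end Region bounds, 0-based half-open residue coordinates.
#' @return List with `is_homopolymer` (logical) and `max_tract_length`
#'   (longest single-residue run in the region).
#' @examples
#' classify_homopolymer("AAAAAAAAAA", 0, 10)  # homopolymer, tract 10
#' classify_homopolymer("ASASASASAS", 0, 10)  # heteropolymer, tract 1
#' @export
classify_homopolymer <- function(seq, start, end) {
  stopifnot(start >= 0, end > start, end <= nchar(seq))
  tract <- .max_tract(seq, start, end)
  list(is_homopolymer = tract$length >= (end - start) / 2,
       max_tract_length = tract$length)
}

#' Detect low-complexity regions in a protein sequence
#'
#' Scans the sequence with [window_entropy()]. Any window with entropy
#' strictly below the trigger bound `k1` starts a region; the region is
#' extended over all contiguous windows with entropy below the extension
#' bound `k2`, and regions whose residue spans overlap or touch are merged.
#' Windows containing non-standard residues never trigger or extend.
#'
#' @param seq Character scalar protein sequence.
#' @param params An [lcr_params()] object.
#' @return A data frame with one row per LCR: `start`, `end` (0-based
#'   half-open residue coordinates), `min_entropy` (bits, minimum over
#'   windows inside the region), `primary_aa` (most frequent residue in the
#'   minimum-entropy window, alphabetical tie-break), `is_homopolymer`, and
#'   `max_tract_length`. Zero rows when the protein has no window below
#'   `k1` (including all proteins shorter than the window).
#' @examples
#' seq <- paste0("MKVLITGAGSGIGL", strrep("Q", 20), "EVARHGGKVVLAVR")
#' detect_lcrs(seq)
#' @export
detect_lcrs <- function(seq, params = lcr_params()) {
  w <- params$window
  h <- window_entropy(seq, w)
  empty <- data.frame(start = integer(0), end = integer(0),
                      min_entropy = numeric(0), primary_aa = character(0),
                      is_homopolymer = logical(0), max_tract_length = integer(0))
  if (length(h) == 0L) return(empty)
  trig <- !is.na(h) & h < params$k1
  if (!any(trig)) return(empty)
  ext <- !is.na(h) & h < params$k2
  runs <- rle(ext)
  run_end <- cumsum(runs$lengths)
  run_start <- run_end - runs$lengths + 1L
  keep <- which(runs$values &
                  vapply(seq_along(runs$values),
                         function(i) any(trig[run_start[i]:run_end[i]]), FALSE))
  # residue spans (0-based half-open) of the kept runs
  starts <- run_start[keep] - 1L
  ends <- run_end[keep] - 1L + w
  # merge spans that overlap or are adjacent
  m_start <- starts[1]; m_end <- ends[1]
  out_start <- integer(0); out_end <- integer(0)
  if (length(starts) > 1L) {
    for (i in 2:length(starts)) {
      if (starts[i] <= m_end) {
        m_end <- max(m_end, ends[i])
      } else {
        out_start <- c(out_start, m_start); out_end <- c(out_end, m_end)
        m_start <- starts[i]; m_end <- ends[i]
      }
    }
  }
  out_start <- c(out_start, m_start); out_end <- c(out_end, m_end)

  n_lcr <- length(out_start)
  min_e <- numeric(n_lcr); prim <- character(n_lcr)
  homo <- logical(n_lcr); tract <- integer(n_lcr)
  for (i in seq_len(n_lcr)) {
    win_idx <- (out_start[i] + 1L):(out_end[i] - w + 1L)   # windows inside region
    hw <- h[win_idx]
    min_e[i] <- min(hw, na.rm = TRUE)
    best <- win_idx[which.min(hw)]
    prim[i] <- .window_primary_aa(seq, best - 1L, w)
    cls <- classify_homopolymer(seq, out_start[i], out_end[i])
    homo[i] <- cls$is_homopolymer
    tract[i] <- cls$max_tract_length
  }
  data.frame(start = out_start, end = out_end, min_entropy = min_e,
             primary_aa = prim, is_homopolymer = homo,
             max_tract_length = tract)
}

#' Most prevalent residue of a protein's lowest-entropy region
#'
#' For an LCR-positive protein, returns the most frequent residue within
#' the minimum-entropy window of its lowest-entropy LCR; ties among
#' residues break alphabetically, ties among regions go to the first
#' (left-most) region.
#'
#' @param seq Protein sequence.
#' @param lcrs Data frame of regions from [detect_lcrs()]; detected from
#'   `seq` when omitted.
#' @param params An [lcr_params()] object, used when `lcrs` is missing.
#' @return Single residue code.
#' @export
primary_low_entropy_residue <- function(seq, lcrs = NULL, params = lcr_params()) {
  if (is.null(lcrs)) lcrs <- detect_lcrs(seq, params)
  if (nrow(lcrs) == 0L)
    stop("protein has no LCR; primary low-entropy residue is undefined")
  lcrs$primary_aa[which.min(lcrs$min_entropy)]
}

#' Annotate a set of proteins with LCR status
#'
#' Runs [detect_lcrs()] over a named vector of protein sequences and
#' summarises per protein.
#'
#' @param seqs Named character vector of protein sequences.
#' @param params An [lcr_params()] object.
#' @return Data frame with columns `id`, `length`, `lcr_status`, `n_lcrs`,
#'   `min_entropy` (NA for LCR-negative proteins), `primary_aa`,
#'   `has_homopolymer` (any homopolymer LCR), `max_tract_length`.
#' @export
annotate_lcrs <- function(seqs, params = lcr_params()) {
  stopifnot(is.character(seqs), !is.null(names(seqs)))
  res <- lapply(seqs, detect_lcrs, params = params)
  n <- vapply(res, nrow, 0L)
  data.frame(
    id = names(seqs),
    length = nchar(seqs),
    lcr_status = n > 0L,
    n_lcrs = n,
    min_entropy = vapply(res, function(d)
      if (nrow(d)) min(d$min_entropy) else NA_real_, 0),
    primary_aa = vapply(res, function(d)
      if (nrow(d)) d$primary_aa[which.min(d$min_entropy)] else NA_character_, ""),
    has_homopolymer = vapply(res, function(d)
      if (nrow(d)) any(d$is_homopolymer) else FALSE, FALSE),
    max_tract_length = vapply(res, function(d)
      if (nrow(d)) max(d$max_tract_length) else NA_integer_, 0L),
    row.names = NULL
  )
}
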