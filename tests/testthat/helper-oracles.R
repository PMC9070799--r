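# Independent oracles used to cross-check the package's optimized paths.

AAS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
         "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

random_protein <- function(n) paste(sample(AAS, n, replace = TRUE),
                                    collapse = "")

# direct per-window entropy: tabulate each window from scratch
naive_window_entropy <- function(seq, window = 15L) {
  chars <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(chars)
  if (n < window) return(numeric(0))
  vapply(seq_len(n - window + 1L), function(i) {
    f <- table(chars[i:(i + window - 1L)]) / window
    -sum(f * log2(f))
  }, 0)
}

# same brute force with integer codes + tabulate, for large scans
naive_lcr_status_fast <- function(seq, window = 15L, k1 = 1.9) {
  codes <- match(strsplit(seq, "", fixed = TRUE)[[1]], AAS)
  n <- length(codes)
  if (n < window) return(FALSE)
  for (i in seq_len(n - window + 1L)) {
    f <- tabulate(codes[i:(i + window - 1L)], 20L) / window
    f <- f[f > 0]
    if (-sum(f * log2(f)) < k1) return(TRUE)
  }
  FALSE
}

# brute-force LCR status: does any 15-mer have entropy below the trigger?
naive_lcr_status <- function(seq, window = 15L, k1 = 1.9) {
  h <- naive_window_entropy(seq, window)
  length(h) > 0 && min(h) < k1
}

# full-state TWnTE simulation: every codon species updated every step,
# the translated species with its perturbability, all others with alpha 0
naive_twnte <- function(idx, S0, D, alpha_i, beta) {
  S <- S0
  eff <- numeric(length(idx))
  for (t in seq_along(idx)) {
    c <- idx[t]
    eff[t] <- S[c] / D[c]
    S_new <- beta * S0 + (1 - beta) * S          # resupply only
    S_new[c] <- beta * S0[c] + (1 - beta) * (1 - alpha_i[c]) * S[c]
    S <- pmax(S_new, 0)
  }
  list(twnte = if (any(eff <= 0)) 0 else exp(mean(log(eff))),
       step_efficiency = eff)
}

# hand-buildable codon economy for unit tests
toy_economy <- function(codons, supply, demand) {
  out <- data.frame(codon = codons, supply = supply, demand = demand)
  out$nte_codon <- out$supply / out$demand
  structure(out, class = c("codon_economy", "data.frame"))
}

# exact permutation p-values by enumerating every labelling of n_pos
exact_perm_p <- function(values, labels, log2 = TRUE) {
  obs <- quartile_shift(values, labels, log2 = log2)
  v <- if (log2) base::log2(values) else values
  combos <- utils::combn(length(v), sum(labels))
  shifts <- apply(combos, 2L, function(pos) {
    stats::quantile(v[pos], c(0.25, 0.5, 0.75), names = FALSE) -
      stats::quantile(v[-pos], c(0.25, 0.5, 0.75), names = FALSE)
  })
  p <- vapply(1:3, function(q) {
    if (obs[q] > 0) mean(shifts[q, ] >= obs[q])
    else if (obs[q] < 0) mean(shifts[q, ] <= obs[q])
    else 1
  }, 0)
  names(p) <- c("q1", "median", "q3")
  p
}
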