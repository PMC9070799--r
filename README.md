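# lcrab

Low-complexity regions (LCRs) — protein segments of biased, repetitive
composition such as poly-glutamine tracts — sit in an odd regulatory
corner: the transcripts that encode them tend to be *more* abundant than
average while the proteins themselves are *less* abundant. `lcrab` is an R
package for dissecting that disconnect. It is written for computational
biologists who want to run the full chain on their own proteome,
transcript-abundance and protein-abundance tables, or to study the
statistical machinery itself on simulated data with known ground truth.

The package implements:

* **LCR detection** by sliding-window Shannon entropy
  (window 15, trigger 1.9 bits, extension 2.5 bits), with
  homopolymer/heteropolymer classification (a single-residue tract
  covering at least half the region) and extraction of the primary
  low-entropy residue.
* **Abundance integration**: per-gene medians over tissues with nonzero
  measurement, the tau tissue-specificity index
  τ = Σᵢ(1 − xᵢ/x_max)/(N−1) ∈ [0, 1], exponential ischemia-time
  adjustment to t = 0, degradation-coefficient aggregation
  (k_deg = ln2 / t_half, geometric mean across studies), and isoform
  deduplication.
* **The codon economy and TWnTE**. Codon supply from genomic tRNA counts
  under wobble constraints, S₍ᵢ,₀₎ = Σⱼ(1−sᵢⱼ)Nᵢⱼ / max S₀; demand from
  abundance-weighted codon counts; normalized translation efficiency
  (nTE, geometric mean of supply/demand) and its **time-weighted**
  extension TWnTE, in which each elongation step depletes the translated
  codon's local supply by its perturbability αᵢ and every species relaxes
  toward global supply at resupply rate β:
  S₍ᵢ,ₜ₎ = βS₍ᵢ,₀₎ + (1−β)(1−αᵢ)S₍ᵢ,ₜ₋₁₎.
  Both the wobble constraints and (α, β) are fitted by Nelder–Mead
  against codon demand and measured translation rates respectively.
* **Quartile-shift permutation tests** (Q1/median/Q3 differences between
  LCR⁺ and LCR⁻ groups against a label-shuffling null) with the labelled
  variants — disorder labels, ischemia-adjusted TAb, homopolymer-only,
  heteropolymer-only, isoform-dedup — and a Mann–Whitney verification.
* **Logistic regression** of LCR status on log2 abundance and covariates,
  reported as standardized coefficients and as odds change per doubling,
  with per-residue stratified fits and a 25-point (α, β) sensitivity grid.
* **A synthetic proteome/transcriptome generator** producing every input
  above with known injected truth (LCR labels recoverable exactly by the
  detector, abundance effects, true translation parameters), used by the
  test suite for end-to-end validation.

## Worked example

Simulate a proteome in which LCR⁺ genes get +0.5 log2 units of transcript
abundance and −0.5 of protein abundance, then run the whole pipeline:

```r
library(lcrab)

cfg <- simulation_config(n_genes = 600, lcr_effect_tab = 0.5,
                         lcr_effect_pab = -0.5, seed = 42)
ds  <- simulate_dataset(cfg)

res <- run_pipeline(
  proteins    = setNames(ds$proteins$protein_seq, ds$proteins$id),
  cds         = setNames(ds$proteins$cds_seq, ds$proteins$id),
  tab = ds$tab, pab = ds$pab,
  trna_counts = ds$trna_counts, kdeg = ds$kdeg,
  n_perm = 10000, seed = 1)

subset(res$permutation, select = -c(seed, n_perm))
#>    variant abundance_type quantile observed_shift      p direction
#> 1 baseline            tab       q1      0.6654343 0.0000         1
#> 2 baseline            tab   median      0.7136584 0.0000         1
#> 3 baseline            tab       q3      0.6904725 0.0001         1
#> 4 baseline            pab       q1     -0.5265254 0.0002        -1
#> 5 baseline            pab   median     -0.4768637 0.0013        -1
#> 6 baseline            pab       q3     -0.7799485 0.0009        -1

res$regression
#> Logistic regression of LCR status (n = 600 complete cases)
#>  regressor coef_std  se_std odds_per_doubling pct_per_doubling   p_value
#>        pab  -0.4798 0.10386            0.7352           -26.5% 3.835e-06
#>        tab   0.4656 0.10214            1.3448           +34.5% 5.146e-06
#>       kdeg   0.1687 0.09798            1.2622           +26.2% 8.503e-02
#>      twnte   0.0980 0.09995            1.1874           +18.7% 3.269e-01
#>     length  -0.0782 0.09872            0.9195            -8.0% 4.283e-01
```

Reading the output: the observed TAb quartile shifts are positive
(LCR⁺ transcripts more abundant) and the PAb shifts negative (LCR⁺
proteins less abundant), each with empirical p-values from 10,000 label
permutations — the injected ±0.5 log2 effects, recovered with the correct
signs at every quartile. The regression tells the same story per protein
while adjusting for degradation, translation efficiency and length: a
doubling of PAb lowers the odds of carrying an LCR (−26.5%), a doubling of
TAb raises them (+34.5%), and the covariates carry no injected signal.

The detector itself is exact on this data by construction: the generator
rejection-samples LCR⁻ sequences until no 15-mer drops below 1.9 bits, so

```r
ann <- annotate_lcrs(setNames(ds$proteins$protein_seq, ds$proteins$id))
identical(ann$lcr_status, ds$proteins$lcr_true)
#> [1] TRUE
```

See the methods vignette (`vignettes/lcr-abundance-methods.Rmd`) for the
models, parameter meanings, and design decisions.

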