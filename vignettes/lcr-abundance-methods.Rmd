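---
title: "Methods: low-complexity regions, abundance, and time-weighted translation efficiency"
author: "lcrab"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: low-complexity regions, abundance, and time-weighted translation efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`lcrab` studies how low-complexity regions (LCRs) in protein sequences
relate to transcript abundance (TAb) and protein abundance (PAb) across
tissues, and whether translation dynamics can account for the relationship.
This vignette is the package's account of the underlying models, the
parameters that matter, the design choices made where the design was
genuinely open, and what the synthetic-data tests do and do not establish.

## LCR detection

A protein region is low-complexity when its residue composition is biased
and repetitive. The detector scans each protein with a sliding window of
`window = 15` residues and computes the Shannon entropy of the within-window
residue frequencies,

$$H = -\sum_a f_a \log_2 f_a ,$$

so a window of one repeated residue scores 0 bits and a window of 15
distinct residues scores $\log_2 15 \approx 3.91$ bits. A protein is
LCR-positive exactly when some window falls strictly below the trigger
entropy `k1 = 1.9` bits. Region extents use the classic two-threshold
scheme: a triggering window opens a region, which extends over all
contiguous windows below the extension entropy `k2 = 2.5` bits; regions
whose residue spans overlap or touch are merged. The defaults (15 / 1.9 /
2.5) are the parameterization long used to pick out longer, more repetitive
regions.

Two conventions are deliberate:

* **LCR status depends only on the minimum-window criterion.** The full
  compositional-probability refinement stage of classical segmentation
  tools is not reimplemented; region extents only feed homopolymer
  classification and residue extraction, for which trigger/extend/merge is
  sufficient and much easier to reason about. The brute-force property
  tests compare the status flag against an exhaustive window scan.
* **Coordinates are 0-based half-open** in every structure and output
  file.

Windows containing non-standard residues (X, U, B, ...) are skipped by
default (they can neither trigger nor extend a region); a strict mode
errors instead. Comparisons against the thresholds are strict (`<`),
matching the definition of the positive class.

An LCR is a **homopolymer** when one contiguous single-residue tract covers
at least half the region (a run of exactly half counts). The **primary
low-entropy residue** of a protein is the most frequent residue in the
minimum-entropy window of its lowest-entropy LCR, ties broken
alphabetically; it is undefined (an error) for LCR-negative proteins.

## Abundance integration

Per-tissue tables are integrated per gene as the **median over tissues with
strictly positive measurement**; genes with all-zero rows are flagged
unexpressed and excluded downstream. This exclusion rule matters because
roughly half of gene-by-tissue cells in real compendia are zero, and the
synthetic generator reproduces that sparsity (`dropout_rate = 0.5`).

Tissue breadth uses the tau index over the $N$ tissue values,

$$\tau = \frac{\sum_i (1 - x_i / x_{\max})}{N - 1} \in [0, 1],$$

0 for uniform expression and 1 for single-tissue expression. Tau is
computed on linear values by default; a `log2` option computes it on
$\log_2(x+1)$, exposing a transform the literature leaves ambiguous.

**Ischemia adjustment.** Post-mortem transcript decay is modelled as
$A e^{-kt}$ per gene and tissue; the adjusted abundance is the fitted value
at $t = 0$, obtained by ordinary least squares of log abundance on time.
The decay constant is left unconstrained in sign (a constrained fit would
silently hide compositional artefacts); fits need at least 3 positive
samples and distinct times, otherwise the unadjusted median of positive
observations is used, with a warning when the times are degenerate.

**Degradation rates** are aggregated by converting every reported value to
a first-order coefficient ($k_{deg} = \ln 2 / t_{1/2}$ for half-lives) and
taking the per-protein geometric mean across studies.

**Isoform deduplication** keeps one transcript–protein pair per gene: the
pair with the highest integrated PAb, ties broken by record id order. The
rule is this package's convention; nothing in the source analyses pins it
down.

## Codon economy and TWnTE

Translation efficiency is modelled from the supply of tRNA isoacceptors
versus the demand for each codon.

**Supply (initial conditions).** For sense codon $i$ with isoacceptors $j$,

$$S_{i,0} = \sum_j (1 - s_{i,j})\, N_{i,j} \Big/ \max S_0,$$

where $N_{i,j}$ is the genomic copy number and $s_{i,j} \in [0,1]$ the
wobble constraint of the pairing. Codon positions 1–2 must pair
Watson–Crick; position 3 pairs Watson–Crick ($s = 0$) or through one of the
four tolerated mismatches A:A, U:G, G:U, A:C
(codon base : anticodon wobble base), each with its own constraint; all
other pairings are excluded. Inosine editing of A34 is not modelled; the
annotated A is used as-is, with A:C standing where inosine:C would act.
Codons with zero raw supply are floored to half the minimum nonzero
normalized supply (configurable) so geometric means stay defined; floored
codons are recorded on the economy object.

**Demand.** $D_i$ is the TAb-weighted codon count across the
transcriptome, max-normalized for symmetry with the supply scale.

**nTE** of a transcript is the geometric mean over its codons of
$S_{i,0} / D_i$ (the stop codon is excluded).

**TWnTE** adds local dynamics. Every codon species keeps a local supply
state, initialized at $S_{i,0}$. At elongation step $t$ the translated
codon $c_t$ is scored as $S_{c_t}(t-1) / D_{c_t}$ — before that step's
update — and then

$$S_{i,t} = \beta S_{i,0} + (1 - \beta)(1 - \alpha_i) S_{i,t-1},$$

with the perturbation $\alpha_i$ applied only to the translated species and
$\alpha_i = 0$ (pure resupply) for all others. TWnTE is the geometric mean
of the per-step efficiencies. The per-codon perturbability is scaled to the
least supplied codon, $\alpha_i = \alpha\, S_{\min,0} / S_{i,0}$ (capped at
1): one elongation event consumes the same absolute amount of every
species, calibrated on the scarcest. One time step is one elongation
event; there are no physical time units.

Useful exact consequences, all asserted in the tests:

* $\alpha = 0$ or $\beta = 1$ collapses TWnTE to nTE.
* Along an uninterrupted run of one codon the per-step efficiency is
  non-increasing (repeats deplete their own supply), and
  TWnTE $\le$ nTE whenever $\alpha > 0,\ \beta < 1$.
* Repeated translation of one species converges to the fixed point
  $S^* = \beta S_0 / (1 - (1-\beta)(1-\alpha_i))$; after translation stops
  the state relaxes back to $S_0$ geometrically with factor $(1-\beta)$.

The implementation updates idle species lazily (the relaxation has the
closed form above), with the per-step loop in compiled code; a naive
simulator that updates all 61 species every step serves as the test
oracle.

Default dynamics parameters are $\alpha = 0.0578$ and $\beta = 0.00064$ —
the mouse estimates: a single step consumes 5.78% of the scarcest codon's
supply while 0.064% of the local deficit is replenished per step. With
resupply that slow, TWnTE is strongly length-dependent, which is part of
the intended signal rather than an artefact.

**Fitting.** Both calibrations use Nelder–Mead on a logit transform of the
unit box (the standard simplex optimizer in base R):

* `fit_wobble` maximizes the correlation between $S_{\cdot,0}$ and
  $D_{\cdot}$ over the four mismatch constraints, starting from
  yeast-derived estimates ($s_{A:A} = 0.9999$, $s_{U:G} = 0.68$,
  $s_{G:U} = 0.41$, $s_{A:C} = 0.28$).
* `fit_translation_params` maximizes the correlation between TWnTE and
  measured translation rates over $(\alpha, \beta)$, starting from
  $(0.5, 0.5)$.

Correlations default to Pearson on log-transformed positive values —
both quantities span decades, and log-scale Pearson is the stable choice —
with plain Pearson and Spearman available. Degenerate inputs (constant
rates, demand unrelated to supply) are reported as non-convergent or
uninformative rather than masked.

## Permutation tests

For the quartile-shift test, abundances are $\log_2$-transformed (linear
mode available), and for $q \in \{0.25, 0.5, 0.75\}$ the observed shift is
$\mathrm{quantile}_q(\mathrm{LCR}^+) - \mathrm{quantile}_q(\mathrm{LCR}^-)$
with type-7 (linear-interpolation) quantiles. Group labels are shuffled
`n_perm` times preserving group sizes; the empirical p per quantile is the
**raw proportion** $k / n$ of permuted shifts at least as extreme as
observed, one-sided in the observed direction, reported together with the
sign. A `(k+1)/(n+1)` estimator and a two-sided mode are flags.

One calibration subtlety is worth stating plainly: because the direction is
chosen from the data, the one-sided p is approximately Uniform$(0, 1/2)$
under the null — its raw rejection rate at nominal 0.05 is about 0.10 for
any implementation of this scheme. The two-sided p is the calibrated
quantity, and the null-calibration tests check exactly that pairing: the
one-sided p concentrates near mean 1/4, the two-sided p is uniform with
rejection rate within binomial error of 0.05.

Variants re-run the same machinery under alternative conditions: permuting
intrinsic-disorder labels instead of LCR status; substituting
ischemia-adjusted TAb; comparing only homopolymer (or only heteropolymer)
LCR proteins against the LCR-negative pool; and deduplicating isoforms
first. A Mann–Whitney rank-sum test (normal approximation with tie and
continuity correction) verifies the median result.

## Logistic regression

LCR status is regressed on $\log_2$-transformed regressors (PAb, TAb,
kdeg, TWnTE, protein length), complete cases only, no regularization;
possible separation is flagged, not penalized away. Two parameterizations
of the same fit are reported:

* **standardized** coefficients (unit-variance regressors) for
  cross-regressor comparison;
* **log2-scale** coefficients, whose natural exponential is the odds
  fold-change per doubling of the regressor — the reporting convention in
  which a coefficient of $\ln(1.089)$ reads as "+8.9% odds per doubling".

The two are linked by $b_{\log 2} = b_{std} / \mathrm{sd}(\log_2 x)$; the
tests assert both routes give identical per-doubling odds, and that
standardization leaves the log-likelihood and fitted probabilities
untouched.

**Per-residue effects.** The primary low-entropy residue is undefined for
LCR-negative proteins, so a single joint model with residue-by-abundance
interaction terms would need response-only indicator columns, which
degenerate. The interaction analysis is therefore fitted stratified: for
each residue level with at least 20 LCR-positive proteins (sparser levels
pooled into `"other"`), that level's LCR-positive proteins are compared
against the full LCR-negative pool. This yields exactly the per-residue
marginal PAb/TAb effects of interest.

**Sensitivity to translation parameters.** The regression is refitted over
a 5×5 evenly spaced grid of $(\alpha, \beta)$ on $[0,1]^2$ plus one fit
excluding TWnTE (26 fits), and the signs of the PAb and TAb coefficients
are summarized. At the degenerate corner $\alpha = 1, \beta = 0$ a
transcript that uses its scarcest codon twice scores a zero step
efficiency, TWnTE is 0, and the protein drops out of the log-scale
complete cases; a grid point left with too few cases is reported with NA
coefficients rather than aborting the grid.

## The synthetic-data generator

The generator produces every input the pipeline consumes, with known
ground truth, so each stage can be validated end to end without external
downloads. What it emulates, and how the free parameters were set:

* **Sequences.** Protein lengths uniform over 80–1000 residues (a
  realistic mammalian span; length variation is part of the TWnTE signal).
  LCR-negative backgrounds are drawn uniformly over the 20-letter alphabet
  and rejection-checked so *no* 15-mer falls below 1.9 bits; LCR-positive
  proteins receive an inserted low-entropy segment (single-residue tract
  with probability `homopolymer_fraction = 0.125`, else a 2–3 residue
  repeat, both with every 15-mer below the trigger), so injected labels and
  detector output agree by construction, not by chance. `lcr_fraction`
  defaults to 0.25, the order observed in human proteomes.
* **Codon usage.** One genome-wide preferred synonymous codon per amino
  acid; each gene uses its preferred codons with an intensity drawn from a
  U-shaped distribution over $[0, 0.95]$ (many weakly biased genes plus a
  strongly adapted class, as optimal-codon fractions are in vivo). tRNA
  copy numbers are drawn from a deliberately narrow band (15–25): in the
  mammalian regime codon bias is largely mutational in origin and
  decoupled from tRNA pools, so between-gene translation-efficiency
  contrast comes from biased usage concentrating demand, not from extreme
  within-family supply differences. Supply-"co-adapted" pools are exactly
  the regime in which demand cancels supply and the contrast vanishes;
  scoring such genomes is uninformative for the recovery tests.
* **Abundance.** Gene baselines are log-normal (`abundance_log_sd = 1.5`
  on the log2 scale) with unit-variance per-tissue deviations and
  independent Bernoulli dropout at 0.5 per cell. LCR effects are additive
  on the log2 scale (`lcr_effect_tab`, `lcr_effect_pab`). The default
  spread understates the full dynamic range of real abundance compendia
  (log2 SDs of ~3); it is chosen so that the package's own calibration
  studies — quartile-shift detection of half-log2 effects at $n = 2000$,
  and translation-parameter recovery under 10% rate noise — operate at a
  workable signal-to-noise ratio. Conclusions about real data must take
  the larger real spread into account.
* **Rates and decay.** Translation rates are TWnTE under the true
  $(\alpha^*, \beta^*)$ times log-normal noise (`translation_noise_sd =
  0.1`); degradation coefficients are log-normal around $2.42 \times
  10^{-2}\,h^{-1}$ (the human-compendium median); ischemia samples decay
  exponentially from each gene's per-tissue truth with per-gene constants
  from `ischemia_decay_range` (default 0–0.005 min$^{-1}$, i.e. post-mortem
  half-lives from infinite down to ~2.3 h) at 8 donors per tissue over
  0–720 min. Intrinsic-disorder labels are emulated as a copy of the LCR
  labels (the overlap is strong in real proteomes; variant machinery only
  needs a permutable second label).
* **Reproducibility.** One RNG stream per dataset, seeded from the config;
  identical configs give bit-identical datasets, and the writer serializes
  doubles at 17 significant digits so a written-then-read dataset compares
  equal.

What passing the synthetic tests does **not** show: real proteomes have
phylogenetic structure, correlated TAb/PAb noise, composition-dependent
LCR classes, inosine wobble, and far wider abundance ranges; none of these
are emulated. The generator validates the machinery, not the biology.

## Problem sizes and numerical choices

The shipped test-suite studies use: 1,000 random sequences (length
20–500) for the detector-versus-oracle scan; 100 random
economies/transcripts for the TWnTE degeneracy checks; 500 replicates of
$n = 200$ for null calibration; 500 transcripts for translation-parameter
recovery; 200 replicates of $n = 5000$ for regression CI coverage; and
$n = 2000$ genes with $10^4$ permutations for the directional
reproduction study. These sizes keep each study's Monte-Carlo error well
inside the margins being asserted while remaining desk-scale.

Numerical conventions: entropy uses an incremental count update with a
clamp at 0 for rounding; optimizers work on logit-transformed parameters
with box endpoints nudged by $10^{-6}$; quantiles are type 7; Wald 95%
intervals throughout; supply states are floored at 0; a geometric mean
with any zero factor is reported as 0.

## Known limitations

* Region extents are a convention (trigger/extend/merge), not a
  reimplementation of full SEG refinement; homopolymer classification
  therefore inherits that convention.
* The wobble model treats annotated A34 as A (no inosine), and the four
  mismatch constraints are global, not position- or family-specific.
* The ischemia fit is a two-parameter log-linear regression; it does not
  model measurement error in ischemia times.
* The stratified per-residue fits estimate marginal, not jointly adjusted,
  interaction effects.
* The generator's abundance spread is calibrated for the package's
  validation studies and is narrower than real compendia (above).
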