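---
title: "Methods: auditing single-cell somatic L1 insertion call sets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: auditing single-cell somatic L1 insertion call sets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scL1audit)
```

This vignette is the package's own account of its models and the design
choices behind them. It states no empirical result that the test suite and
the analysis drivers do not themselves compute.

## The audit model

A single-cell retrotransposon profiling experiment yields, per cell, a set
of candidate insertion calls with supporting read counts. Three
populations mix in those calls: germline known non-reference (KNR)
insertions, rare true somatic insertions, and chimeric artifacts of
whole-genome amplification and library construction. The audit treats the
KNR insertions — selected per individual by strict bulk evidence and prior
independent cataloguing — as a measurable stand-in for what a true
single-copy insertion looks like in the same cell, for three reasons it
makes explicit and testable:

* most KNR insertions in a carrier are heterozygous (single copy per
  cell): under Hardy–Weinberg at allele frequency $p$, the carrier
  heterozygosity is $2pq/(p^2+2pq)$, which exceeds 0.88 at the low $p$
  typical of polymorphic L1 insertions (`hw_heterozygosity()`);
* allelic dropout hits germline and somatic insertions alike, so dropouts
  are represented by *absence of a call row* and excluded from read-count
  histograms on both sides of the comparison;
* read counts are tallied **per (sample, locus) call** — an insertion seen
  in three cells contributes three entries — which removes recurrence
  across samples as a confounder.

### Read-count mixture

Single-cell KNR read counts are bimodal. The package models them as a
zero-truncated mixture

$$P(X=k) \;=\; w_\mathrm{low}\, p(1-p)^{k-1}
  \;+\; (1-w_\mathrm{low})\,\mathrm{ZTNB}(k;\mu,\theta), \qquad k \ge 1,$$

fit by EM on counts collapsed to (value, multiplicity) pairs. The
component families are a package decision — the data motivating them are
described only as bimodal — chosen because the truncated geometric puts
its mode at one read (amplification failure at the insertion length
scale) while the truncated negative binomial gives an overdispersed high
mode. Numerical choices:

* deterministic initialisation by a moment split at read count 3 — no
  random restarts, so fits are reproducible;
* the geometric M-step is closed-form; the negative-binomial M-step is a
  Nelder–Mead maximisation warm-started at the previous parameters and
  accepted only when it improves, making the EM a generalised EM with a
  non-decreasing log likelihood (asserted in the tests);
* convergence at relative log-likelihood change $< 10^{-8}$ or 500
  iterations;
* an identifiability guard: when the fitted high mode's mean collapses to
  within 1.2× the low mode's mean, a two-component reading is meaningless
  and the better single-component fit is returned, flagged, with a
  BIC-sized margin required before preferring the overdispersed family
  (which nests the geometric).

`estimate_true_fraction()` refits the mixture to *somatic-candidate*
counts with the high component frozen at the gold-standard fit, so the
estimated high-mode weight reads directly as "fraction of candidates drawn
from the true-insertion signal distribution"; a bootstrap over calls
supplies the confidence interval.

### Threshold choice

`threshold_table()` scans inclusive thresholds `min_reads` = 1… and
reports retained gold-call fraction, mean per-cell gold sensitivity, and
retained candidate fraction. A threshold printed as "> 2 reads" is stored
as `min_reads = 3` throughout — inclusive storage removes the
strict/inclusive ambiguity. `choose_threshold()` encodes the
diminishing-returns argument as an explicit knee rule, since no formal
objective was stated for it: raising the threshold is worthwhile while
each step buys at least `knee_ratio` (default 0.5) percentage points of
false-positive reduction per percentage point of sensitivity lost; the
chosen threshold is the first whose arriving step falls below the knee,
and a table that never retains false positives keeps the smallest
threshold. The default knee is exposed in `default_run_config()`.

### Rate estimation

Per cell: count somatic candidates at or above the threshold, remove
definite chimeras, divide by that same cell's gold-standard detection
sensitivity. Cells with zero surviving candidates contribute rate 0
without division, so they stay in group denominators; cells whose
individual has no gold set (or zero sensitivity) cannot be corrected and
are skipped with a warning rather than imputed. Reported rates are
rounded half-up to two decimals (`round_half_up()`), matching the
precision at which such rates are conventionally printed; computations
keep full precision. Group comparison uses classic one-way ANOVA on
per-cell rates, with a Kruskal–Wallis p-value reported alongside but not
used as the default.

The chimera adjustment `pre_rate × (1 − n_chimeras/n_candidates)` is kept
as a separate primitive because it acts on published summary statistics
as well as on simulated cohorts. A known arithmetic curiosity: applying
the analogous adjustment with a 12/20 chimera fraction to a rate of 2.4
gives 0.96, not the 1.1 printed alongside those inputs in the source
material; the package reproduces only the 0.38→0.15 and 0.44→0.18 cases,
which are self-consistent.

### Gold-standard selection rules

Three method-specific selectors, all with inclusive inequalities exactly
as printed, per-locus audit logs, and clause-by-clause brute-force oracles
in the tests: capture-based (≥ 40 reads in both bulks + prior independent
study, with capture-only priors admitted only on request), WGS (≥ 2
anchored mate reads each side, ≥ 4 clipped reads, TSD/deletion ≤ 50 bp
without poly-A or ≤ 250 bp with, at least half of clipped reads within
± 2 bp of the breakpoint, prior study — all in both bulks), and PCR-based
(score ≥ 0.5 in at least half the bulks, ceiling at odd counts — the
conservative reading of "at least half"). An individual without exactly
two bulk samples is an error for the two-bulk rules; the package does not
guess a degraded rule.

### Chimera rules

The rule engine makes the manual sequence-curation criteria explicit.
Definite rules (R1 inactive source subfamily, R2 missing poly-A at a 3'
junction, R3 distinct 5'/3' sources) convict; junctions arising inside an
L1 body or poly-A tract (R4) are indeterminate by construction because
sequence analysis cannot distinguish them from true breakpoints; the
oversized-TSD flag (F1, default 50 bp, configurable) never convicts on
its own but blocks the "consistent with a true insertion" verdict.
Subfamily activity is an input annotation (a small lookup fixture ships
with the package); no sequence-level ORF analysis is attempted.

## The synthetic cohort

`simulation_config()` defaults define the study conditions the audit runs
under, chosen once to match the statistical structure the analysis
assumes: 3 individuals × 57 cells (~170 cells); 140 KNR insertions per
individual; per-cell per-locus dropout 0.55 (so sensitivity at a 1-read
threshold averages ~45%); mixture weights 2/3 low / 1/3 high with a
low-mode mean of 2.2 reads and a high mode at NB(μ=20, θ=2); true somatic
insertions Poisson(0.2)/cell subject to the same dropout and read-count
law as germline single-copy insertions; chimeras Poisson(28)/cell with
zero-truncated-geometric counts at success probability 0.935, placing
93.5% of chimeras at one read and 99.6% at ≤ 2 reads; bulk KNR counts
NB(μ=150, θ=5) in two bulks per individual. Junction status is sampled
per class (true calls reach both junctions with probability 0.6, chimeras
0.02 — a chimera is a single spurious junction). One global seed feeds
named substreams (loci, cells, somatic, chimera, depths), so adding a
stream never perturbs the others and equal config+seed gives
byte-identical tables.

What the simulator does *not* emulate — and hence what green tests do not
show about real data: sequence content, mappability structure, clonal
somatic insertions shared across cells, locus-specific capture
efficiency, or correlated dropout between neighbouring loci. The coverage
simulator likewise reduces MALBAC to a fixed-phase ~1 kb cosine with
multiplicative log-normal cell noise and MDA to a smoothed Gaussian
log-field (length scale 300 kb) over Poisson sampling; these reproduce
the *spectral ordering* of the two chemistries (fine-scale power above
3.5×10⁻⁵ /bp higher for MALBAC-like, coarse-scale higher for MDA-like)
and the survival of systematic peaks under pooling, not any particular
genome's profile.

## Coverage QC choices

Equal-read bins are computed once on a designated reference (target 500
kb expected span), snapped to source-bin edges, then frozen for all
compared samples. Log2 ratios use a pseudocount of one read-equivalent
per bin, are centred to autosomal median 0, and support two sex
corrections: re-centring chrX to the sample's own chrX median and zeroing
chrY (for female samples normalised against a male reference). MAPD is
the median absolute difference over genomically adjacent same-contig bin
pairs — "pairwise" in its standard consecutive-bin usage — and never
spans contig boundaries; both MAPD and MDAD are shift-invariant, which
the tests assert. The PSD is a Welch averaged periodogram (periodic Hann
window, 50% overlap, default segment 2¹⁴ bins, all exposed as arguments
since no estimator parameters were inherited), normalised so the
one-sided power sums to the track variance (Parseval, checked to 1%).
Subsampling is per-bin binomial thinning; a keep-fraction of 1 returns
the input unchanged.

## Problem sizes

The test suite and drivers run at sizes chosen to make the statistical
assertions sharp while staying quick on a laptop: cohorts of 120–200
cells (and the 171-cell default) for estimator recovery; n = 4,000 counts
and 20 seeds for mixture-weight recovery (±0.05); 100 seeds of pure
chimera draws for the "< 0.5% true fraction" property; 2¹⁴–2¹⁶-bin tracks
for the spectral checks; 10⁴-point random grids for the detection-theory
algebra; and 1,000+ random small instances against brute-force oracles
for MAPD, MDAD, Gini, TSD size and the three gold-standard selectors.

## Known limitations

* The mixture component families and the knee rule are explicit stand-ins
  for procedures that were described only qualitatively; both are
  parameterised and overridable.
* Corrected rates divide by an *estimated* per-cell sensitivity; with
  ~140 gold loci per individual the resulting ratio bias is second-order
  (≈ +2% at sensitivity 0.24) and sits inside the Monte-Carlo tolerance
  of the recovery tests, but it is a real small-sample effect.
* The recurrent 5'-junction chimera class is represented in the simulator
  only through the junction-side mix of chimeras; no dedicated rule
  targets it, because no mechanistic signature was specified.
* Real-data headline percentages (97%, 99.6%, 53%, 24%, MAPD score
  tables, group means) require datasets available only on request or
  from archives; the package's claims about them are structural —
  reproduced in distribution shape on synthetic cohorts — not numeric.
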