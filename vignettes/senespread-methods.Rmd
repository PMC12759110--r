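---
title: "senespread: methods, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{senespread: methods, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(senespread)
```

# The problem

Replicatively senescent cells rewire their chromatin: marks of active
transcription such as H3K79me³ redistribute from promoter-proximal
enrichment into gene bodies, preferentially on long genes, while the
promoter mark H4R3me²ˢ is lost at the genes that become induced. The
induced gene set itself is biased toward long genes. `senespread` turns
coverage tracks and gene models into the quantities these statements are
made of: window densities, metagene profiles, pausing indices, fold
changes, gene-set calls, and overlap statistics. This vignette documents
the models, units, defaults and the places where the design was genuinely
open.

# Coordinates and the coverage model

All coordinates are 0-based half-open (`[start, end)`, BED convention);
GTF input (1-based closed) is converted on read. The TSS of a `+` strand
gene is `start`; of a `-` strand gene it is `end`, i.e. the first
transcribed base is `end - 1`. Windows are specified in transcribed
orientation (negative = upstream) and mirrored for `-` strand genes;
windows extending past position 0 are clipped, never errors.

A coverage track stores, per chromosome, sorted disjoint
`(start, end, value)` segments — overlapping input intervals are merged
by summation, which tolerates replicate-pooled bedGraphs — plus a
precomputed cumulative integral `S(x)` = signal in `[0, x)`. Because the
per-base signal is piecewise constant, `S` is piecewise linear and may be
evaluated at *fractional* positions; any bin sum is `S(b) - S(a)`. This
is what makes the package's bin apportionment exact: when a gene body is
split into 100 equal bins its bin boundaries are generally fractional,
and a base overlapping two bins contributes to each in proportion to the
overlap, with no rounding. The unit tests compare this path against a
literal per-base summation oracle on randomized tracks and require exact
equality (fixtures use integer tag values so both summation orders are
exact in double arithmetic).

# Normalization

Densities are reported as **tags per kb per 10 million library tags**:

$$d = \frac{\text{raw tags}}{w/1000 \cdot L/10^7}$$

with window width $w$ (after clipping) and library size $L$ (supplied, or
defaulting to the track's total signal). Published figures say
"normalized tag density" without units; fixing one documented unit makes
tracks comparable and gives the two invariants the tests enforce:
densities scale linearly with signal and inversely with library size.
Ratios (pausing indices, spreading ratios) are normalization-free.

# Key operations and their defaults

**Metagene profiles** (`metagene_profile`): 100 body bins, 2 kb flanks in
20 bins each. The originating figures state no bin counts; these defaults
are a documented choice, and all shape claims in the acceptance suite are
bin-index-level (maximum position, mean over bin ranges), not bin-exact.
Genes shorter than `n_body_bins` bases are excluded and counted, never
silently dropped.

**Pausing index** (`pausing_index`): promoter window TSS −50..+300,
body from TSS +300 to the TES. The exact windows used in the original
analyses are in an unavailable methods appendix; these defaults follow
common nascent-transcription practice and every window is configuration.
PI is a ratio of densities from one track, hence invariant to library
scaling; records are invalid (with a reason) when the gene is shorter
than `body_from + 100` bp or the body density is zero.

**Fold changes and classification** (`fold_change_table`,
`classify_regulation`): `log2fc = log2(((n_b + pc)/N_b)/((n_a + pc)/N_a))`
with pseudocount 1; the combined value is the arithmetic mean of the RNA
and GRO log₂ fold changes when both exist, RNA alone otherwise.
Thresholds default to ±1 log₂ units — the repeated "< −1" / "> 1" filter
convention of the source analyses; the original upstream gene-set
definition lives in a prior publication and is deliberately not asserted
here, only exposed as configuration. Sign concordance between RNA and GRO
is required by default (a zero is compatible with either sign).
"Expressed" means mean normalized exonic density across conditions
≥ 0.5 tags/kb/10M — the sources say "expressed" without a threshold, so
it is configurable.

**Mark dynamics** (`mark_change`, `select_by_mark_change`,
`spreading_summary`): mark log₂ fold changes add a pseudocount of 0.5
tags/kb/10M on *normalized densities* (zero-signal promoters make one
mandatory; none is stated in the sources). The fold change is computed as
a difference of logs, which makes condition-swap antisymmetry exact in
floating point — an invariant the tests check with `identical()`.
Selection thresholds are strict inequalities, reading "< −2.5" literally;
a record exactly at the threshold belongs to neither side. The spreading
scalar (body/promoter ratio per condition, Δ = difference of log₂ ratios)
is this package's own summary of the spreading phenomenon; it shares the
pausing promoter window by default so one promoter definition serves a
run.

**Association of mark change with expression change**
(`mark_expression_association`): genes are binned on mark log₂ fold
change and each bin's expression fold-change distribution is compared to
a reference by a two-tailed z-test. Whether such comparisons should use
the full (overlapping) gene population or the disjoint complement is
ambiguous in the sources; both are supported via `reference = "all"`
(default — matches the all-genes reference curves, and makes a bin equal
to the whole input give z = 0 exactly) and `reference = "complement"`
(disjoint groups, for which the z-test null is calibrated — the
permutation-uniformity test uses this mode, because subset-vs-superset
z-tests are provably non-uniform under the null). The mode used is
recorded in the result. Bins with fewer than 3 genes are flagged and not
tested.

# Statistical toolkit

* **z-test**: Welch-style two-sample on the fold-change vectors
  (`z = (\bar x - \bar y)/\sqrt{s_x^2/n_x + s_y^2/n_y}`), two-tailed
  normal p. The sources say only "two-tailed z-tests"; the Welch form
  avoids an equal-variance assumption the data do not justify. Zero
  variance with equal means gives z = 0, p = 1; with unequal means, p = 0
  flagged degenerate.
* **Mann–Whitney U**: midranks; exact two-sided p (twice the smaller
  tail, capped at 1) when `n_x + n_y <= 16` with no ties, otherwise a
  normal approximation with tie-corrected variance, continuity
  correction, and an Edgeworth fourth-cumulant term. The plain normal
  approximation disagrees with the exact path by up to 0.011 right at the
  exact-path boundary (n = 8+8, U = 24); the Edgeworth term (exact
  κ₄ = −mn(N+1)(m²+n²+mn+N)/120 for the tie-free null) brings that to
  ~6×10⁻⁴ and improves the approximation generally. With ties the
  tie-free κ₄ is used as an approximation.
* **Fisher's exact test**: two-sided p by the minimum-likelihood rule
  (sum of all fixed-margin tables whose point probability is at most the
  observed, with a 1+10⁻⁷ relative guard), the standard exact two-sided
  convention; sample odds ratio (ad)/(bc) with ∞ for empty off-diagonal;
  Jaccard = a/(a+b+c) (defined as 1 when both sets are empty). The tests
  verify equality against full table enumeration for every 2×2 table with
  total ≤ 40.
* **Box-plot summaries**: type-7 (linear-interpolation) quartiles,
  whiskers at the most extreme observations within 1.5·IQR — box-plot
  conventions vary, so the rule is fixed and documented.

# The synthetic world

The generator states one world and the acceptance suite measures whether
the pipeline recovers it. Per `synthetic_config()` defaults:

* 2000 genes on one synthetic chromosome with ≥ 10 kb intergenic gaps
  (keeps window clipping and overlap edge cases testable without a real
  assembly); random strands; a handful of evenly spaced exons covering
  ~40% of each body.
* Gene lengths log-normal, `meanlog = log(20000)`, `sdlog = 1` — median
  20 kb with a realistic long tail, matching expressed human
  protein-coding genes at the resolution that matters here.
* 10% of genes planted GAINED and 10% LOST, with ±2 log₂ units of
  expression effect; GAINED lengths multiplied by 3 (the reported
  upregulated sets are markedly longer; the acceptance suite's
  length-bias criterion uses exactly this factor).
* Expression counts: baseline mean ∝ (exonic or body) length × a shared
  log-normal per-gene level (so RNA and GRO are sign-concordant);
  condition-1 means normalized to 10⁶ expected tags; condition-2 means
  are the condition-1 means × 2^(±effect) — *not* renormalized. A naive
  renormalization of condition 2 induces composition bias (the induced
  long genes absorb ~0.8 log₂ units of everyone else's library share) and
  contradicts the generator's contract that condition-2 *means* are
  scaled by the planted effect; instead the condition-2 library is simply
  larger, as in a spike-in-normalized experiment, and fold changes in the
  pipeline use the configured depth as the library size for both
  conditions. Noise is Poisson by default; negative binomial
  (var = μ + φμ²) is opt-in.
* Mark tracks: expected per-base signal = Gaussian TSS peak (amplitude ×
  exp(−(x−TSS)²/2σ²), strand-anchored) + uniform body level ×
  (1 + spread_coefficient · log₁₀ length); discretized into 50 bp bins
  (Gaussian mass via the normal CDF, body mass by exact overlap),
  globally rescaled to 10⁶ expected tags, Poisson-sampled per bin.
  Values are stored as per-base densities so window integrals equal tag
  counts.

**Mark-shape defaults and why.** H3K79me³: EPQ amplitude 60, σ = 150 bp,
body level 0.1, no spreading; SEN identical but spread_coefficient 1.0
per log₁₀ bp. Two constraints pin this down. First, both condition
tracks are normalized to the same depth, so a genuine body gain is only
visible in normalized densities if the EPQ track hides most of its mass
*outside* gene bodies — i.e. in the promoter-proximal peak. That is the
stated EPQ biology (promoter-proximal enrichment that later spreads), and
it quantitatively requires peak mass a few-fold the body mass; a gentle
5–10× per-base peak would put > 80% of the mark in bodies and
equal-depth normalization would cancel the planted spreading almost
exactly (measured ratio ≈ 0.97). Second, σ must be small relative to the
shortest genes: the peak of a gene shorter than ~15σ bleeds past the
first fifth of its own body, inflating both conditions' body bins and
diluting the across-gene mean ratio. σ = 150 bp confines that to the rare
< 2 kb genes. With these defaults the planted spreading corresponds to a
~2.4–2.9× (seed-dependent) gain in mean normalized body density beyond
the first body quintile — the ≥ 2-fold magnitude of the published
metagene pattern. H4R3me²ˢ keeps the narrower 250 bp peak (amplitude 10,
body 0.1); it carries the promoter-loss coupling instead: −5 log₂ units
applied to the promoter amplitude of GAINED genes in the senescent
condition, and only to this configured `coupled_mark` — coupling the
spreading mark as well would conflate the two planted effects.

**Determinism.** One master seed; every output (gene set, each count
table, each mark × condition track) draws from a child seed obtained by a
stable string hash of (seed, label), so adding a track never perturbs an
existing one. Generator calls save and restore the caller's RNG state.
Byte-identical reruns of the full pipeline are an acceptance criterion.

**What the generator does not emulate** — and hence what a green test
does not establish: replicate-level variance structure (a single pooled
track per condition; no dispersion shrinkage), mappability and GC
artifacts, input/IgG background, peak-called intervals, isoform
structure, inter-chromosomal effects, and any causal biology (the
coupling between promoter mark loss and induction is planted jointly, not
mechanistically). Recovery on this world validates the arithmetic and the
inference conventions, not the original biological claims.

# Pipeline

`run_pipeline()` executes simulate → quantify → classify → pause →
markshift → stats from one validated config (YAML or R list;
`validate_config()` returns all problems at once rather than raising on
the first). All tables are written with deterministic row and column
order; the manifest records the config echo, package version, per-file
MD5 hashes and exclusion counts (short genes, invalid pausing records,
zero-promoter spreading drops), each of which is also logged as one line
in `run.log`. On synthetic data the `pause` stage runs on the spreading
mark's two condition tracks, since the generator emits count tables
rather than a dedicated nascent-coverage track.

# Known limitations

* BED12 carries no biotype, so biotype filtering is only effective on GTF
  input; BED round-trips drop the biotype field.
* The Mann–Whitney exact path is limited to `n_x + n_y <= 16`; beyond
  that the Edgeworth-corrected approximation is used even for tie-free
  data.
* `mark_expression_association` with the default overlapping reference
  yields conservative p-values for large bins (the bin is part of its own
  reference); use `reference = "complement"` when calibrated type-I error
  matters.
* The generator's single chromosome means chromosome-level confounders
  (e.g. copy-number differences between conditions) are out of scope.
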