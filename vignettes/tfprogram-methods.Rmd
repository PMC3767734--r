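---
title: "Methods: models, conventions and design choices in tfprogram"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, conventions and design choices in tfprogram}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tfprogram)
```

This vignette is the package's own account of the science it implements: the
statistical model behind each stage, the parameters that matter and why their
defaults are what they are, what the synthetic-data generators do and do not
emulate, and the numerical conventions adopted where the field's descriptions
leave room.

## The analysis chain

The package operationalizes a common integrative design in regulatory
genomics: a transcription factor (the motivating case is HNF1B, a homeodomain
factor marking clear-cell carcinomas) is connected to a downstream program by
(i) predicting candidate targets from promoter binding sites, (ii) validating
the candidate set against an induction experiment by gene set enrichment,
(iii) characterizing the validated ("leading edge") genes by
over-representation in curated collections, (iv) tying the factor's own locus
to its epigenetic state by bisulfite methylation analysis, (v) verifying
selected targets by relative qPCR, and (vi) testing whether the marker
predicts a clinical event with exact 2x2 statistics. Each stage is an
ordinary function with files in standard formats on both sides, so real data
can replace synthetic data stage by stage.

## Motif scanning and target prediction

Binding sites are expressed as IUPAC consensus strings (e.g.
`WRGTTAATNATTAACNNN` for the HNF1 site; `W` = A/T, `R` = A/G, `N` = any).
A consensus is a deliberately coarse model — a position-weight matrix with a
log-odds threshold would grade mismatches — but it is deterministic,
transparent, and the form in which such sites are usually published.
Conventions:

* Coordinates are 0-based; the scan window is a half-open interval relative
  to the TSS on the transcribed strand, default `[-2000, +2000)`. A gene is a
  predicted target iff at least one occurrence lies with its *full extent*
  inside the window, which makes predictions independent of sequence outside
  the window (a tested invariant).
* Both strands are scanned by default. The 13 bp core `GTTAATNATTAAC` is its
  own reverse complement but the full 18-mer is not, so strandedness matters;
  hits identical in (gene, start, extent) are reported once.
* An `N` in the *subject* matches only the pattern code `N`, never `A/C/G/T`
  classes: an unknown base is not evidence for a site.
* The expected background hit rate on i.i.d. uniform sequence has the closed
  form `(L - w + 1) * prod(|class_i|/4)` per strand
  (`expected_background_hits()`), which the test suite verifies by Monte
  Carlo with a short motif; the 18-mer's own rate (~1.5e-8 per position) is
  too small to measure directly at test scale.

## The enrichment engine

Ranking uses the signal-to-noise metric
`(mean_A - mean_B) / (sd_A' + sd_B')`, with each class standard deviation
floored at `0.2 |mean|` (and at 0.2 when that floor is zero). The floor keeps
low-variance genes from dominating the ranking on small designs; below three
samples per class the metric is flagged as unstable with a warning. Ties in
score are broken by gene id, ascending — an arbitrary but documented and
stable choice.

The enrichment score walks the ranked list: set members add
`|score|^p / N_R` (with `N_R` the sum of in-set `|score|^p`), non-members
subtract `1/(N - k)`. The running sum telescopes to zero; the ES is the
deviation of maximal magnitude with its sign, bounded in `[-1, 1]`. The
weight exponent defaults to `p = 1`; `p = 0` gives the unweighted
Kolmogorov–Smirnov form, exposed because its scores are exactly rational and
therefore ideal for oracle tests. Two degenerate conventions: if every
in-set weight is zero (all-zero scores at `p > 0`), hit increments fall back
to the uniform `1/k`; on an exact tie between the positive and negative
extremes the positive one is reported (a tolerance of 1e-12 absorbs float
noise — genuine gaps are at least `1/(k(N-k))` at `p = 0`).

Two permutation nulls are provided. *Gene-set* permutation draws uniform
random same-size subsets of the ranked universe — the appropriate null when
there are too few samples to permute labels, as in a two-arm induction
experiment. *Phenotype* permutation reshuffles class labels and recomputes
the metric per permutation; when the number of distinct assignments is at
most `n_perm` they are enumerated exhaustively (an exact test), otherwise
distinct assignments are sampled without replacement. Nominal p-values use
the plus-one convention within the same-sign null subsample:
`p = (#{|ES_null| >= |ES|, same sign} + 1) / (n_same_sign + 1)`, which can
never return zero at finite permutations. The default `n_perm` is 1000 in
`run_gsea()` (999 in the pipeline, giving p-resolution 1/1000 after the
plus-one correction).

NES divides each ES by the mean magnitude of its same-sign nulls; the FDR q
for a set is the ratio of the same-sign normalized-null tail fraction to the
observed tail fraction at its |NES|, clipped to `[0, 1]` and then made
monotone non-increasing in |NES| within each sign class (a set inherits the
smallest estimate among thresholds that include it). Sets with no same-sign
nulls get `NA` with a warning rather than an invented value.

The leading edge of a positively enriched set is its members at ranks at or
before the running-sum peak; for negative ES, at or after.

## Over-representation

Overlaps between a query list and each curated set are tested with the exact
hypergeometric upper tail `P(X >= k)` on an explicit universe. The universe
is a *required* argument: public databases use their own gene universes, and
the choice moves every p-value, so the package refuses to guess. FDR control
is Benjamini–Hochberg — the deterministic, testable convention when a report
says "false discovery rate" without naming a method. The default report
filters (nominal p < 0.01, q < 0.25, top 10) follow the common practice for
such tables and are overridable.

## Bisulfite methylation

The model is top-strand bisulfite PCR: unmethylated cytosine reads as
thymine, methylated CpG cytosine is protected, all non-CpG cytosines convert.
The bottom strand is out of scope. Primer validation enforces the design rule
for methylation-independent amplification: each primer must match at exactly
one, identical position on both the fully-methylated and fully-unmethylated
converted templates — which requires a Y (or R on the bottom strand) wherever
a primer crosses a CpG.

Calling is ungapped: a read must be exactly the scored region (indels are an
upstream trace-processing concern). At each CpG cytosine, C calls
methylated, T unmethylated, and the ambiguity code Y calls *partial* — the
direct-PCR Sanger signature of a mixed template population (hemizygous
methylation, tumor heterogeneity, stromal contamination). Partial sites count
as presence of methylation in the per-sample fraction, matching the binary
filled/empty convention of amplicon summaries. Every non-CpG reference
cytosine must read T; residual Cs are conversion failures, and a rate above
1% (default) rejects the read, as does any mismatch at a non-cytosine
position.

The bundled `synthetic_hnf1b_amplicon()` is a *synthetic* reference: it
reproduces the published degenerate primer pair
(`GGGGTYGAGTTYGATATTAAGT` / `TACCTAAACATCCRATCCACCT`), the 191 bp amplicon
length, and 16 scorable CpG sites, but its interior sequence is a
deterministic construction, not the genomic sequence. The published numbers
also contain a small arithmetic tension — 191 bp minus two 22-mer primers is
147 bp, though the interior is described as 148 bp — so the interior length
is a parameter (default 147) rather than a constant. Group comparison of
per-sample fractions uses the equal-variance two-sample t-test, with fixed
conventions for the degenerate cases: identical zero-variance groups give
p = 1; complete separation with zero variance gives the smallest
representable p with a `separated` flag rather than a bare zero.

## qPCR quantification

The delta-delta-Ct model assumes amplification efficiency 2.0 (TaqMan assays
without standard curves):
`log2 level = -[(Ct_t,s - Ct_ref,s) - (Ct_t,r - Ct_ref,r)]`, so the reference
sample sits at 0 for every gene and any constant shift of a sample's Cts
cancels (both are tested identities). Undetected targets are imputed to the
smallest detectable level observed *for that gene* — per-gene rather than
per-run, since detection limits are assay-specific — and carry an `imputed`
flag so comparisons can be rerun without them.

Group comparison uses the Mann–Whitney U test. For `nA + nB <= 13` the
two-sided p is exact by enumeration of all label assignments, with mid-rank
tie handling inherited from the U statistic itself
(`p = P(|U - nAnB/2| >= |U_obs - nAnB/2|)`); the threshold 13 is chosen so a
6-versus-7 design — the canonical small qPCR contrast here — is tested
exactly. Above the threshold a tie-corrected normal approximation with
continuity correction is used, and the mode is recorded in the output.

## 2x2 association

The two-sided Fisher exact test follows the minimum-likelihood convention:
with margins fixed, it sums the hypergeometric probabilities of all tables no
more probable than the observed one, with a relative tolerance of 1e-7
guarding floating-point ties — the convention of the dominant statistical
software, hence the one most likely to reproduce published p-values. Risk is
reported as *relative risk* (ratio of event proportions, marker-positive over
marker-negative), not an odds ratio, because published "x-fold" statements
about event rates are proportion ratios. A zero event count in the
marker-negative group leaves the ratio undefined and flagged; no continuity
correction is invented. Table orientation is fixed (marker rows, event
columns) to preclude transposition bugs, and pooling cohorts is a cellwise
sum.

## The synthetic-data module

The generators define the study conditions the package is tested under:

* **Expression** (`gen_expression`): background log2 values are
  Normal(0, `noise_sd` = 1); a planted set of 50 genes among 5000 is shifted
  by +2 in the "induced" class of a 10 + 10 design. This emulates the shape
  of a two-class induction experiment with a strong but noisy signature —
  effect two noise-SDs is large per gene but realistic for direct targets.
* **Promoters** (`gen_promoters`): 4 kb promoters with the TSS at the
  midpoint, i.i.d. background (uniform by default, GC-biasable) *regenerated
  until motif-free on both strands*, so the planted genes are by construction
  exactly the genes containing the motif; each planted gene gets one uniform
  instantiation of the consensus at a uniform offset, recorded in a truth
  table.
* **Bisulfite** (`gen_bisulfite_samples`): each CpG methylated independently
  with its group's probability; defaults 0.9 versus 0.05 for 4 + 4 samples,
  emulating a heavily methylated versus essentially unmethylated contrast
  with minor contamination.
* **Ct tables** (`gen_ct_table`): reference gene at Ct ~ Normal(20, 0.2),
  targets at a baseline delta-Ct of 8 cycles with measurement noise 0.5 and a
  group shift of -3 cycles (higher expression) in the first group of a
  6-versus-7 design; values above Ct 35 become the `ND` sentinel.
* **Cohorts** (`gen_cohort`): marker ~ Bernoulli(0.55), event risk 0.18
  baseline versus 0.54 for marker-positive (risk ratio 3), cohort size 38 —
  the shape of a small observational marker/event cohort.

One master seed drives everything; each generator derives its own substream
seed as `(64 * seed + k) mod (2^31 - 1)` with a fixed `k` per generator, so
adding or reordering generator calls never perturbs another generator's
draws, and every generator is byte-reproducible (tested).

What the generators deliberately do **not** emulate: microarray probe
effects, batch effects, correlated genes, copy-number structure, bisulfite
sequencing errors or indels, PCR efficiency drift, or confounding in the
cohorts. Passing tests therefore demonstrate correctness of the statistical
machinery under its stated model, not robustness to the artefacts of real
data.

## Problem sizes and test design

The suite's heavier checks run at sizes chosen to balance statistical
resolution against a comfortable single-CPU run: enrichment-score oracle
equivalence on 200 random lists of up to 12 genes (where `p = 0` arithmetic
is exactly rational); null-calibration of permutation p-values over 200 seeds
with 199 permutations each (Kolmogorov–Smirnov at alpha 0.01);
planted-enrichment detection over 100 seeds at 5000 genes and 999
permutations; the hypergeometric tail verified against full enumeration on
*every* instance with universe size up to 30; Fisher's test against an
independent log-factorial enumeration on random tables with totals up to 60,
and against `stats::fisher.test` as a second route. Permutation nulls for
gene-set mode use a closed-form evaluation of the running-sum extrema from
sorted hit positions (`O(k)` per permutation instead of `O(N)`), which is
tested for exact agreement with the full running sum.

## Known limitations

* The consensus scan does not score near-matches; a user-supplied PWM mode
  would be the natural extension.
* Phenotype permutation recomputes the full ranking per permutation and is
  therefore the slow path; it is intended for small designs, where it is
  exact anyway.
* The methylation model is top-strand only and assumes reads are already
  trimmed to the amplicon's scored region.
* FDR estimates from permutation nulls are noisy at small `n_perm`; the
  pipeline default of 999 is a floor, not a recommendation, for final
  analyses.
* Real-data adapters (e.g. for public microarray repositories) are out of
  scope; the package consumes the standard file formats instead.
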