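---
title: "Methods and design notes for dendtrans"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for dendtrans}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dendtrans)
```

# The problem

Neurons translate mRNAs locally in dendrites, and synaptic activity changes
which messages are translated. Proximity labeling with a promiscuous biotin
ligase (TurboID) fused to postsynaptic-density elements (TurboID-PSD95),
against an untargeted Pan-TurboID control, makes the dendritic compartment
experimentally addressable across three molecular layers:

* **PL-CLIP** — which RNAs are crosslinked to the biotinylated dendritic
  proteome (compartment enrichment of transcripts);
* **PL-Ribo-seq** — where ribosomes sit on those RNAs, region-resolved
  (5'UTR vs CDS), before and after KCl depolarization;
* **PL-MS** — which proteins the biotin ligase reaches (the dendritic
  proteome), with a minus-biotin control per sample.

The scientific signal of interest is *translational*: transcripts whose
ribosome occupancy in the 5'UTR (upstream open reading frames, uORFs)
rises with depolarization, coupled to either increased or decreased
downstream CDS translation, without a change in transcript abundance —
and the association of those classes with 5'UTR binding of the
non-canonical initiation factor eIF4G2 (motif CGCGGC). `dendtrans`
implements the statistical backbone of this analysis as a tested,
reusable pipeline, plus a synthetic-data generator with a truth table so
every stage can be validated without the original raw data.

# Models and procedures

## PL-CLIP: nested contrasts on log-cpm

Pulldown samples are grouped by condition × bait; the per-gene linear
model on `log2((count + 0.5)/(lib + 1) * 1e6)` includes group and
fixed-effect replicate (batch) indicators. Three contrasts are estimated:
PSD95 − Pan within resting and depolarized conditions, and their
difference (Dep.PSD95 − Dep.Pan) − (Rest.PSD95 − Rest.Pan). Localization
calls use raw t-statistic thresholds, strict: t > 1 within a condition,
t > 1.25 for the differential.

**Deviation, by design**: the precision-weighting and sample-quality
weighting machinery of limma-style pipelines is *not* reproduced. We fit
unweighted OLS with optional fixed-prior-df variance moderation
(`prior_df = 4`, shrinking residual variances toward their grand mean,
adding the prior df to the t reference). The inference design (nested
contrasts, BH correction, t-threshold calls) is the contract; acceptance
is planted-effect recovery, not numerical replication of a third-party
implementation. The `flag` column records whether moderated or ordinary t
was used, because the printed t thresholds do not say which statistic
they were applied to. Calibration checks (null tail mass vs the
t distribution at the design's residual df) use ordinary t.

## PL-Ribo-seq: region-level occupancy and the z procedure

Footprint P-sites are read 3' ends minus 12 nt; a P-site in
`[0, utr5_len)` counts to the 5'UTR, `[utr5_len, utr5_len + cds_len)` to
the CDS, and anything further 3' is discarded (reads are conserved:
utr5 + cds + discarded = input). Region counts become RPKM, then quantile
normalization equalizes the per-sample distributions (ties get the mean
of the reference values their ranks span).

Dendritic translation per condition is
`log2(mean PSD95-pulldown RPKM + 0.1) − log2(mean input RPKM + 0.1)`; the
pseudocount 0.1 (the same constant as the CLIP stage, chosen once for
consistency) resolves zeros, and "inputs" means all input libraries of
the condition, both baits, averaged per sample before the log.

Significance comes from three routes:

1. **NB-GLM LRT** within a condition: per transcript, null =
   intercept-only, alternative adds a PSD95-pulldown indicator; offset
   `log(lib_size)`; dispersion by method of moments, floored at 1e-8,
   shared between the fits (a documented desk-scale deviation from
   empirical-Bayes tagwise dispersion); LRT vs chi-squared(1); only
   transcripts with basemean > 1. With the dispersion at its floor the
   statistic agrees with a Poisson-deviance oracle to 1e-3 and the null
   p-values are approximately uniform; with the method-of-moments
   plug-in they are close to, but not exactly, uniform (plug-in
   miscalibration of order a few percent — expected and documented).
2. **The z procedure** for the depolarized-minus-resting differential:
   fold changes of all admitted transcripts are z-transformed
   (`z = (fc − mean)/sd`, one pool, not per-class), two-sided normal p,
   flagged when |z| > 1.96 — by construction 2.5% per tail under a null.
   Admission applies the basemean rules first: differential basemean ≥ 1
   (≥ 3 for 5'UTRs); transcripts failing that but passing in both
   single-condition sets inherit the differential value of their gene's
   highest-expressed transcript (provenance flagged); otherwise excluded.
   Note the pooled sd is inflated by whatever true effects exist — with
   many strong planted effects the procedure is conservative; this is a
   property of the published method, visible in the generator.
3. **Pooled permutation t-tests** per region class between conditions
   (per-sample mean RPKM as the unit), exhaustive over labelings when
   ≤ 10,000, else seeded random draws, with add-one smoothing
   `(1 + #{|t*| ≥ |t|})/(1 + N)` and Bonferroni over region classes. The
   pooled-per-class reading was chosen because the source methods do not
   say whether the test is per transcript; both the statistic and mode
   are reported in the output.

uORFs enter only through their host transcripts: records of class `uORF`
strictly longer than 9 nt (stop codon included) with caller score
strictly above 0.7 (0.6 when intersecting with CLIP/Ribo-seq sets).

## eIF4G2 CLIP: binomial tests on normalized tags

5'UTR tag counts per transcript are depth-normalized to tags per million,
fold changes use pseudocount 0.1, and the depolarized-vs-resting test is
an exact binomial: `k = round(norm_dep)` of `n = round(norm_dep +
norm_rest)` at null proportion 0.5, two-sided by the minimum-likelihood
rule (sum of all outcomes no more likely than observed), which is well
defined for asymmetric cases and oracle-tested. The null proportion,
and rounding of fractional normalized tags, are package decisions — the
source sentence specifies only "binomial tests on the normalized values".
Note the test's sampling model is Poisson-like: it is calibrated when
normalized tags are on the scale of actual counts, and anticonservative
if normalization inflates them; library depths near one million reads
keep the two scales aligned, which is what the generator emulates.

Bound calls: `log2fc > 0 & p < 0.2` (the canonical bound set — a
deliberately permissive screen); for intersections with translation gene
sets the printed rule is fold change > 1 with no p filter
(`call_bound(mode = "intersect")`). Both are implemented; note the
intersect rule admits roughly half of all unbound transcripts by sign
noise alone, so precision-oriented analyses should use the bound call
(the package's end-to-end validation does).

## Motif enrichment

PWMs (4 × L column-stochastic matrices, rows A/C/G/U) are scanned over
5'UTR sense strands only (UTRs are single-stranded RNA). Window score =
sum of `log(p + 1e-6)`; a window hits when its score reaches
`min + 0.95 × (max − min)` of the achievable range — our reading of the
"minimum score = 95%" convention; the exact scoring of the delegated
implementation is unspecified, so this scheme is documented and
oracle-tested rather than claimed identical. Enrichment is at the
transcript level (≥ 1 hit) by the upper-tail hypergeometric against an
expressed background (longest transcript per gene), BH-corrected across
motifs, enriched at FDR < 0.1. The packaged eIF4G2 matrix is
consensus-derived (CGCGGC) and labeled synthetic — a stand-in for the
curated PWM, not a copy of it.

## PL-MS: Perseus-style processing

Fixed order, logged per run: log2 → detection filter (observed in
≥ ceil(2n/3) replicates of at least one condition × bait × biotin cell —
"minimum two-thirds" read as at-least) → downshifted-normal imputation
(per column: Normal(m − 1.8·s, (0.3·s)²) for missing entries) → width
adjustment (per column: center at the column median, scale by its IQR,
restore the across-column median IQR and median of medians — a symmetric
stand-in for the proprietary asymmetric-quartile variant, order-
preserving and idempotent) → minus-biotin subtraction in log2 space,
matched by condition/bait/replicate → paired t (PSD95 vs Pan, within
condition) and unpaired Student t (dep vs rest enrichments), enriched at
mean log2 > 0 and p < 0.05, zero-variance rows flagged with p = 1.
Whether the original order imputes before or after width adjustment is
not recorded in the source; ours is fixed and stated.

# The synthetic world

The generator's defaults state the emulated experiment: 4 RNA replicates,
3 ribosome-profiling replicates, 5 MS replicates; 2 conditions × 2 baits
× input/pulldown (± biotin for MS); negative-binomial counts
(variance μ + αμ², α = 0.05) with log-normal baselines, replicate batch
offsets (sd 0.1 log2) and heterogeneous library factors (sd 0.15 log).
Planted structure, per gene: dendritic (20%, +2 log2 in PSD95 pulldowns,
both conditions), uORF-bearing (15%), uORF-up (6%, +2 log2 on the 5'UTR
in depolarized PSD95 pulldowns only), of which CDS-up and CDS-down
(2.5% each, ±2 log2 on the CDS) — fractions at the scale of the real
study's gene sets (hundreds of genes among ~15k detected). Translation
effects never touch RNA-level means: the translation-only premise is
enforced by construction. eIF4G2 binding (15% base rate, +1.5 log2 CLIP
tags in depolarization) is coupled to motif presence (coupling 0.9; at
coupling 1 every bound gene carries the motif), and the motif is planted
preferentially in CDS-up 5'UTRs (probability 0.8 vs 0.1 background).
CLIP tags are Poisson at ~1e6 nominal depth (see the binomial-test
calibration note above). Protein intensities are log-normal (log2 sd 2
across proteins, replicate noise 0.5), dendritic proteins +3 log2 in
PSD95 plus-biotin samples (8-fold — the scale of bona fide postsynaptic
proteins), a de-enriched class (25%, −3 log2) keeping planted mass
two-sided as in real pulldown proteomes, minus-biotin samples 3 log2
lower background only, and missing-not-at-random dropout: per-run
detection limits with logistic dropout in decreasing intensity, ~15%
nominal. Every output stream draws from `seed + fixed offset`, so
regenerating one file never perturbs the others, and identical
parameters give byte-identical outputs.

What a green recovery test establishes — and what it does not: the
generator produces clean factorial designs with independent genes, exact
region annotations, no mapping error, no multimapping, no 3-nt
periodicity structure, and single-transcript genes. Recovery there
demonstrates that the statistical machinery identifies what it claims to
identify at realistic effect sizes and noise; it says nothing about
alignment, quantification or annotation artifacts of real libraries.

Two measured properties of the stated world are worth knowing:

* Per-condition PL-MS sensitivity is ~0.75, not ≥ 0.8: imputation noise
  propagated through minus-biotin subtraction, plus the width
  adjustment's compression of the PSD95 columns (planted mass inflates
  their IQR), cap what a single paired test can see at 8-fold effects
  and 15% missingness. The dendritic proteome is the union of the
  per-condition enriched lists, and planted proteins are dendritic in
  both conditions, so recovery is assessed against that union (~0.94).
* The z procedure's pooled sd includes planted effects, so its
  sensitivity falls as the planted fraction grows; at the stated
  fractions, 5'UTR sensitivity is ~0.85–0.9.

# Numerical choices

Strict inequalities everywhere a threshold is printed (> 1, > 1.25, > 9
nt, > 0.7, < 0.05, < 0.2, < 0.1, |z| > 1.96, t < 2, t > −2); pinned by
unit tests. Pseudocount 0.1 in both the ribo enrichment and CLIP fold
changes. OLS residual variances floored at 1e-8; NB dispersions floored
at 1e-8 and capped at 50; PWM probabilities floored at 1e-6 before logs.
Ties: longest-transcript selection breaks ties by lexicographically
smallest transcript id; quantile normalization gives tied values the
mean of the spanned reference values. Degenerate inputs error loudly
(zero fold-change dispersion, zero IQR, empty filtered matrices,
residual df 0) rather than returning silent NAs, except where the
contract says otherwise (zero-variance t rows are flagged with p = 1;
non-converged GLMs are flagged with missing p). Non-coding transcripts
get all region lengths zero and are excluded from region analyses.
Gene identifiers are opaque text throughout; no cross-reference between
annotation vocabularies is attempted.

# Known limitations

* The moderated t is fixed-prior-df, not estimated-prior empirical
  Bayes; with few samples its df gain is modest and deliberate.
* The binomial CLIP test inherits its scale sensitivity from the
  published design; replicate-aware count models would be stronger but
  are out of contract.
* The permutation test at 3 vs 3 has only 20 labelings; its smallest
  attainable smoothed p is 1/21 — Bonferroni across two region classes
  can never reach 0.01 at this design size.
* `test_translation_lrt` fits ~2 GLMs per transcript and is the slowest
  stage (~5 s per 1000 transcripts); the z route is the default for
  differential calls.
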