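---
title: "Chiral metabolomics analysis with chiralome: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Chiral metabolomics analysis with chiralome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chiralome)
```

## The problem

Enantiomers — mirror-image forms of a chiral metabolite such as D- and
L-glutamine — have identical masses and, on an achiral column, identical
retention, so ordinary untargeted LC-MS cannot distinguish them. Chiral
derivatization with diacetyl-tartaric anhydride (DATAN) converts an
enantiomer pair into a pair of diastereomers that separate
chromatographically: after alignment, a chiral pair appears in the feature
table as two features with (nearly) the same m/z and a retention-time
offset of a couple of minutes. Crucially, the (+)- and (−)-forms of the
derivatizing agent invert the elution order of the two diastereomers, so a
pooled quality-control sample derivatized both ways provides an internal
check: at the two fixed retention positions, the intensity ratio should
flip between the (+)- and (−)-DATAN pools for a true enantiomer pair.

`chiralome` implements the downstream analysis of such an experiment — from
an aligned feature table to normalized intensities, detected and verified
enantiomer pairs, per-feature differential statistics, and integration with
a gene expression matrix — together with a synthetic-data generator that
plants known pairs, effects and gene–metabolite correlations so that every
stage can be scored against ground truth.

## Normalization: iterated probabilistic quotient normalization

PQN corrects per-sample dilution. The reference spectrum is the per-feature
median over the non-QC study samples; each sample's dilution factor is the
median of its feature-wise quotients against that reference, computed only
over features observed in both (no imputation), and intensities are divided
by the factor. QC pools are normalized against the same reference.

One subtlety: a *single* median-quotient pass is not exactly idempotent,
because rescaling the samples moves the median reference itself. Re-running
a single-pass PQN on its own output yields factors that deviate from 1 by
as much as a few percent on small tables. `pqn_normalize()` therefore
repeats the pass until every per-pass factor equals 1 within `tol`
(default 1e-12; convergence is geometric and each pass is cheap), making
the normalization a true fixed point. The classical single-pass factors are
still reported (`first_pass_factor`) and available via `max_iter = 1`.

## Pair detection, labeling, and swap verification

Two features are candidate enantiomers when their mass difference is
strictly below `ppm_max` (default 5 ppm, denominator the mean of the two
masses — immaterial at this scale) and their RT difference strictly between
0 and `rt_pair_max` (default 3 min). Both windows are strict inequalities.
When a feature appears in more than one candidate pair the conflict is
resolved greedily by ascending ppm difference, then ascending RT
difference, then lexicographic ids; the result is a deterministic matching
(each feature in at most one pair) and every conflict resolution is logged.
The greedy rule is this package's choice: nothing in the underlying method
prescribes a resolution, and greedy is auditable and reproducible.

Within a pair, E1 is the member with the lower mean intensity over study
samples and E2 the higher (ties break by elution order). Swap verification
computes the positional ratio R = intensity(E1)/intensity(E2) in the
(+)-DATAN QC pool and the same ratio in the (−)-DATAN pool and calls the
pair `verified` when the two log2 ratios have opposite signs and both
magnitudes reach `swap_tau` (default 0.5, i.e. at least a 1.4-fold ratio in
both pools). No numeric switching criterion exists in the underlying
method, so `swap_tau` is deliberately a visible, configurable knob; pairs
with an absent pool or missing values are `untestable`, never silently
dropped.

Annotation matches features to a standards library by smallest ppm error
within `ppm_max` and `annotation_rt_tol` (default ±1 min — a separate,
tighter knob than the pairing window, which describes diastereomer
separation rather than identification accuracy). D/L calls come from the
library's per-enantiomer expected retention times; no global "D elutes
first" rule is assumed, since elution order is compound- and
agent-dependent.

## Differential testing

Per feature, a Welch unequal-variance t-test compares the positive and
negative groups (Student pooled-variance by config). The default
`tail_mode = "observed"` reports the one-tailed probability in the
direction of the observed difference — the two-tailed p divided by 2. This
reproduces one-tailed volcano-style reporting without assuming a global
direction, but it is anti-conservative: under the null its p-value is
uniform on (0, 0.5), so the realized level at nominal 0.05 is 0.10. The
output flags p-values as unadjusted and the fixed-direction modes
(`"greater"`, `"less"`) are exactly calibrated; the acceptance tests assert
both facts.

Tests run on log2-transformed intensities by default (`test_on_log`).
Integrated LC-MS intensities are log-normal to good approximation, and at
n = 5 per group a raw-scale t-test is visibly miscalibrated (about 0.08
at nominal 0.05 in the generator's stated world); on the log scale the
small-sample t is exact under the generator. Fold changes are always
`log2(mean(x)/mean(y))` of raw-scale group means, the scale on which they
are conventionally reported.

Features need `min_per_group` (default 3) non-missing values per group;
below that they are `untested`, excluded from significance counts. Tiers:
`significant` (p < 0.05), `borderline` (0.05 ≤ p < 0.06, the asterisk
band), `not_significant`. A pair passes the downstream gate only if at
least one member is fully significant — borderline does not pass. The
pooled (E1+E2) test sums the two members per sample; a sample missing one
member falls back to the other, and a member missing everywhere reduces the
pool to the other member with a `pool_fallback` flag.

No multiple-testing correction is applied anywhere, mirroring the original
workflow; every output labels p-values as raw.

Clinical-style comparisons use `wilcoxon_rank_sum()` (exact enumeration
distribution for combined n ≤ 20 without ties, normal approximation with
tie correction otherwise) and `two_tailed_ttest()`.

## Integration with expression data

Genes pass the CV filter when sd/mean (n−1 denominator) lies strictly
inside (0, 0.25): the lower bound removes flat genes, the upper bound genes
dominated by patient-specific variation. Gene–metabolite edges are Pearson
correlations over matched samples kept at r ≥ 0.7, positive only —
negative correlations are discarded by design, matching the biological
question of co-varying expression. Zero-variance rows are logged and
skipped rather than producing NaN edges.

Joint pathway analysis tests gene hits and compound hits by separate
hypergeometric upper-tail tests over explicit universes, combines the
available p-values with Fisher's unweighted method (chi-square with 2k df;
a test enters only when the pathway has members of that type in the
universe), and scores impact as the fraction of total pathway degree
carried by hit nodes. Pathways without topology fall back to
|hits|/|members| (the complete-graph assumption) and are flagged. The
report filter requires at least one compound hit, one gene hit,
p_combined < 0.05 and impact > 0.2.

Two caveats are deliberate. First, the universes (all profiled genes; all
annotatable-or-pathway compounds in the shipped pipeline) are explicit
arguments because enrichment p-values shift with them and the original
analysis does not state its universes. Second, our impact is normalized to
[0, 1]; the reference web tool that inspired the 0.2 cutoff reports impact
values above 1 for some pathways, so its internal normalization differs and
the two scores are not numerically comparable — only the cutoff's role is
reproduced.

## The synthetic-data generator

`generate_feature_table()` emulates a small two-group chiral study: 500
features, 100 planted pairs, 5 samples per group, log-normal baseline
intensities (log2 mean 17, sd 2 — Orbitrap-scale integrated intensities),
1 ppm mass jitter per pair member (redrawn until the realized pair ppm
difference is below 5, so planted pairs satisfy the window by
construction), RT offsets uniform in [0.2, 2.5] min (inside the 3-min
window; the true offset distribution of DATAN diastereomers is not
derivable from the underlying study, so this default is flagged as
arbitrary), within-pair log2 abundance ratios uniform in [1, 2.5], a 10%
fraction of features carrying a +2 log2-fold group effect, log2-scale
Gaussian noise sd 0.5, and 5% completely-at-random missingness in study
samples (so the ≥3-per-group rule is exercised). The (+)-DATAN QC pool is
the per-feature mean of all study samples; the (−)-DATAN pool is the same
pool with intensities exchanged within every true pair — the idealization
of elution-order switching that makes swap verification exactly checkable.

The truth file records, per planted pair, both the generator's target log2
ratio and the *realized* log2 ratio in the (+)-pool. The realized value is
the one the swap-verification guarantee refers to: because the (−)-pool is
an exact exchange, verification at any `swap_tau` at or below the realized
|log2 ratio| succeeds as an arithmetic identity, whereas the target ratio
only holds in expectation (sample means wobble at n = 10). Recording the
realized plant keeps that guarantee exact rather than statistical.

`generate_expression()` plants correlated genes as affine transforms of a
metabolite vector plus Gaussian noise sized so the conditional correlation
equals `target_r` (default 0.9); the affine map places planted genes on a
TPM-like scale (mean 100) with CVs inside the filter band, so they survive
the CV filter as real correlated genes would have to. Background genes are
independent: 30% constructed inside the CV band, 10% constant (CV = 0,
exercising the strict lower bound), the rest high-CV. `generate_pathways()`
draws random member sets with Erdős–Rényi topology; planted enriched
pathways over-sample 80% of their members from the planted gene/compound
lists.

What a green test does *not* establish: the generator has no
chromatographic drift, no batch structure, no correlated missingness, no
heavy-tailed contamination, and its pairs never overlap in RT with
unrelated isobaric features except by rare chance. Recovery rates on this
stated world are upper bounds on what real data would give.

## Numerical choices and degenerate inputs

Zeros read from feature tables are treated as missing (an unintegrated
peak, not abundance zero). Intensity round trips hold to 15 significant
digits; ids and metadata are bit-exact. A zero standard error yields t = 0
(p = 0.5 one-tailed), not NaN. Hypergeometric p-values use the upper tail
P(X ≥ k); Fisher's method returns a single p unchanged. Equal group means
give direction `none`. The exact Wilcoxon switches to the tie-corrected
normal approximation whenever ties or combined n > 20 make enumeration
inappropriate. All thresholds sit in `analysis_config()` — nothing is
hard-coded — and every exclusion (failed gate, failed CV, undefined r,
greedy conflict) is logged at record granularity.

## Known limitations

The package consumes aligned feature tables; it performs no peak picking,
no mzML parsing, and no RNA-seq quantification (an external DE gene list
can be supplied as a file). Pathway sets are file inputs (GMT plus optional
edge list); there are no live database clients. Impact supports degree
centrality only. The one-tailed direction convention of the original
analysis is unknown; both fixed and observed modes are provided and neither
is asserted as the original.
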