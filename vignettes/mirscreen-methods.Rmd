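---
title: "Models and design choices in mirscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices in mirscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirscreen)
```

mirscreen implements a replicate-free, threshold-based screen for
treatment-responsive microRNAs across a panel of receptor-positive and
receptor-negative cell lines, plus the downstream assay statistics used to
validate hits. This vignette records the models, the parameters that
matter, and the choices made where the design was genuinely open.

## The screen model

The screen assumes one treated and one control array per cell line (more
are allowed; replicates are averaged in log2 space). Raw intensities are
background-subtracted feature medians on a linear scale, so they can be
zero or negative; values below 1 are clipped to 1 before the log2
transform, and the number of clipped cells is reported.

**Quantile normalization.** All samples are forced to a common empirical
distribution by rank-wise replacement with cross-sample rank means, with
ties resolved by the mean of the tied ranks' target values. This is
performed on the linear scale (delegated to `limma::normalizeQuantiles`)
before the log2 transform. Two consequences matter for interpretation:
after normalization the sorted values of any two samples are identical
exactly, and a planted log2 effect is only *approximately* preserved —
normalization moves each value to the average empirical quantile at its
rank, so an effect of 1.2 log2 units re-emerges as the rank-gap it
induces. With 200 features this distortion is at the percent level; with
very few features it can be substantial, which is why the closed-form
recovery test uses 200 features.

**Thresholds.** All comparisons are strict, following the "more than"
reading of the screening rules: the expression floor is `> 6` log2 units,
negative-line exclusion removes fold changes `> 1.5` or `< 1/1.5`, and the
same thresholds define the up/down RFC lists. A fold change of exactly 1.5
in a negative line is therefore *kept*. The floor rule is "before or
after" treatment — `max(treated, control) > 6` per line — because a
microRNA switched fully on or off by treatment is precisely the kind of
responder the screen must not discard; a `both_conditions` variant is
exposed on `screen_criteria()` for the stricter reading.

**Relative fold change.** The published definition of RFC is a
"subtraction" of the average negative-line fold change. We interpret both
the average and the subtraction in log2 space: linear fold-change ratios
of down-regulated microRNAs must remain positive ratios (published
down-regulated RFC values lie in 0.46–0.65, impossible under linear
subtraction), and a log-space subtraction is the natural operation on
fold changes. The cross-line "mean RFC" is accordingly the geometric mean
of the per-line RFCs: on the published up-regulated pairs this reproduces
the printed 4-decimal values (e.g. `sqrt(2.4300 * 3.5825) = 2.9505`), with
a single row off by one unit in the 4th decimal that is consistent with
the published values being rounded from full precision. The cross-line
lists admit a microRNA whenever its *mean* RFC clears the threshold even
if one per-line RFC does not, matching the published table's rows whose
mean appears without a second per-line entry.

One published invariant — that raising the fold-change threshold can only
shrink the up lists — holds for the RFC listing step in isolation. It can
fail for the screen as a whole because the same threshold also drives
negative-line exclusion: loosening exclusion admits new survivors. The
monotonicity test therefore plants effects in positive lines only, making
the exclusion stage inert.

## The array simulator

The generator emulates the 8-sample two-factor design: per-microRNA log2
baseline `~ Normal(9, 1.2)`, a per-(microRNA, line) offset
`~ Normal(0, 1)` shared by both conditions of a line, a treatment effect
added only where planted, and measurement noise `~ Normal(0, 0.1)` in log2
units; stored intensities are `2^log2`, i.e. log-normal on the linear
scale. Noise additive in log2 space keeps fold changes symmetric under
up- and down-regulation. A configurable fraction (default 0.3) of
microRNAs receives a baseline drawn uniformly in (2, 5.5), safely below
the log2 floor of 6, to exercise the expression filter. The line offset
cancels in fold changes but makes same-line samples correlate, so
expression clustergrams reproduce the qualitative published structure
(same-line treated/control pairs merge first; the first branch separates
receptor-positive from receptor-negative lines when effects are planted
there). The published design is replicate-free, and that is the default;
a `replicates` parameter exists because the simulator should not hard-code
that reading.

What the simulator does *not* model: array spatial artifacts, dye or probe
biases, cross-hybridization, or correlated noise between features.
Passing recovery tests therefore demonstrate correctness of the screening
logic under the stated noise model, not robustness to array pathology.

The screen-recovery study uses 200 microRNAs, 10 planted responders at
+1.2 log2 in both positive lines, log2 noise sd 0.1, no low-expression
subset and no line offsets — the generative model of the screen's own
assumptions — over 100 seeds, and asks for sensitivity at least 0.95 on
the cross-line list with at most 1 false positive per run on average.

## Assay models

**ΔΔCq.** Amplification efficiency is fixed at 2 (no efficiency
correction, matching standard SYBR/TaqMan relative quantification).
Multiple reference genes are combined by arithmetically averaging their
per-gene mean Cq, equivalent to a geometric mean of reference quantities
("the average amount" of the references). ΔΔCq is invariant to adding a
constant to every Cq, which the tests assert.

**Viability.** Replicate absorbances are averaged *before* the
treated/control ratio is formed (the alternative — averaging per-replicate
ratios — is not distinguishable from published summaries; averaging first
is the variance-minimizing choice for a ratio of means). Cross-line
summaries are arithmetic means of per-line inhibition percentages, e.g.
56% and 24% combine to 40%.

**Cell cycle.** The proprietary histogram-deconvolution software used in
practice is replaced by an explicit three-component mixture: Gaussian G1
at `mu`, Gaussian G2/M constrained to `2*mu` with an sd broadening factor,
and S phase as a uniform on `(mu, 2*mu)` convolved with the G1 Gaussian —
the simplest model in which the three occupancies are identifiable. Bins
are treated as a multinomial sample; the likelihood is maximized by
Nelder-Mead over `(log mu, log sigma, log broadening, softmax fractions)`
from two starts (tallest bin read as the G1 peak or as the G2/M peak),
keeping the better optimum. Defaults: G1 mean 200 DNA-content units, CV
0.03, broadening 1.15, bin width `mu/50`. Fitting the simulator's own
model is consistent — at 10,000 events the fractions are recovered within
0.02 — and the published BT474 G1 contrast (65% control vs 91% treated),
used as simulation truth, is recovered to within 0.03 on the G1
difference. Below a few hundred events the fit degrades; inputs with
fewer than 100 events are rejected.

**Luciferase.** Firefly is normalized per replicate to its renilla
internal control; percent repression is `100*(1 - mean(oligo)/mean(ncRNA))`
with a pooled-variance t test on the normalized activities. The simulator
gives the two single-site mutants half the wild-type repression each and
the double mutant none — a two-equal-sites reading of the construct
design; the estimator does not depend on this split. Multiplicative
log-normal noise with unit mean and configurable CV (default 0.05, n = 3)
makes the estimator unbiased to well under one percentage point at the
published 27% effect.

**Apoptosis.** The two-channel quadrant gate of a real Annexin/PI assay
is reduced to a single fixed intensity threshold; the simulator draws
log-normal negative and positive populations two decades apart, so
threshold placement is uncritical there. Double-positive handling is out
of scope.

**t test.** `unpaired_t_test()` is the pooled-variance Student test
(matching the published methods; not Welch), delegated to
`stats::t.test(var.equal = TRUE)` with explicit handling of zero-variance
degeneracies (equal means: `t = 0, p = 1`; unequal: the `p -> 0` limit,
flagged with a warning).

## Seed matching

The seed is nucleotides 2–8 of the mature microRNA (7 nt; `GUAAACA` for
the miR-30 family). Site types follow the canonical taxonomy — 6mer
(match to nt 2–7), 7mer-A1 (6mer plus an A opposite nt 1), 7mer-m8 (match
to nt 2–8), 8mer (both) — since every canonical site contains the 6-nt
core, each core occurrence is classified exactly once into its maximal
type, which is also what suppresses lower-grade calls inside a reported
higher-grade site. Only the sense strand is scanned (mRNA context); U and
T are interchangeable; coordinates are 0-based half-open internally and
1-based inclusive in rendered reports. No thermodynamic scoring,
conservation, or 3'-supplementary pairing is attempted — the module
localizes candidate sites; it does not rank them.

Mutant constructs substitute three transversions inside a site's 6-nt
core, drawn deterministically from a seed, and re-scan to verify that no
site of any type survives at the disrupted locus while unselected sites
are untouched (the mut1 / mut2 / mut1+2 semantics). The published
constructs' actual coordinates and substituted bases are not available,
so constructs are emulated on synthetic UTRs.

## Numerical notes and problem sizes

Linear intensities at or below 0 are clipped to 1 before log2. Quantile
normalization of a single sample is the identity. RFC requires strictly
positive fold changes and errors otherwise. Cluster distances to a
zero-variance profile are undefined under `1 - r` and are set to 1 with a
warning. Reports round RFC to 4 decimals, keeping full precision
alongside. Test problem sizes — 200-feature screens over 100 seeds,
10,000-event histograms, 500 luciferase replications, 1,000 null t tests,
100 random-kilobase UTR scans — were chosen so the full suite documents
estimator behaviour at the scale of the motivating experiment while
remaining quick to run.
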