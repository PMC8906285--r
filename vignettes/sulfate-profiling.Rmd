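---
title: "Untargeted profiling of the urinary sulfate metabolome: methods"
author: "sulfoprofiler"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Untargeted profiling of the urinary sulfate metabolome: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sulfoprofiler)
```

# The problem

Phase II sulfate conjugates dominate the excreted metabolome of many
compounds, ionize readily in negative-mode electrospray, and fragment in a
highly stereotyped way: collision-induced dissociation of an `R-O-SO3H`
ester yields a small set of sulfur-bearing product ions and neutral losses
regardless of the aglycone. `sulfoprofiler` exploits this to classify every
feature of an untargeted DDA LC-MS/MS experiment as sulfate or non-sulfate
from its MS/MS spectrum alone, and then to ask which sulfated features
change between two conditions (for example before and after administration
of a steroid, or before and after incubation with a sulfatase enzyme).

The pipeline consumes three text artifacts produced upstream: MGF product
ion spectra, an aligned feature table (one intensity per sample), and a
sample sheet labelling each injection as biological, pooled QC or blank.
Peak picking and chromatographic alignment are out of scope; they belong to
the upstream software that produced the feature table.

# Diagnostic signals and matching tolerances

Six sulfate-derived signals are matched per spectrum: the product ions
`•SO3−`, `HSO3−`, `•SO4−`, `HSO4−` and the neutral losses `SO3` (79.9568
Da) and `H2SO4` (97.9674 Da), all computed from monoisotopic atomic masses
with one electron mass (0.00054858 Da) added per negative charge. Matching
uses absolute mass windows: **±5 mDa** for product ions and **±10 mDa** for
neutral losses (a loss difference accumulates the error of two measured
m/z values). We deliberately do not use a ppm window here: at m/z 80 a
5 ppm window is 0.4 mDa, far tighter than realistic HCD fragment mass
accuracy; ppm tolerances are reserved for precursor-level comparisons
(feature mapping and candidate matching, both ±5 ppm by default).

One numerical footnote: the radical anion `•SO3−` computes to 79.95736,
which rounds at four decimals to 79.9574; the value commonly tabulated in
the literature, 79.9573, is a truncation of the same quantity. The ±5 mDa
matching window makes the distinction irrelevant in practice.

Seven glucuronide transitions (losses of 194.0427 and 176.0321 Da, plus
five sugar fragment ions at m/z 175.0248, 157.0142, 113.0244, 85.0295,
75.0088) support a secondary screen; a spectrum is called a glucuronide
when **at least two distinct** transitions match.

# Per-spectrum statistics

For each spectrum the package computes:

* **IR (intensity ratio)** — the summed intensity of the distinct peaks
  matched by any sulfate signal divided by the summed intensity of all
  peaks, as a percentage. A peak matching several rules is counted once,
  so IR is bounded by 100.
* **MA (maximum abundance)** — the relative abundance (percent of the base
  peak) of the most intense matched sulfate signal.

The intensity credited to a neutral loss is that of the product-ion peak
implying the loss (the loss itself has no peak). The *dominant species* of
a spectrum is the matched rule of highest intensity; ties break product
ions before neutral losses and then lower accurate mass — an arbitrary but
deterministic rule, since the upstream definition leaves ties unspecified.

# Feature curation

Spectra attach to features when the precursor is within ±5 ppm in m/z and
±3 s in retention time; among candidates, the closest RT wins and the
assignment is greedy and injective (one spectrum annotates at most one
feature), which prevents a single scan from annotating two co-eluting
isomers. Features are then removed, with an audited reason, when they lack
MS/MS, have S/N below 3, or appear in fewer than two samples. A
static-exclusion analogue removes features matching the 1,000 most intense
blank-derived ions (±5 ppm, ±3 s); the instrument applied this at
acquisition time, we apply it on the table with equivalent effect.

# Signal-drift normalization

Pooled QC injections are replicate measurements of one material, so any
per-feature trend of QC intensity against injection order is instrument
drift. For each feature with at least `minQc = 3` nonzero QCs we fit
`stats::lowess` (span 0.7) of QC intensity versus injection order,
evaluate the curve at every sample's injection order (linear interpolation
inside the QC range, linear extrapolation beyond it), and divide
intensities by `fitted / median(QC)`. Corrected values are re-anchored so
the per-feature QC median is exactly invariant; zeros stay zero, and
features with too few usable QCs pass through flagged. The span of 0.7 is
wide enough that five to ten QCs constrain a smooth trend without chasing
replicate noise.

# Classification

Each feature contributes eight parameters, all on the 0–100 percent
scale: the relative abundances of the six sulfate signals, IR and MA.
Because k-means is scale-sensitive and the columns have very different
spreads, columns are z-scored before clustering (sample-SD, `n − 1`
convention, as in `base::scale`; constant columns map to zeros). Lloyd's
algorithm with k = 2 and Euclidean distance runs from 25 k-means++
initializations drawn from a caller-supplied seed, keeping the lowest
within-cluster sum of squares; on matrices of up to eight rows the result
is verified in the test suite against exhaustive enumeration of all
bipartitions. The cluster whose centroid has the larger MA on the original
scale is labelled *sulfate* — sulfate spectra are dominated by their
diagnostic fragments, so high MA is the defining signature. Sulfate
features are then *speciated* by dominant signal (HSO4−-dominant spectra
indicate saturated esters; •SO3−/SO3-loss-dominant spectra indicate
phenolic and other unsaturated esters), and the fraction showing two or
more signals above 5 percent relative abundance is reported.

# Differential analysis

Intensities (corrected assay when normalization ran) for the two
biological groups are floored by half-minimum imputation per feature
(zeros replaced by half the smallest nonzero value; all-zero features are
excluded with an audit record) and log2-transformed. Per feature the
log2 fold change is the plain mean difference, and the pooled residual
variance `s²` has `d = n1 + n2 − 2` degrees of freedom. Empirical-Bayes
moderation estimates a prior `(d0, s0²)` by the method of moments on
`log s²` (using the mean and trigamma-variance of the log-F distribution,
with a Newton inversion of the trigamma function), and the moderated
statistic is

```
t = log2FC / sqrt( s̃² (1/n1 + 1/n2) ),   s̃² = (d0·s0² + d·s²)/(d0 + d)
```

on `d0 + d` degrees of freedom. With `priorDf = 0` the statistic reduces
exactly to the ordinary pooled t (a tested identity), and the test suite
cross-checks the estimator against `limma::eBayes` on heteroscedastic
simulations. Raw p-values are adjusted by Benjamini–Hochberg — the
conventional choice where only "adjusted p-value" is specified — and
features are classed **grey** (adjusted p > 0.01), **blue** (significant,
|log2FC| ≤ 3) or **red** (significant, |log2FC| > 3, i.e. fold change
above 8). The fold-change boundary is read on the absolute value, so
strong down-regulation is also red; the boundary itself is blue because
the red band is defined by a strict inequality.

# Candidate annotation

To propose identities for changed features, the package enumerates every
multiset of up to three phase-I transformations of a parent compound —
hydroxylation (+O), bond oxidation read as dehydrogenation (−H2), and
reduction (+H2) — followed by conjugation (sulfation +SO3, or
glucuronidation +C6H8O6), and computes the theoretical `[M−H]−` m/z of
each product. Reading "bond oxidation" as −H2 is the minimal
interpretation under which the full published steroid sulfate series
(m/z 367.1583 … 387.1845) is reachable within 5 ppm, which the test suite
asserts. Applications that would drive an element count negative are
skipped; candidates with identical final formulas (e.g. the empty multiset
versus oxidation+reduction) are collapsed with all generating multisets
recorded. Matching against features is at ±5 ppm, and a shortlist keeps
matches that are significant (adjusted p ≤ 0.01) with log2 fold change in
[4, 10] — the 16- to 1024-fold window in which direct administration
metabolites are expected. Only mono-conjugation is enumerated; isomers
are reported, never resolved, since distinguishing them requires
retention-time and MS/MS comparison against reference materials, which is
out of scope.

# The synthetic-data generator

Because the original raw data are not redistributable inputs, a seeded
generator (`generateSyntheticStudy`) emulates the statistical structure
the pipeline assumes, with exact-count class allocation so tests are
deterministic:

* 28 percent sulfate features (the published study proportion) and, by
  default, 5 percent glucuronides; two biological conditions in
  triplicate, six pooled QCs interleaved through the injection sequence,
  two blanks;
* sulfate spectra are built backwards from target statistics: a dominant
  species drawn with weights echoing the published speciation (•SO3− 51%,
  SO3 loss 22%, HSO4− 20%, …), MA equal to 100 for 60 percent of spectra
  and uniform on [40, 99.5] otherwise (matching the published MA
  median ≈ 99 and mean ≈ 88), and an IR target uniform between 5 and 97
  (spanning the published 4–97 range) hit exactly by construction of the
  non-diagnostic peaks;
* non-sulfate spectra contain no peak within 0.03 Da of any sulfate
  window, so their IR is exactly zero — an idealization: real non-sulfate
  spectra show small nonzero IR from near-isobaric noise, which makes the
  real classification problem slightly harder than the synthetic one;
* intensities are log-normal (natural-log SD 1 around 10^6) with a shared
  multiplicative drift of 2 percent per injection, log2-scale replicate
  noise of 0.5 (biological) and 0.1 (pooled QC), and a 5 percent spiked
  subset multiplied by `2^log2FC` in the treated group with |log2FC|
  uniform on [4, 10] (63 percent up-regulated, echoing the published
  up/down split);
* a 2 percent contaminant subset is intense in blanks, and small fractions
  of non-sulfate features carry the curation defects (no MS/MS, low S/N,
  single-sample detection) so the filters are exercised.

What passing tests on these data do show: the mass arithmetic, matching
windows, IR/MA algebra, curation, drift correction, clustering geometry
and differential calibration all behave as specified under realistic
magnitudes. What they do not show: robustness to chimeric spectra,
isotope envelopes, adduct networks, missing-not-at-random dropout or
nonlinear drift, none of which the generator emulates.

Boundary sulfates — low IR (5–30) with MA near 40–55 — are genuinely
ambiguous under best-WCSS bipartition and a few percent of them land in
the non-sulfate cluster; at the default 500-feature scale overall sulfate
recovery is typically 97–99 percent. Test problem sizes (a few hundred
features for end-to-end runs, 10,000 features for null-calibration
simulations) were chosen as the smallest scales at which these stochastic
properties are stable.

# Degenerate inputs and numerical choices

Zero-intensity peaks are dropped at read time; spectra re-sort peaks by
m/z on construction. Relative abundances are computed as `100·(i/base)`
and clamped at 100 to keep the base peak itself exactly on the boundary.
LOWESS fits falling to zero or below yield a unit correction factor
rather than a sign flip. k-means errors explicitly when all rows are
identical (no two-cluster partition exists), and failed restarts (empty
clusters) are discarded rather than propagated. BH adjustment validates
p-values into (0, 1]. All RNG use is confined with a save/restore of the
caller's random seed.

# Known limitations

Only singly charged negative ions are considered; di-anionic conjugates
and other conjugate classes (phosphates) are future work. The IR/MA
definitions use relative intensities, so the classifier is invariant to
uniform intensity rescaling but blind to absolute abundance. The
differential model is a two-group contrast; multi-treatment designs are
run as repeated contrasts against a common control.
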