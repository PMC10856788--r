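---
title: "In-silico directed evolution of ssDNA-SWCNT serotonin nanosensors: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In-silico directed evolution of ssDNA-SWCNT serotonin nanosensors: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sensevo)
```

## The problem

Single-walled carbon nanotubes (SWCNTs) wrapped in single-stranded DNA
fluoresce in the near-infrared (nIR-II) window, and the intensity of that
emission shifts when small molecules adsorb at the corona. Which molecules
modulate the signal — and by how much — depends on the wrapping sequence, so
the sequence is an engineerable recognition element. The sensors considered
here are 30-mer oligos with fixed hexa-C flanks and an 18-nt central
variable region; the readout is the relative fluorescence change
$\Delta F/F_0 = (F - F_0)/F_0$ at 1202 nm, where $F_0$ is the intensity
after a DI-water (blank) addition and $F$ the intensity after analyte
addition.

`sensevo` implements the full screening loop used to improve such a sensor
for serotonin (5HT): enumerate every variant at exactly three substitutions
from a parent (22,032 sequences for the 18-nt region), rank them with a
surrogate model ensemble, "measure" the top 20, promote the best, and
repeat. Because the package is an in-silico study, the wet-lab assay is
replaced by a synthetic sequence-to-response landscape calibrated to the
known behaviour of the original sensor.

## The mutant library

A library member differs from the parent at *exactly* `k` variable-region
positions, each substituted position set to one of the three non-parental
bases; flanks are never touched. For `k = 3` this gives
$\binom{18}{3}\,3^3 = 22{,}032$ sequences. A rule allowing "mutation to any
of A, C, G, T" would permit null substitutions and produce a different
count; the count-consistent exactly-`k` rule is the one implemented.
Position indexing is 1-based within the variable region (full-sequence
offset +6), which makes the known serotonin-selective variant L1-14 a
mutation at positions 4, 7 and 11, all to adenine:

```{r}
orig <- validate_sequence("CCCCCCAGCCCTTCACCACCAACTCCCCCC", "original")
l114 <- validate_sequence("CCCCCCAGCACTACACAACCAACTCCCCCC", "L1-14")
diff_positions(orig, l114)
```

Enumeration is exhaustive, never sampled, and returned in lexicographic
order so all downstream tie-breaking is reproducible byte-for-byte.

## The synthetic landscape

The wet-lab study measures biology and specifies no generative model, so
the ground truth here is a package design choice: an **additive
position-base model**. For each analyte, an 18 x 4 weight table (entries
drawn N(0, 0.15) under the landscape seed) assigns a response contribution
to every (position, base) pair; a sequence's plateau response is the sum of
its 18 contributions plus a calibrated per-analyte offset, clipped below at
-1 (fluorescence cannot fall below zero intensity). Sparse pairwise
epistatic terms (NK-style) can be switched on through
`epistasis_density` for harder test conditions; the default is 0 because
the observed pattern of recurring beneficial single-base changes (mostly to
adenine) in the wet-lab campaign is consistent with a largely additive
landscape.

Calibration pins the landscape to the known behaviour of the original
sensor through anchors solved exactly by the per-analyte offsets:

* `true_response(original, 5HT) = 0.949` — the original sensor's measured
  serotonin response;
* `true_response(original, 5HT) / true_response(original, DA) = 0.508` —
  its serotonin/dopamine selectivity (dopamine therefore responds *more*
  than serotonin for the original sensor, as observed);
* nominal responses for the unanchored panel analytes, chosen to mirror the
  reported qualitative panel: small for acetylcholine, GABA, glutamate and
  uric acid (0.03–0.06), and 2.0 for ascorbic acid, which is known to
  brighten ssDNA-SWCNT emission more than dopamine does.

Contradictory anchors (two different targets for the same sequence/analyte)
or a ratio anchor with a zero ratio raise an infeasibility error rather
than being averaged away. Re-calibrating a calibrated landscape is a
no-op.

`true_response` is the *plateau* (saturating-concentration) response.
Concentration dependence follows the Hill form with cooperativity 1 and a
per-(sequence, analyte) dissociation constant drawn log-normally around
10 µM (`kd_log_sd = 0.25`), the regime reported for these sensors; anchored
pairs override it (11.6 µM for the original sensor with both serotonin and
dopamine — using one K_d for both analytes keeps the measured 100 µM
selectivity ratio equal to the calibrated plateau ratio of 0.508). A
measurement at the 100 µM protocol concentration therefore reads
`0.949 * 100/(11.6 + 100) = 0.850` for the original sensor, not 0.949: the
anchors are plateau values and the protocol concentration sits just below
saturation.

### Spectra and noise

Simulated emission spectra are sums of four Gaussian peaks (stand-ins for
HiPCo chirality features) at 1000, 1120, 1202 and 1290 nm on a 950–1350 nm
grid. Only the 1202 nm readout peak responds to analyte, scaled by
$1 + \text{true\_response} \cdot c/(K_d + c)$. The peak widths (12 nm) and
spacings are chosen so the off-readout tails contribute less than $10^{-10}$
of the readout intensity at 1202 nm, which keeps the spectrum-derived
$\Delta F/F_0$ equal to the closed form to nine decimals — the pipeline
consistency the test suite asserts.

Measurement noise is multiplicative Gaussian per replicate
(`replicate = noiseless * (1 + eps)`, `eps ~ N(0, 0.05)`), in triplicate,
matching the assay protocol's replication; no replicate variances are
reported for the real assay, so the 5% figure is a package choice, set so
that late-round improvements of a few percent are statistically
indistinguishable on triplicates (the behaviour that motivates the
saturation test). Every measurement derives its RNG stream from a hash of
(noise seed, sequence, analyte, concentration), so panels and campaigns are
reproducible and independent of evaluation order.

## The surrogate ensemble

Screening 22,032 candidates per round is what the surrogate is for. The
ensemble mirrors the published screening stack's composition: **two
support-vector regressors** (radial-basis and sigmoid kernels) predicting
$\Delta F/F_0$ from a 72-bit one-hot encoding of the variable region, and
**nine small binary classifiers** (single-hidden-layer networks of widths
4/6/8, each with its own seed) voting "high response" vs "low response".
The published stack's trained weights, CNN architectures and experimental
training corpus are not public; the claims of this package are about the
*screening procedure*, so the surrogates are retrained each round on a
seeded sample of landscape-labelled sequences (400 by default; a frozen
ensemble can be passed to mimic a pre-trained regime).

Per sequence the ensemble reports `pred_min`, `pred_max` and the ranking
indicator `mean_r` (the mean of the regressor outputs), plus the nine
votes. The "high response" training label threshold is the top quartile of
training labels (config-overridable); the published description does not
state a consistency rule, so the implemented rule is a majority vote.
`select_top_k` sorts by `mean_r` (ties broken lexicographically), skips
candidates the classifier consensus rejects, and promotes the next-ranked —
so the selection always returns `min(k, eligible)` records.

An **oracle mode** replaces the regressors with the landscape function
itself; it is used in tests to separate selection-machinery errors from
surrogate errors (with the oracle, top-20 selection must equal the
brute-force top-20).

## Dose-response fitting

Concentration curves use the seven protocol concentrations
0.1, 1, 5, 10, 30, 70, 100 µM and are fit with the Hill equation

$$\Delta F/F_0 = (\Delta F/F_0)_{max}\frac{c^n}{K_d^n + c^n}$$

by bounded Levenberg–Marquardt least squares ($K_d \in (0, 10^4]$ µM,
$n \in (0, 10]$, tolerances $10^{-12}$), initialised at the concentration
nearest half-maximum with $n_0 = 1$. The typeset source equation reads
"$K_d + c^n$" (a bare $K_d$); at $n = 1$ — the regime of every reported
fit — the two forms coincide, and the dimensionally consistent $K_d^n$ form
is the default, with the literal variant available via `form = "literal"`.
Convergence is reported honestly through a flag, never assumed.
Normalizing a curve by its maximum response rescales only
$(\Delta F/F_0)_{max}$; K_d and n are invariant, which the tests verify by
refitting.

```{r}
cc <- c(0.1, 1, 5, 10, 30, 70, 100)
fit_hill(dose_response_curve(cc, hill_model(cc, kd = 6.6, n = 1, dff0_max = 1)))
```

## The evolution driver

`run_round` chains the pieces: enumerate, screen, select 20, simulate
triplicate measurements (serotonin only for the sensitivity objective;
serotonin *and* dopamine for selectivity), promote the best. The
selectivity statistic is the ratio of triplicate means (not the mean of
per-replicate ratios), matching how the assay's ratio is defined on
averaged intensities; per-replicate ratios are retained for the saturation
test. The parent is re-measured each round so fold-improvements are
within-round comparisons. Saturation between consecutive round bests is
judged by a two-sided Welch t-test at alpha = 0.05 — the
minimal-assumption choice for n = 3 with unequal variances; early stopping
is off by default (the study ran a fixed number of rounds and judged
saturation post hoc).

## What the simulation does and does not show

The generator reproduces the *structure* of the study — library sizes,
protocol concentrations, triplicates, anchored responses and K_d values,
Hill-shaped titrations — so a passing suite demonstrates that the
screening, selection, fitting and saturation logic are correct and
reproducible. It does not validate the surrogate against real
sequence-photophysics (the synthetic landscape is far smoother than
reality unless epistasis is enabled), does not model solvatochromic
shifts, chirality mixtures or exciton physics, and the noise level is
assumed, not measured. On the additive default landscape the evolution
keeps finding improvements for more rounds than the wet-lab campaign did;
saturation there reflects assay biology the generator does not emulate.

## Problem sizes and numerical choices

The shipped analyses and tests run the full 22,032-member library for
enumeration, oracle screening and ranked selection; surrogate training uses
400 labelled sequences per round (500/200 train/test splits in the
correlation tests); Monte-Carlo checks use 500 noisy Hill fits, 1000
saturation draws and 2000–4000 measurement seeds. Degenerate inputs fail
loudly with typed conditions: non-ACGT bases, broken flanks, contradictory
anchors, unknown analytes, zero baselines, zero dopamine response,
all-identical training labels, sub-triplicate saturation tests.
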