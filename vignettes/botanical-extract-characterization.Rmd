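---
title: "Characterizing botanical extracts with CAD, UV and HRMS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Characterizing botanical extracts with CAD, UV and HRMS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(botanicad)
library(dplyr)
```

## The problem

Safety assessment of a botanical extract under the threshold of
toxicological concern (TTC) framework needs two things for every
constituent down to a small fraction of the material: *how much is there*
and *what is it, at least at the level of functional groups*. Neither of
the two classic LC detectors answers both. UV absorbance and electrospray
MS response vary wildly between compound classes, so they cannot
quantitate constituents for which no authentic standard exists; and a
universal detector cannot identify anything.

botanicad implements the computational side of a multi-detector answer: a
single UHPLC separation feeds a charged aerosol detector (CAD), whose
signal tracks analyte *mass* largely independent of structure, together
with UV and a high-resolution Q-TOF. Every CAD peak is quantitated as a
percentage of the total CAD signal; high-resolution MS features are
grouped into analytes, given molecular formulas with an isotope-fit
score, and correlated back to the CAD peaks to produce a constituent
report with per-record confidence tiers. The design target is the
characterization of a standardized *Ginkgo biloba* leaf extract: 83 CAD
peaks down to 0.05% of the total signal, with roughly 10% of the signal
unidentified and no single unknown above 1.2%.

## Relative quantitation by CAD

Analyte *i*'s relative amount is

$$\mathrm{pct}_i = 100 \cdot \frac{A_i}{\sum_j A_j},$$

where $A_i$ is the baseline-subtracted peak area. The total is the sum of
*detected peak* areas, not the raw trace integral: botanical runs often
sit on a broad hump of chromatographically unresolved material (tannins),
which is deliberately excluded from the denominator. The baseline that
separates peaks from that hump is an asymmetric-least-squares (Whittaker)
smoother: a second-difference penalty `lambda` (default `1e9` per sample)
makes the fit stiff over hundreds of samples, and asymmetric weights
(`p = 0.001` for points above the fit) pin it to the lower envelope. Two
numerical details matter in practice and are part of the package's
definition of the method:

* after the asymmetric iteration converges, points clearly above the
  provisional baseline (> 3 noise MADs) are masked out and the remaining
  points are refit with unit weight. This removes both the smoothing
  undershoot next to tall peaks and the downward bias that pure
  asymmetric weighting has inside noise;
* the signal is median-centered before solving and each solve gets two
  steps of iterative refinement — at `lambda = 1e9` the penalized system
  loses several digits otherwise, which shows up as spurious ripples
  around isolated peaks.

Peak detection runs on a lightly smoothed copy of the residual
(Savitzky–Golay, 9-sample window): apexes are local maxima, adjacent
apexes separated by a valley shallower than 3 smoothed-noise MADs are
merged (a noisy peak top is one peak), and bounds extend valley-to-valley
with a fall-back at the baseline re-crossing. The signal-to-noise ratio
is `height / noise` with height the smoothed residual maximum inside the
bounds and noise `1.4826 ×` the median absolute deviation of the smoothed
residual over peak-free regions — i.e. S/N as a chromatographic
integrator measures it on the processed trace, which is the definition
under which the 0.05%-at-S/N-3 detection floor is achievable. Areas are
integrated trapezoidally on the *unsmoothed* residual. The 0.05%
relative-area reporting floor is applied in a second pass once the total
detected signal is known.

USP system-suitability shape metrics are measured per peak at 5% and 10%
of the baseline-subtracted apex height with linear interpolation between
samples: asymmetry factor $A_f = b_{10}/a_{10}$ and tailing factor
$T = (a_5 + b_5)/(2a_5)$.

## Exact-mass chemistry

The package pins a NIST/CODATA-derived isotope table (masses and natural
abundances for H, C, N, O, F, Na, Mg, P, S, Cl, K, Ca, Br, I) so every
computation is bit-reproducible; `element_table()` accepts a YAML
override. All charged-species arithmetic includes the electron mass
(~0.55 mDa per charge — material at low-ppm accuracy):

$$m/z = \frac{n \cdot M + m_\Delta - z\, m_e}{|z|}$$

for an adduct with `n` M-units, atom delta $\Delta$ and signed charge
`z`. The vocabulary covers the ions seen in practice for plant extracts:
`[M+H]+`, `[M+NH4]+`, `[M+Na]+`, `[M+K]+`, `[M+2H]2+`, `[2M+H]+`,
`[M-H]-`, `[M+HCOO]-` (formate, modeled as +CHO2 plus an electron),
`[M-2H]2-`, `[2M-H]-`.

Isotope envelopes are exact multinomial convolutions over the element
distributions, aggregated at nucleon resolution (A, A+1, A+2, ...) with
abundance-weighted centroid masses — the resolution at which a Q-TOF
actually sees the envelope; fine structure is never exposed. The
implementation convolves per-element distributions by binary
exponentiation; the test suite checks it against an independent
polynomial-expansion oracle to 1e-6 in both abundance fraction and mass.

Ring-and-double-bond equivalents use the standard valence convention
(halogens count as H, P as N, divalent O and S contribute nothing):
`DBE = nC - (nH + nX)/2 + (nN + nP)/2 + 1`.

## Formula assignment and the isotope-fit score

Candidate formulas for an observed ion are enumerated exhaustively within
element bounds (defaults C 0–100, H 0–150, N 0–6, O 0–40 — the
CHNO-dominated space of flavonoid glycosides, terpene lactones and alkyl
phenols; S and P are opt-in). The search grids the non-hydrogen elements
and solves the hydrogen count from the mass residual, which is exact
because 1 Da hydrogen spacing dwarfs any ppm-scale tolerance. Candidates
must have DBE ≥ 0, integer DBE and nitrogen-rule parity (singly charged
even-electron ions only; toggleable), and H ≤ 2C + N + 2.

Each candidate is scored 0–100 against the observed envelope:

$$\mathrm{score} = 100\,(w_m S_\mathrm{mass} + w_a S_\mathrm{abund}
  + w_s S_\mathrm{spacing}),$$

with Gaussian kernels on the three deviation classes: ppm error of the A
peak, relative-abundance deviations of A+1…A+K (K = 2 by default), and
adjacent-peak spacing deviations. Defaults are weights 0.4/0.4/0.2 and
kernel widths 5 ppm, 10 abundance points, 0.002 Da; a missing observed
A+k contributes its worst-case deviation capped at 3 kernel widths. A
score of 90 or above is labeled confident. These weights and widths are
this package's definition — vendor formula-generation scores are
proprietary — and are fully configurable. Ranking is by score, then
|ppm|, then fewer heteroatoms, then Hill order.

A caveat the package states openly: with 2 ppm mass noise and 5%
abundance noise, random CHNO formulas up to C50 are recovered rank-1
about 85% of the time, not more. The failures are high-mass ions where a
rival inside the 5 ppm window (typically trading ~4 C + 4 H for 6 N, a
~3 mDa difference) lands closer in mass than the truth after noise, while
the A+1/A+2 abundance differences (~2 points) are the same order as the
abundance noise. No scorer restricted to A…A+2 resolves these; the
package keeps the published kernel defaults rather than pretending
otherwise.

## From spectra to analytes

Centroided spectra (mzML via mzR, or the package's plain JSON format;
profile data are rejected) are clustered into m/z channels, split into
contiguous scan runs (≥ 3 consecutive scans, ~0.6 s at 5 Hz — far below
chromatographic peak widths), and co-apexing runs spaced by `1.00336/z`
Da are merged into deisotoped features with charge assignment (z ≤ 2 by
default). Features whose implied neutral masses agree within tolerance
and whose apexes fall within 0.05 min are grouped into analytes, greedily
from the most intense feature, the adduct hypothesis explaining the most
features winning and ties broken by smallest neutral-mass disagreement.
Unexplained features stay as singleton groups under the polarity's
default adduct. In-source fragments are not modeled. Positive and
negative acquisitions are separate runs; grouping across polarity happens
at the neutral-mass level.

## Fusion and the report

Detector time offsets (post-column split transit) are constant per
detector pair and calibrated as the median apex difference over matched
standards. An analyte group is assigned to the CAD peak whose window
(± 0.1 min margin) contains its offset-corrected apex; overlaps resolve
to the nearest apex. Groups matching no CAD peak are reported as
"< 0.05%" — seen by MS, below the CAD floor. CAD area is *not*
apportioned among coeluting analytes; they are reported jointly under one
peak number, since MS response is structure-dependent and any split would
be pseudo-quantitative. Extra MS signals below 10% of a peak's top group
set a low-level flag instead of raising the analyte count.

Confidence tiers per record: `standard_match` (retention time + formula
agree with an authentic standard), `proposed` (confident formula plus
external annotation text — the package deliberately does not automate
literature or MS/MS interpretation), `formula_only`, and `unknown_no_ms`.
For the summary statistics a record counts as *unidentified* when it has
no proposed name and no standard match — a bare formula does not make a
constituent identified for TTC purposes, though a configuration switch
flips that interpretation.

## The synthetic extract generator

`simulate_extract()` renders a ground-truth constituent list into the raw
inputs of the pipeline: exponentially modified Gaussian CAD peaks (areas
proportional to mass fractions; EMG so the USP metrics are non-trivial)
on an optional broad Gaussian hump, with additive Gaussian noise, sampled
at 10 Hz; and centroid spectra at 5 Hz containing each constituent's
adduct envelopes with optional per-centroid ppm and abundance jitter.
Default noise is anchored to the reporting floor: a hypothetical peak at
0.05% of the total area would have apex S/N 10 — a clean acquisition.
The generator does not emulate in-source fragmentation, detector
saturation, retention drift, or solvent-composition-dependent CAD
response (no functional form exists for the latter; the configuration
keeps a hook). Passing tests on this generator therefore demonstrates
the pipeline's correctness on resolved, well-behaved signals, not
robustness to every artifact of real acquisitions.

The packaged transcription of the reference ginkgo characterization
(`table1_fixture()`: 83 CAD peaks, 113 analyte records with names,
formulas, adduct annotations and tiers) anchors structural tests. Its
per-peak percentage column is empty — the source's supplementary
percentages are not distributed — so `table1_synthetic_percentages()`
provides a clearly synthetic allocation that respects the published
summary constraints (every peak ≥ 0.05%, unidentified peaks totalling
10% with none above 1.2%, standards weighted double among the rest).
Summary-statistic checks against that allocation exercise the tier and
reporting machinery, not the original measured values.

## Validation experiments and problem sizes

Two packaged experiments reproduce the method's headline numbers at desk
scale and are run by `scripts/acceptance.R`:

* `detection_floor_experiment()` — 20 seeded chromatograms, five major
  peaks plus minors at √2-spaced relative areas from 0.05%, noise fixed
  so the 0.05% minor has true apex S/N = 3; reports the smallest area
  detected in ≥ 19/20 replicates. Detection uses `min_snr = 3` with the
  reporting floor disabled: at exactly the floor boundary the area rule
  censors half of all at-floor peaks regardless of detectability, so
  leaving it on would measure the reporting rule, not the detector.
* `formula_recovery_experiment()` — random CHNO formulas, simulated
  protonated envelopes at 2 ppm / 5% noise, rank-1 recovery rate.

Test problem sizes (20-replicate floor experiments, 20-constituent
recovery runs, 25–100-formula recovery samples, one 83-peak full-length
chromatogram) were chosen as the smallest sizes at which the statistics
stabilize; all tests run deterministically under fixed seeds.

## Known limitations

* Coeluting analytes share one CAD percentage; the optional EIC-ratio
  split is heuristic and labeled non-quantitative.
* UV data are carried as presence flags only; no spectral similarity is
  computed.
* The isotope-fit score is a surrogate with published defaults, not a
  reimplementation of any vendor score.
* Charge states above 2 and inorganic cluster series (e.g. metal-formate
  repeats) are representable as adduct entries but not searched for
  automatically.
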