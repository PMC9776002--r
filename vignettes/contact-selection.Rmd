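---
title: "Beta-guided monopolar contact selection from bipolar LFP surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Beta-guided monopolar contact selection from bipolar LFP surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(detecr)
```

## The problem

Subthalamic beta-band activity (13--35 Hz) is the best-established
electrophysiological marker of the akinetic--rigid parkinsonian state, and
it concentrates spatially near the stimulation sites that give the best
clinical response. Chronically implanted sensing stimulators can record
local field potentials at rest from all contact pairs of a directional lead
(a "survey": 15 bipolar channels for an 8-contact lead, sampled at 250 Hz
for about 20 s). But therapeutic programming needs a *monopolar* answer --
which single contact to stimulate -- and a bipolar recording cannot be
attributed to either of its two contacts directly.

`detecr` implements a fully automated selection pipeline that bridges this
gap: it re-references the bipolar survey onto per-contact "monopolar"
spectra by distance-weighted averaging, quantifies beta activity on the
flattened (1/f-removed) spectra, and ranks first the four stimulation
levels and then the three directional contacts of the winning level.

## The model

### Distance-weighted monopolar spectra

For a contact $c$, every bipolar channel involving $c$ carries a mixture of
the activity at $c$ and at its partner contact. The package averages the
Welch spectra of all $n$ channels involving $c$, weighting each by the
inverse distance to the partner:

$$\mathrm{PSD}_{\mathrm{weighted}}(f) \;=\;
  \frac{\sum_{i=1}^{n} \mathrm{PSD}_i(f)\, d_i^{-1}}
       {\sum_{i=1}^{n} d_i^{-1}},$$

where $d_i$ is the Euclidean distance (mm) between the center of $c$ and
its partner in channel $i$. Nearby partners -- which share more local
signal -- are weighted up; the scheme is the lead-geometry analogue of a
Laplacian re-reference. Distances come from a configurable geometric model
of the lead (`lead_geometry()`): ring centers on the shaft axis, segment
centers on the cylinder wall, registered dialects for the common 0.5 mm and
1.5 mm inter-level gaps (center spacing 2 mm and 3 mm; contact height
1.5 mm, diameter 1.27 mm). The hardware vendor does not publish a survey
montage definition beyond "15 combinations"; the package adopts the only
15-channel montage the device records: 6 ring/level pairs (the two middle
levels sensed in *ring mode*, i.e. all three segments tied), 6 intra-level
segment pairs, 3 inter-level segment pairs. Ring-mode levels are treated as
virtual contacts on the shaft axis; their monopolar spectra average every
channel involving any segment of the level, with $d_i$ measured from the
level's axial center (intra-level pairs use the lead radius, the distance
from the axis to the contact surface).

Whether level-to-segment distances use the full 3-D distance or only the
axial component is genuinely open; the package uses 3-D (the physically
meaningful separation) and exposes `distance_mode = "axial"` for
sensitivity analyses.

### Spectral estimation

`welch_psd()` reproduces the survey-standard estimate: 1 s hamming windows,
50% overlap, per-segment mean removal, zero-padding to a 256-point FFT
(the 250-sample window falls below it), one-sided density scaling, averaged
modified periodograms interpolated onto the fixed 1--100 Hz grid at
1 Hz/bin. All downstream math lives on this grid. The convention is fixed
and checked against an independently coded definitional oracle in the test
suite.

### Aperiodic (1/f) removal

Neural spectra ride on a broadband power-law background that must be
removed before oscillatory power is compared across contacts.
`fit_aperiodic()` fits $\log_{10} P(f) = b - \chi \log_{10} f$ by two-pass
least squares: an initial fit, then a refit using only bins at or below the
initial fit, so peaks cannot drag the background up (the robust scheme used
by spectral-parameterization tools). No knee term is fit: at 20 s of data
on a 1 Hz grid a knee is rarely identifiable, and the robust pass already
discounts the spectral-leakage lift of the lowest bins. The fit range
defaults to the full 1--100 Hz grid; recordings with heavy drift or line
noise can narrow it (e.g. 3--45 Hz) via `detec_config(fit_range = )`.
Flattening is linear: $\mathrm{flat}(f) = P(f) - 10^{b - \chi \log_{10} f}$.

### Peak detection and the strategy switch

A hemisphere is analyzed in *peak mode* if at least one of its 10 screened
monopolar configurations (2 rings, 2 ring-mode levels, 6 segments) shows a
qualifying beta peak; otherwise *low-beta mode* uses band power at
13--20 Hz. A local maximum of the flattened spectrum inside 13--35 Hz
qualifies as a peak when

1. its value exceeds the fitted aperiodic curve, and
2. its topographic prominence is at least the fit's root-mean-square error
   measured on the linear power scale.

The linear-scale RMSE is the natural output of a least-squares fit to the
raw spectrum and is dominated by the high-power low-frequency end of the
fit range. This gives the criterion its discrimination: in-band noise
wiggles (a few percent of local power) stay far below it, while a genuine
beta peak of near-background magnitude clears it. The decision is exactly
invariant to amplitude scaling, since both prominence and RMSE scale
together. With several qualifying peaks, low-beta candidates (13--20 Hz)
are preferred and the most prominent wins; hemispheres whose candidate
frequencies disagree by more than 3 Hz carry a QC flag. Band edges are
inclusive throughout.

### Normalized activity and the two-step ranking

In peak mode, activity is the mean flattened power within $\pm 2$ Hz of the
consensus peak (a 5-bin window, robust to 1-bin jitter; configurable). In
low-beta mode it is the mean flattened power over 13--20 Hz. Either score
is divided by the total *positive* flattened power over 5--95 Hz of the
same spectrum. This normalization is the package's own documented choice
(the device-trial appendix formulas are not public): it makes scores
dimensionless and insensitive to amplifier gain and electrode impedance,
which is what pooling across contacts and hemispheres requires. It is
swappable via `detec_config(norm_range = )`.

Ranking is two-step: the four level configurations are ranked ascending
(rank #4 = highest activity) and the winner chosen; if a ring wins, the
neighboring directional level is analyzed instead (level 0 → 1, level
3 → 2); the three segments of the analyzed level are then ranked (rank
#3 = highest) and the winner proposed as the stimulation contact. Exact
ties are broken deterministically (more ventral level, alphabetically first
segment) and flagged -- continuous data essentially never tie, but
degenerate inputs (e.g. an all-zero survey) rank reproducibly with QC
flags rather than erroring.

## The synthetic survey generator

Patient recordings are not redistributable, so `simulate_survey()` provides
a ground-truth test substrate. It emulates:

* a spatially localized beta source near the lead: a point source whose
  potential at contact $c$ is
  $A\,\mathrm{env}(t)\sin(2\pi f t + \varphi)\, / \,d(c,\mathrm{src})^\alpha$
  with $\alpha = 1$ (ideal quasi-static monopole, configurable),
  slow sinusoidal amplitude modulation (depth 0.3, 0.4 Hz) standing in for
  beta waxing and waning;
* contact-local $1/f^\chi$ Gaussian background ($\chi = 1.5$, typical for
  subcortical LFP) plus a small white floor;
* the bipolar montage: each channel is the difference of its endpoint
  potentials; ring-mode levels carry the mean of their three segments;
* optionally, a common-mode ECG-like pulse train (150 ms Ricker pulses at a
  cardiac rate) with small random per-channel residuals, for exercising the
  QC screen.

SNR is defined as the ratio of beta-band source power to beta-band
background power at the contact nearest the source, and is realized exactly
per simulation by calibrating the source amplitude against the generated
noise. The reference SNR is frozen at 4 with study tiers 0.5 / 1.5 / 4
(`snr_tiers()`): 4 corresponds to a clear but not extreme beta peak, and
the tiers bracket the steep part of the recovery curve.

What the generator does *not* emulate: volume conduction through
inhomogeneous tissue, impedance differences between ring and segment
contacts (a known caveat of distance-only weighting), multiple simultaneous
sources, movement artifacts, and non-stationarities beyond the slow
envelope. Passing recovery tests therefore demonstrate the pipeline's
internal correctness and its behavior under the stated forward model, not
clinical performance.

## Numerical choices and degenerate inputs

* All simulations and analyses are deterministic given the seed; the
  weighted average iterates channels in canonical montage order so results
  are bit-identical under channel reordering.
* An all-zero or constant channel produces a zero spectrum; the aperiodic
  fit refuses it, the configuration's flattened spectrum is set to zero,
  scores are 0 and the selection carries tie and degenerate QC flags.
* A normalization constant that is not strictly positive yields score 0
  with a QC flag rather than an error.
* `spearman_rank()` uses average ranks for ties; its p-value is an exact
  full enumeration for n ≤ 9 and the t approximation above that.
* The mirror of right-hemisphere coordinates in the sweet-spot analysis is
  a sign flip of x, a documented simplification of nonlinear template
  mirroring (which needs imaging infrastructure out of scope here).

### The high-SNR limit

Because the activity score is scale-free, two contacts whose spectra are
exact scaled copies of each other score identically. In the exact
noiseless limit every contact sees a scaled copy of the same source
spectrum, so ranking is undefined there; discrimination comes from the
background contribution to the normalizer. In practice recovery is flat
and high (~95% correct segment) from SNR ≈ 1 up to SNR ≈ 10^3 and only
degrades in the regime where background power is numerically negligible --
far beyond physiological beta elevations. The recovery studies therefore
probe SNR 0--64.

## Problem sizes used in the shipped studies

The test suite and `scripts/acceptance.R` run: 50-seed Welch oracle
comparisons; aperiodic recovery on 5 analytic exponents and 50 simulated
noise channels; the recovery grid of 6 source positions × 100 seeds at each
of the 3 SNR tiers; a 300-run silent-source chance study; and a 100-seed
score-vs-distance monotonicity study. One full survey analysis takes tens
of milliseconds, so the whole battery runs in a few minutes on one CPU.

## Known limitations

* The distance-weighting assumes purely geometric signal mixing; impedance
  mismatch between rings and segments is not modeled (the two-step design
  -- levels first, then segments within a level -- partly insulates the
  final choice from it).
* Beta is the only biomarker used; tremor-dominant phenotypes and
  higher-frequency markers are out of scope.
* The normalization stands in for unpublished formulas and, being
  scale-free, saturates at extreme SNR (see above).
* The evaluation module compares selections against clinical monopolar
  review scores supplied by the user; it ships no patient data and makes no
  claims about clinical efficacy.

## A worked example

```{r example}
geom <- lead_geometry("sensight-short")
sim <- simulate_survey(source_model(source_near_segment(geom, "2B")),
                       noise_model(), geom, snr = 4, seed = 1)
res <- run_detec(sim$survey)
res
```

The report can be serialized with `write_report()`, and a cohort of reports
compared against clinical scores with `match_rates()` and
`sweetspot_distance_analysis()`.
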