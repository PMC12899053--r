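---
title: "Methods: spectral variability analysis of surface EMG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral variability analysis of surface EMG}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(emgspecvar)
```

## Scope and model

`emgspecvar` measures how reproducible the *shape* of the surface-EMG power
spectrum is across repeated isometric contractions — within a participant
(intra-subject) and between participants (inter-subject) — and whether
forearm posture (supinated open-hand SP vs neutral grip NT) modulates that
reproducibility in the elbow flexors (biceps brachii BB, brachioradialis
BR).

The statistical object is the normalized, smoothed power spectrum of one
contraction. For participant $s$, condition $c$ (muscle × posture) and
repetition $i$, the pipeline produces $\tilde P^{(i)}_{s,c}[f_m]$ on a
common frequency grid; the participant's reference spectrum is the mean
over repetitions,

$$\bar P_{s,c}[f_m] = \frac{1}{n_\mathrm{rep}}\sum_i \tilde P^{(i)}_{s,c}[f_m],$$

and variability is quantified with Minkowski distances
$D(x,y) = \big(\sum_k |x_k-y_k|^l\big)^{1/l}$ for $l = 1$ (Manhattan), $2$
(Euclidean) and $\infty$ (Chebyshev): each repetition against its own
reference (intra), and every unordered pair of references within a
condition (inter).

## Processing chain and its assumptions

The per-recording chain is fixed: notch → zero-pad → Hann taper → FFT →
moving-trend-filter smoothing → normalization → common-grid interpolation.

**Notch.** A second-order IIR notch at 50 Hz with quality factor 35
(bandwidth $f_0/Q \approx 1.4$ Hz), applied forward–backward. The two-pass
application has zero phase, doubles the stop-band attenuation and halves
the bandwidth relative to a single pass; narrowband line residue is the
only contamination it is meant to remove. Because the notch is narrow, its
transients decay over roughly a second — harmless for 5 s contractions.

**Zero-padding and taper.** All segments of a recording are padded to the
longest segment's length $N$, giving one frequency grid
$f_m = m\,f_s/N$ per recording. The Hann taper is applied *after* padding:
the chain follows the stated processing order literally even though
tapering before padding is the more common convention; with
boundary-refined segments whose edges sit in rest intervals, the
difference is negligible.

**Moving trend filter (MTF).** The smoother fits, in every length-$K$
window covering a bin, an order-$p$ polynomial by least squares on
normalized coordinates $u \in [-1,1]$, evaluates it at the bin, and
averages the evaluations over all window positions ($p = 3$ by default).
The configured span of 180 bins is interpreted as $K = \lfloor 180/2
\rfloor = 90$ with the averaging sweep covering $\approx 2K+1$ bins; the
span-in-bins convention means the *bandwidth* of the smoother in Hz is
$\mathrm{span}\cdot f_s/N$, i.e. it adapts to the recording's segment
length. At the series boundaries windows are truncated and only truncated
windows retaining at least $p+2$ points enter the average; negative
smoothed power is clipped to zero (a linear-filter mode without clipping
exists for diagnostic use). Averaging shifted local fits — rather than
taking one centred fit per bin — gives a much flatter pass band and
stronger noise suppression, which is what makes single-contraction spectra
comparable without Welch averaging.

**Normalization.** Peak-power normalization ($\max \tilde P = 1$)
emphasises the dominant component; total-energy normalization
($\sum_m \tilde P = 1$) yields a probability-like shape descriptor.
Normalization operates on the *smoothed* spectrum, and is re-applied after
interpolation onto the common grid (0.5 Hz spacing on (0, 500] Hz, linear
interpolation) so the container invariants hold exactly on the final grid.
One guard bin above the band edge is kept before interpolation so the edge
itself remains interpolable for every segment length.

## Segmentation

Contractions are isolated on the summed two-channel trace (simultaneous
activation makes the channels approximately phase-synchronous, so summing
raises contrast). Candidate local maxima must satisfy three constraints:
topographic prominence ≥ 500 µV; inter-peak distance ≥ 0.35 s (conflicts
resolved in favour of the taller peak); and the peak's RMS-envelope value
must exceed the envelope minima towards both neighbouring peaks by
≥ 250 µV. The last rule is evaluated iteratively, discarding the lowest
offending peak and re-evaluating, so clusters of oscillation maxima inside
one contraction collapse onto the dominant peak. Segment boundaries are
the envelope minima (first index on ties) between consecutive surviving
peaks; the first and last segments extend to the recording ends, so the
segments partition the recording.

On a raw bipolar trace, prominence cannot separate within-burst maxima
(the trace crosses zero constantly, so every sizable maximum is
"prominent"); the neighbour rule carries that burden, and its reliability
is governed by the variance of the RMS-envelope estimate. Band-limited EMG
noise with corner frequencies near 60–140 Hz has a correlation time of
5–10 ms, so a 0.1 s envelope window holds only ~10–20 independent samples
and fluctuates enough on the contraction plateau to mimic
inter-contraction gaps. The package therefore defaults `rms_window_s` to
0.5 s — a standard contraction-detection smoothing scale that is still
several times shorter than the rest intervals which define the boundaries.
With the default generator, this recovers the exact repetition count in
every tested recording, where 0.1 s recovered it in only ~20%.

## The synthetic cohort generator

The generator emulates the acquisition protocol the analysis assumes, with
ground truth for every quantity the pipeline estimates:

* **Spectral shape**: colored Gaussian noise with relative PSD
  $G(f) = f_h^2 f^2 / \big((f^2+f_l^2)(f^2+f_h^2)^2\big)$ — the standard
  rational band-pass model of the sEMG spectrum (zero at DC, one broad
  peak, gradual high-frequency decline). Coloring is exact: white noise is
  filtered in the frequency domain by $\sqrt G$.
* **Contractions**: trapezoidal envelope (10% rise, 80% plateau, 10%
  fall), plateau RMS 400 µV per channel, nominal duration 5 s with ±5%
  uniform duration jitter (contractions only last *approximately* their
  nominal duration; without duration variation the zero-padding stage
  would be vacuous). Ten repetitions per task.
* **Rest intervals**: 2 s of bounded uniform noise plus a common 50 Hz
  sinusoid (2 µV) on both channels; the noise amplitude is scaled to
  `baseline_amp_uv − line_amp_uv`, so the composite rest signal respects
  the 5 µV baseline criterion of the acquisition protocol. Larger line
  amplitudes are configurable for stress-testing the notch.
* **Random effects**: participant-level corner-frequency offsets
  $\mathcal N(0, 8\ \mathrm{Hz})$ drawn once per participant (per muscle
  and corner — a multivariate subject effect, which is what makes
  inter-subject distances behave like multivariate deviation magnitudes),
  and repetition-level jitter with posture-specific SD —
  `c(SP = 5, NT = 10)` Hz by default. The 2× NT:SP contrast is the
  generator's built-in posture effect; its absolute scale sits in the
  physiologically typical 5–10 Hz range of repetition-to-repetition
  variability of sEMG spectral descriptors and is large enough that the
  jitter-driven component of the intra-subject distance is detectable
  above the single-contraction spectral-estimation noise floor. Condition
  means: BB 60/120 Hz, BR 70/140 Hz (SP), shifted +5 Hz in NT.
* **Reproducibility**: one cohort seed; per-recording substreams are
  derived deterministically, so enlarging a cohort never perturbs existing
  recordings.

What the generator does **not** emulate: motor-unit action-potential
trains, recruitment or firing-rate dynamics, fatigue-related spectral
compression, force fluctuations, electrode-placement effects,
non-stationarity within a contraction, or cross-channel crosstalk. Passing
pipeline tests on synthetic cohorts therefore demonstrates that the
*estimation machinery* recovers known spectral structure and group
contrasts — not that real sEMG satisfies the generator's assumptions.

## Inference choices

* **Pairing**: the intra-level SP-vs-NT comparison pairs participants by
  their mean repetition distance (the paired design's natural unit;
  repetition-level pooling is available via `aggregation = "pooled"`); the
  inter-level comparison pairs participant pairs, both postures being
  observed for every pair.
* **Signed-rank test**: zero differences are discarded (Wilcoxon's
  original method), tied absolute differences receive midranks; the exact
  null distribution is used for ≤ 25 untied differences, otherwise the
  normal approximation with continuity and tie corrections. Two-sided
  p-values throughout.
* **Distribution families**: normal, Laplace and Maxwell–Boltzmann, all
  with closed-form maximum-likelihood estimates (Maxwell:
  $\hat a = \sqrt{\overline{x^2}/3}$; its quantiles come from the
  $\chi^2_3$ law of $(x/a)^2$). The Maxwell model encodes the hypothesis
  that between-subject spectral deviations behave like magnitudes of
  multivariate Gaussian displacements.
* **Goodness of fit**: equal-probability binning under the fitted model —
  more stable than equal-width bins for skewed positive samples — with
  $n_\mathrm{bins} = \min(\max(5, \lfloor n/10 \rfloor), \lfloor n/5
  \rfloor)$ so each bin expects ≥ 5 observations, and degrees of freedom
  penalized by the number of estimated parameters. With parameters
  estimated by ML from ungrouped data the statistic is only approximately
  $\chi^2$; with the default bin counts the approximation is empirically
  near-nominal (type-I rate ≈ 5–7% in the package's calibration tests).

## Numerical details and degenerate inputs

* All-zero spectra cannot be normalized (error); empty peak sets yield an
  empty segment list with a warning, not an error.
* Envelope-minimum ties break to the first (leftmost) index —
  deterministic boundaries.
* The common-grid interpolation refuses to extrapolate.
* Segment-count mismatches against an expected repetition count are
  warnings collected into the run manifest, mirroring a recording-level
  quality-control step.
* Distances are computed on the common analysis band only; bins outside
  (0, 500] Hz never contribute.
* Sample standard deviations use the $n-1$ divisor; condition summaries
  pool all repetition distances of a condition.

## Problem sizes used in the test suite

The packaged tests exercise the full chain at reduced problem sizes chosen
to preserve the analysis' behaviour: shorter contractions (0.75–2 s) with
rests ≥ 0.5 s for unit tests, and — for the end-to-end posture-contrast
checks — 2 s bursts with the MTF span reduced proportionally (96 bins) so
the smoothing bandwidth in Hz matches the default configuration at default
burst length. Cohort-level checks run 15–33 participants across 20 seeds
at these sizes; single-recording checks (segmentation recovery, baseline
bound) run at the full default sizes. The acceptance script runs default
recordings and a 10-participant default cohort.

## Known limitations

* The MTF is quadratic-time in the span at the boundaries; spans beyond a
  few hundred bins become noticeably slower.
* The chi-square statistic's null distribution is approximate under
  ungrouped ML estimation (Chernoff–Lehmann); the df penalty brackets but
  does not remove the effect.
* `R`'s mixed-radix FFT slows down when a recording's reference length has
  large prime factors; the reference length is data-dependent by design
  (the longest segment), so run time varies between recordings.
* Segmentation assumes well-separated contractions with quiet rests; it is
  not an onset-detection method and will not handle overlapping bursts or
  high baseline activity.
* Inter-subject distance modelling needs realistic cohort sizes: with
  fewer than ~10 participants the equal-probability binning cannot satisfy
  its expected-count floor and the fits are skipped.
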