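---
title: "Models and estimators in halopol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and estimators in halopol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(halopol)
```

`halopol` implements the estimator chains used to quantify halophilic
adaptation of a DNA polymerase in four assay classes. This vignette states
each model, its assumptions, the tunable parameters, and the numerical and
design choices — including the ones where more than one defensible reading
existed and the package had to pick.

## Single-molecule flow-stretching kinetics

### Signal model

A bead tethered by a single DNA molecule reports primer extension as a
change in tether length. The measured extension (nm) of a reaction trace is

$$x(t) \;=\; \frac{s(t)}{c} \;+\; d(t) \;+\; \varepsilon(t),$$

where $s(t)$ is cumulative synthesis in bases, $c = 3.76$ b/nm is the
ssDNA-to-dsDNA calibration at the applied drag force, $d(t)$ is a slow
instrumental drift shared by every bead in the field of view, and
$\varepsilon$ is white Gaussian localization noise (default 2 nm per
0.5-s sample). Control tethers with no enzymatic activity carry only
$d + \varepsilon$, which is why `correct_drift()` subtracts the pointwise
mean of the *mean-centered* controls: centering ensures the subtraction
removes the drift shape, not the arbitrary tether offset.

$s(t)$ itself is piecewise linear: synthesis bursts with per-burst rate
$r \sim \mathcal N(\mu_r, \sigma_r)$ and length
$L \sim \mathrm{Exp}(\lambda)$ alternate with pauses (no synthesis),
interpreted as polymerase exchange events. The generator
(`simulate_traces()`) draws this process directly and emits the exact burst
and pause boundaries as a truth sidecar, so any downstream estimator can be
scored without reading generator internals.

Three generator choices deserve explanation:

* **Pause durations are offset-exponential** (3 s floor + exponential
  excess, preserving the requested mean of 5 s). The pause *detector* is
  defined on a 6-sample minimum window at 0.5-s sampling, i.e. a 3-s floor;
  pauses shorter than that are undetectable *by definition* and would merge
  adjacent bursts, so simulating them would measure the detector's stated
  blind spot rather than the estimators. The floor and mean are parameters
  (`pause_duration_min`, `pause_duration_mean`); setting the floor to 0
  restores a plain exponential.
* **The final burst of each trace is clipped at the template end** (7,249
  bases by default) and flagged censored in the truth table. Every
  uncensored emitted length is therefore an untruncated exponential draw.
* **Drift is a sum of three low-frequency sinusoids** with amplitudes
  summing to `drift_amplitude`, shared identically across all traces of an
  experiment — the structure that control-trace subtraction assumes.

### Pause detection

The operational pause definition — at least 6 consecutive samples with no
change in DNA length, amplitude fluctuations below 3× the noise sd — is
applied window-wise: every 6-sample window whose maximum deviation from its
own mean is under $3\hat\sigma$ marks its samples as paused, and
overlapping windows merge into maximal runs. Two statistics were
considered for "fluctuation":

* *total range of the run*: rejected, because the expected range of even a
  6-point pure-noise window is $2.53\sigma$ — so close to the $3\sigma$
  threshold that genuinely flat windows fail ~30% of the time — and the
  expected range grows like $\sigma\sqrt{2\ln n}$, so long plateaus can
  *never* pass as a single run and fragment into zero-slope artifacts;
* *maximum deviation from the window mean*: adopted; its expectation for
  6-point noise is $1.27\sigma$, so plateau windows pass with probability
  ≈ 0.9997 while a single 0.5-s synthesis step at the default study
  conditions sits ≈ 26σ above the threshold and fails decisively.

Two refinements handle bursts shorter than the sampling interval, which
leave no sample on their ramp and would otherwise fuse the flanking
plateaus into one "pause" spanning a clear step: a detected run is split
wherever an adjacent-sample jump exceeds `jump_k` = 6× the noise sd, and
likewise at two-sample level changes (a burst spread across two intervals),
dropping the mid-ramp sample. The 6σ jump threshold keeps the false-split
probability per experiment below ~0.1; bursts below ≈ 6σ ≈ 50 bases remain
physically invisible, which leaves a small (+3–5%) upward bias in the
recovered processivity, quantified below.

The noise sd is estimated per trace as
$\mathrm{MAD}(\Delta^2 x)/\sqrt6$. Second differences cancel any locally
linear signal — pause plateaus *and* constant-rate ramps — so the estimate
is insensitive to slope; first differences would be a ~50/50 mixture of
noise and ~230-base synthesis steps at the default duty cycle, breaking
the MAD's robustness assumption.

### Population fits

Per-burst rates are the least-squares slopes over each segment's samples
(segments under 3 samples are excluded from the rate fit, with a message).
The Gaussian "fit" is the maximum-likelihood one — sample mean and sd, with
uncertainty $s/\sqrt n$ — rather than a least-squares fit to a histogram,
which would add binning choices without changing the estimand. Burst
*lengths* are measured plateau-to-plateau (last sample of the preceding
pause to first sample of the following pause), which removes the
$\sim r\Delta t/2$ per-boundary truncation that first-to-last-sample
differences suffer. The exponential mean is the MLE; the final burst of
each trace is treated as right-censored (template or acquisition end) and
enters the censored MLE $\hat\lambda = \sum_i L_i / n_\text{complete}$,
the standard renewal-process estimator. Censored bursts stay in the rate
fit, where a truncated ramp still gives an unbiased slope.

**Accuracy at the study scale.** With 26 traces (~110 bursts, ~83 usable
rate segments) the recovered rate is accurate to a few bases/s
(replicate sd ≈ 2–4 b/s). The processivity estimator is a different story:
its sampling sd is $\lambda/\sqrt{n} \approx 10\%$ at $n \approx 85$
complete bursts — an inherent property of the exponential MLE at this
sample size, not of the implementation (the ground-truth-side MLE shows
the same spread). Individual replicates should be expected to land within
10% of the true mean only about two-thirds of the time; the test suite
therefore checks the estimator on the median of replicate draws.

### Bead localization

`localize_bead()` fits a symmetric 2-D Gaussian (center, sd, amplitude,
offset) by Levenberg–Marquardt least squares, with moment-based starting
values taken from a 17-pixel region around the brightest pixel. A frame
whose fitted amplitude does not exceed 3× the robust pixel noise (MAD)
returns a localization-failure signal rather than a coordinate. RMS error
on synthetic frames at 5% pixel noise is ≈ 0.04 px.

## Raman band decomposition

Spectra are modeled as a linear baseline plus pseudo-Voigt components

$$V(\nu) = A\,[\eta\,\mathrm{Lor}(\nu; \nu_0, w) +
           (1-\eta)\,\mathrm{Gau}(\nu; \nu_0, w)],$$

both shapes area-normalized and sharing center $\nu_0$ and FWHM $w$.
`fit_bands()` fits six components over 1500–1800 cm⁻¹ with centers bounded
±10 cm⁻¹ of the canonical positions (1550/1580/1610/1650/1670/1680),
FWHM in [5, 60] cm⁻¹ and areas ≥ 0, using five jittered multi-starts
(deterministic: the jitter stream is privately seeded) and keeping the
best residual. Secondary structure normalizes the three *structural* band
areas (α 1650 / coil 1670 / β 1680) to percentages — side-chain bands are
excluded from the denominator — with delta-method uncertainties from the
area covariance.

**The mixing fraction is fixed, not fitted, by default.** The coil and
β-sheet components sit 10 cm⁻¹ apart with FWHMs of the same order; if each
band's Gauss-Lorentz fraction is also free, the pair is nearly degenerate
and the coil percentage recovered from a 1%-noise spectrum scatters with
sd ≈ 5 points. Fixing the shape at the conventional 50:50 mix (the
standard reading of "Gaussian-Lorentzian mixed functions", and the
generator's default) restores identifiability: recovered coil percentages
then have sd ≈ 1.3 points and land within 3 points of the planted value in
19–20 of 20 replicates. `free_mixing = TRUE` restores the fully free fit.
Generator default FWHMs (18/16/14/16/14/12 cm⁻¹) are typical amide-region
component widths chosen once so that adjacent structural components are
resolvable.

The Tyr doublet fit applies the same machinery to two peaks over
800–880 cm⁻¹ (centers bounded 830 ± 8 and 850 ± 8 cm⁻¹). "Intensities"
are integrated areas, not peak heights. The ratio classifies the
phenolic-OH hydrogen-bonding state: below 0.9 "buried" (H-bonded to
carboxylates), 1.0–1.5 "exposed" (H-bonded to water), and the literature
overlap [0.9, 1.0) is reported as "ambiguous" rather than silently
assigned. An essentially zero 830-cm⁻¹ area (≤ 10⁻⁴ of the doublet total)
raises an undefined-ratio error.

## SPR steady-state affinity

Equilibrium responses follow the 1:1 Langmuir isotherm
$R(C) = R_\max C/(K_d + C)$, fitted by unweighted least squares
(instrument-software weighting is unknown; `weights = "relative"` is
available). $R_\max$ is bounded above at 500 RU by default, the expected
ceiling of protein responses on these surfaces, and overridable. When the
fitted $K_d$ exceeds 10× the top concentration the series never
approached saturation and $K_d$ is not identifiable from the data;
the fit returns `converged = FALSE` with a diagnostic instead of a number
that would be pure extrapolation. Noiseless series over the 10–600 nM
ladder are recovered to machine precision for any $K_d$ in the
identifiable range; at 2% multiplicative RU noise the median of 50
replicate fits is within ~1% of truth.

## Sequence halophilicity profile

Charge classes follow the adaptation literature exactly: acidic = {D, E},
basic = {R, K}; histidine is excluded and no pKa model is applied.
Percentages use only standard residues in the denominator (`X` is
tolerated and never counted). Domain profiles use 1-based inclusive
coordinates, the convention of domain-architecture figures. "Unique"
acidic residues are query positions with D/E whose aligned subject residue
is not acidic; a query residue aligned to a gap counts as unique by
default (an acidic insertion has no homologous counterpart), toggleable
with `gap_is_unique = FALSE`. Alignments are accepted as input (two gapped
strings from any standard global aligner); the package deliberately does
not choose an alignment algorithm. Disorder tracks are inputs on [0, 1]
with the conventional 0.5 call threshold; the package does not
re-implement a disorder predictor.

The sequence generator plants composition deterministically — counts are
rounded, so realized fractions match targets to 1/length — and applies the
acidic-in-disorder enrichment per tag (Asp and Glu separately), making the
planted overlap fractions exact up to rounding. Non-charged positions draw
uniformly from the 16 remaining residues: no composition beyond the charge
and hydrophobic classes is analyzed, so no further realism is modeled.

## What the synthetic data do and do not show

The generators reproduce the statistical structure each estimator assumes:
piecewise-linear trajectories with shared drift and white noise; spectra
that are exact sums of pseudo-Voigt bands on a linear baseline; exact
Langmuir responses; sequences with planted composition. Passing recovery
tests therefore demonstrates estimator correctness — not robustness to
real-data pathologies such as non-Gaussian tracking outliers, baseline
curvature or cosmic-ray spikes in Raman spectra, mass-transport or
rebinding artifacts in SPR, or disorder-predictor miscalibration. Those
effects are out of scope by design; the module boundaries (plain-text
tables in, JSON results out) are where such preprocessing would plug in.

## Problem sizes

The shipped analyses use 26 + 3 traces (halophilic set, ~110 bursts — of
which ~83 enter the rate fit, matching the published sample size) and
14 + 3 traces (reference set, ~75 bursts); 601-point spectra at 0.5 cm⁻¹;
7-concentration binding series with 50 noise replicates; and one
818-residue sequence. The full test suite runs in well under a minute on
one core.
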