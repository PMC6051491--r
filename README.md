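# halopol

Quantitative analysis chains for the biophysics of halophilic DNA
polymerase adaptation — written for researchers characterizing salt-adapted
enzymes with single-molecule, spectroscopic, binding and sequence-level
assays. Halophilic proteins stay soluble and active in molar salt by
coating their surface with acidic residues and trading rigid hydrophobic
packing for flexible, partly disordered structure; `halopol` implements the
estimators used to quantify those signatures in four data classes, each
paired with a seeded synthetic-data generator so every stage is verifiable
by parameter recovery without any instrument data.

## What it computes

**Flow-stretching replication kinetics.** A laminar flow stretches
bead-tethered DNA; primer extension converts ssDNA to dsDNA and lengthens
the tether. Trajectories sampled at 0.5 s are drift-corrected by
subtracting mean-centered control tethers, converted to synthesized
nucleotides with the calibration factor (3.76 b/nm), and segmented by the
operational pause rule — a pause is ≥ 6 consecutive samples with no change
in DNA length, amplitude fluctuations < 3× the noise sd. Per-segment
slopes form a Gaussian rate sample, fitted by maximum likelihood
(mean ± sd, uncertainty sd/√n); segment magnitudes follow a single
exponential whose mean is the processivity,

  P(L) ∝ exp(−L/λ),  λ̂ = Σ Lᵢ / n_complete

with the last burst of every trace treated as right-censored (template or
acquisition end). Bead positions themselves come from 2-D Gaussian PSF
fits (`localize_bead()`).

**Raman secondary structure and hydroxyl interactions.** The 1500–1800
cm⁻¹ region is decomposed into six pseudo-Voigt components
(η·Lorentz + (1−η)·Gauss sharing center and FWHM) near 1550, 1580, 1610,
1650, 1670 and 1680 cm⁻¹ (Trp indole, Ala+Gly, Tyr/Trp/Phe, α-helix,
random coil, β-sheet). Structure percentages normalize the three
structural band areas. The Tyr doublet ratio I₈₅₀/I₈₃₀ (integrated areas of
two peaks fitted over 800–880 cm⁻¹) reports the hydrogen-bonding state of
the tyrosine phenolic OH: ~0.9–1.5 solvent-exposed, ~0.7–1.0 buried.

**SPR steady-state affinity.** Equilibrium responses follow the 1:1
Langmuir isotherm R(C) = R_max·C/(K_d + C); `steady_state_fit()` recovers
K_d and R_max by least squares, flags non-saturating series, and
`subtract_reference()` removes bulk shifts.

**Sequence halophilicity profile.** Acidic (D+E) versus basic (R+K)
composition and the negative/positive ratio, globally and per domain;
bulky (F, I, L) versus small (G, A, S, T) hydrophobic classes; acidic
residues unique to a query relative to an aligned homolog; and the
fraction of those residues inside predicted disordered regions
(per-residue disorder probability ≥ 0.5).

## Worked example

```r
library(halopol)

sim <- simulate_traces(trace_sim_params(
  rate_mean = 460, rate_sd = 35, processivity_mean = 2000,
  noise_sd = 2, n_reaction_traces = 26, n_control_traces = 3,
  seed = 20260929))
res <- analyze_traces(sim)
res$rate
#> Synthesis rate: 457.7 +/- 3.8 bases/s (sd 34.5, n = 81 segments)
res$processivity
#> Processivity: 2045 +/- 213 bases (n = 118 segments, 26 censored)
```

The simulation planted a 460 b/s mean rate and 2,000-base mean burst
length; the full chain (drift correction → 3.76 b/nm conversion →
6-point/3σ segmentation → population fits) recovers 458 b/s and 2.05 kb
from the noisy trajectories. The numbered scripts under `analysis/`
(`01_simulate_data.R` … `05_seqprofile.R`) run the four assay analyses
end-to-end and write their tables under `results/`.

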