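---
title: "Selective T1 in living cells: models, processing choices and acquisition planning"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Selective T1 in living cells: models, processing choices and acquisition planning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Imino protons of G and T/U bases (10--15 ppm) report directly on base-pair
formation, which makes 1D imino spectra the workhorse readout for nucleic
acids inside living cells. In-cell spectra, however, sit at signal-to-noise
ratios around 8--12 and their lines are several-fold broader than in buffer,
so every quantitative statement -- "this base pair is still formed", "this
duplex relaxes faster inside the cell" -- depends on a chain of choices:
how the FID is processed, how peak intensities and their uncertainties are
read off, how the recovery curve is fitted, and how the measured relaxation
time is converted into acquisition settings. `iminoT1` implements that chain
end to end, together with a synthetic-data generator that reproduces the
statistical structure every stage assumes, so the whole pipeline can be
validated without access to spectrometer data.

## The recovery model

A selective inversion-recovery experiment inverts the imino region, waits a
delay $\tau$, and reads out. Peak intensity follows the mono-exponential law

$$I(\tau) = A + D\,e^{-\tau/\mathrm{selT1}}$$

with $A$ the equilibrium intensity, $\mathrm{selT1}$ the selective
longitudinal relaxation time, and $D$ a free inversion coefficient:
$D = -2A$ for perfect inversion, but selective shaped pulses never invert
perfectly, so $D$ is always fitted. Normalising by the fitted $A$ puts
curves from different samples on a common $[-1, 1]$-ish scale.

`fit_recovery()` minimises the weighted squared residuals of this law by
Levenberg--Marquardt with $\mathrm{selT1} > 0$ enforced, weights
$1/\sigma_i^2$ from the per-point errors, and a three-point multi-start
(the data-driven initial guess, the median delay, and a third of the
largest delay) because a noisy nine-point series occasionally drives a
single start into the boundary. Per-point errors are treated as *absolute*
standard errors -- they are calibrated as the spectrum RMS noise, not
relative weights -- so the covariance is $(J^\top W J)^{-1}$ without
reduced-chi-square rescaling; unweighted fits fall back to the usual
rescaled covariance. A fit is flagged `"failed"` (never silently dropped)
when the optimizer does not converge, the covariance is singular, the
relative standard error of $\mathrm{selT1}$ exceeds 100%, or
$\mathrm{selT1}$ collapses onto its bound.

`fit_recovery_global()` shares one $\mathrm{selT1}$ across replicate series
(each keeping its own $A$, $D$), which is how replicates measured with
*different* delay schedules are combined; with a single series it reduces to
the individual fit.

### Sample deterioration

Cells die during the measurement, scaling all signal down roughly linearly
over the hours of a replicate. The delay schedules therefore re-measure a
0.320 ms reference delay mid-series; `fit_drift()` puts an OLS line through
the reference intensities versus wall-clock time and
`correct_deterioration()` divides every point by the line normalised to the
first reference. The correction is *multiplicative* because cell loss
scales all signal proportionally -- and because it must preserve the sign
of the inverted early-delay points. On noiseless drifted data the
correction is exact and the generating $\mathrm{selT1}$ is recovered to
machine precision (this is one of the package's acceptance properties).

## Processing recipes

Three alternative FID-to-spectrum recipes are provided, used as an internal
control: if the fitted $\mathrm{selT1}$ depends on the recipe, the analysis
is not trustworthy at the prevailing SNR.

| preset | apodization | truncation | linear prediction |
|---|---|---|---|
| `lb1_trunc` | EM, 1 Hz | 2048 to 512 | -- |
| `lb1_trunc_lp` | EM, 1 Hz | 2048 to 512 | 16 coefficients to 8192 |
| `lb15_full` | EM, 15 Hz | -- | -- |

Steps apply in the order truncate, predict, apodize, transform: prediction
coefficients are estimated from the raw truncated FID before any windowing
distorts the autoregressive structure (the conventional order; it is
configurable through the individual step functions if a user disagrees).
The linear prediction is a least-squares forward autoregression whose
characteristic roots are reflected into the unit circle when they fall
outside -- noiseless damped exponentials are continued exactly, noisy ones
cannot diverge. Zero-filling defaults to the next power of two at least
twice the effective length. Only zero-order phasing is applied: the
generator produces phase-coherent signals, so automatic first-order phase
correction would be dead code here; spectra imported from instruments need
phasing upstream.

The ppm axis is descending with the carrier at the centre (standard NMR
display convention); with the default 22.04 ppm window about a 13.5 ppm
carrier it spans 24.52 to 2.48 ppm, leaving the 15--16 ppm stretch
signal-free for noise estimation.

## Extraction and the error model

Peak positions are *frozen* at the extremum observed in the first spectrum
of a series (`locate_peaks()`) and every later spectrum is read at that
fixed shift, nearest grid point, no interpolation -- at SNR 10 chasing the
apparent maximum would systematically inflate intensities. A per-spectrum
diagnostic records how far the apparent maximum wandered from the frozen
shift; it is reported but deliberately never used to re-pick, mirroring how
badly-behaved peaks should be excluded by the analyst, not silently
re-centred.

Noise is the standard deviation of a signal-free region (default 15--16
ppm) *after subtracting the region mean*, so a constant baseline offset
cannot masquerade as noise. SNR uses the spectrometer-software convention
$\mathrm{SNR} = I/(2\,\mathrm{RMS})$, chosen so that the error formula
$\sigma_I = I/(2\,\mathrm{SNR})$ reduces exactly to the RMS noise; the two
conventions are tested against each other.

## The synthetic-data generator

`simulate_experiment()` emulates what the analysis stages assume:

* a handful of Lorentzian imino resonances whose amplitudes follow the
  recovery law -- presets carry the dsA2 duplex values, in vitro
  ($\mathrm{selT1}$ 108--331 ms, 6 Hz lines) and in-cell (24--101 ms,
  25 Hz lines, merged composite peaks with proportionally larger
  amplitudes);
* iid Gaussian noise on both quadrature channels, with
  `noise_sigma_for_snr()` calibrating the per-point sigma so the default
  presets land at spectrum SNR around 8--12 (target 10), the regime of real
  in-cell spectra;
* a linear multiplicative intensity drift (default slope zero; a typical
  in-cell value is $-0.15/240$ per minute, the observed viability loss of
  roughly 15% over four hours);
* the two published nine-delay schedules with their repeated 0.320 ms
  reference, and start times derived from 1024 scans of
  $(968.5 + \tau)$ ms each.

Chemical shifts for peaks other than the 13.4 ppm T4/T22/T18 composite are
not published; the presets place them synthetically between 12.2 and
14.05 ppm, at least 0.25 ppm apart. What the generator deliberately does
*not* model: pulse-shape selectivity profiles, radiation damping, solvent
signal, $B_0$ drift, or within-experiment signal averaging (one effective
FID per delay). Passing tests therefore demonstrate correctness of the
analysis chain under the stated statistical model, not robustness to every
instrumental artefact of real spectrometer data.

## Acquisition planning

For a band-selective fast-pulsing experiment with 120-degree excitation,
sensitivity per unit time as a function of the recovery time
$T_\mathrm{rec}$ is

$$S(T_\mathrm{rec}) = \frac{\sin(\pi/3)\,(1 - E)}
  {\left(1 - E\cos(\pi/3)\right)\sqrt{T_\mathrm{rec} + t_\mathrm{ov}}},
  \qquad E = e^{-T_\mathrm{rec}/\mathrm{selT1}},$$

with $t_\mathrm{ov}$ the per-scan overhead beyond the recovery time.
`sofast_sensitivity()` implements the expression exactly in this printed
form, with the *positive* $\cos(\pi/3)$ term in the denominator. For a
120-degree flip the steady-state algebra would put $\cos(2\pi/3) < 0$
there; only the printed form reproduces the published optima for this
system (66 ms in-cell, 173 ms in vitro), so the package follows it and
documents the discrepancy rather than silently "fixing" the formula.

Defaults: $t_\mathrm{ov} = 11$ ms, the summed shaped-pulse and gradient
durations of the imino-selective sequence (PC9 3.88 ms + Reburp 3.23 ms +
gradients and their recovery intervals, rounded up); this single value
reproduces both published optima to within about 1.5%. The disk-write time
participates in the achievable-recovery-time floor (D1 + acquisition +
disk write) but not in the scan time of the sensitivity expression, because
the scan time is defined as recovery time plus pulse lengths.

`optimal_trec()` maximises $S$ by golden-section search to 0.01 ms on
$(0, 20\,\mathrm{selT1}]$, cross-checked against a 0.1 ms grid ($S$ has a
single interior maximum; both searches must agree to 0.1 ms, a property the
test suite verifies across $\mathrm{selT1} \in [10, 1000]$ ms). Uncertainty
propagates by re-optimising at $\mathrm{selT1} \pm \mathrm{SE}$, which
yields the asymmetric bounds the monotone $\mathrm{selT1} \mapsto
T_\mathrm{rec}^{opt}$ mapping implies. At zero overhead the optimum is the
fixed multiple $T_\mathrm{rec}^{opt} \approx 0.606\,\mathrm{selT1}$
(grid-search value; the package tests freeze 0.6063).

`apply_constraints()` floors the optimum at the instrument's minimum
(D1 + acquisition time + disk write, 137 ms for the default 30/77/30
configuration), `sensitivity_gain()` and `snr_gain()` express comparisons
in percent, and `quantitative_timing()` covers the fully-relaxed
$5 \times T_1$ regime where shorter in-cell relaxation buys a three-fold
scan-rate advantage over the in vitro timing.

## Cell-level quantification

Small closed-form calculators, each exact arithmetic: sphere volumes from
microscopy diameters ($17.0\ \mu m \to 2.57$ pL); the nuclear volume
fraction as the cubed diameter ratio ($9.6/17.0 \to 18.0\%$); the nuclear
share of total signal from a nucleus:cytoplasm concentration ratio and the
volume fraction ($65{:}35$ at 18% volume $\to$ 29.0% unrounded); the
interstitial-medium fraction of a pellet (0.47 mL pellet of $10^8$ cells at
2.5 pL $\to$ 46.8%); sequential-wash dilution through a constant carryover
volume; and the d-PAGE standard-curve route to intracellular concentration
with the 1:40 label ratio.

Conventions worth stating because the sources leave them open: the
carryover volume (pellet minus summed cell volume) is held constant across
washes; the final supernatant concentration includes one further dilution
into the resuspension volume plus carryover; the labelled-to-total
multiplier is exactly 40 (a strict-total option, 41, exists behind a
flag). Under these conventions two 50 mL washes leave 0.0021 uM -- the
published 0.002 -- while a single 15 mL wash gives about 1.55 uM, between
the two published single-wash figures (1.9 and 2.8 uM), which are not
mutually consistent under any single convention we tried; the package
reports the computed value.

## Numerical choices and test scale

* Tolerances: golden-section 0.01 ms; recovery fits run to Levenberg--
  Marquardt convergence (500 iterations cap); noiseless round-trip
  assertions at $10^{-4}$ relative or tighter.
* Monte-Carlo calibration runs at the series level (recovery law plus
  Gaussian noise at the SNR-10 error magnitude, $\sigma = A/20$): 500
  repeats per condition for $\mathrm{selT1} \in \{24, 84, 253\}$ ms,
  median bias under 5%. The fast 24 ms condition uses the short-delay
  schedule -- the long schedule's smallest non-reference delay is already
  $6 \times T_1$, which is precisely why the short schedule was introduced
  experimentally. Full-pipeline (FID to fit) checks are run noiseless,
  where the answer is exact.
* The recipe-robustness acceptance check asserts on the T4/T22/T18
  composite peak. In the synthetic multi-peak spectrum the weakest peaks
  sit next to a three-fold stronger neighbour and pick up percent-level
  Lorentzian-tail and truncation-ripple contamination, a lineshape-overlap
  effect that the frozen-shift extraction deliberately does not deconvolve;
  an isolated single resonance is checked across all three recipes in the
  module tests instead.

## Known limitations

* No multi-exponential or exchange-coupled recovery models; no
  non-selective $T_1$ analysis.
* No deconvolution of overlapped iminos -- composite peaks are fitted as
  one effective resonance, so their $\mathrm{selT1}$ is an amplitude-
  weighted average.
* The Bruker dataset adapter (`read_bruker_fid()`) is best-effort plumbing
  (int32/float64, both byte orders, no digital-filter group-delay
  correction) and is tested only against synthetic files in the TopSpin
  layout.
* The drift correction assumes the deterioration is linear and common to
  all delays of a series; strongly non-linear cell death would need a
  richer model.
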