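---
title: "Quantifying photomorbidity and planning NOEL imaging conditions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying photomorbidity and planning NOEL imaging conditions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(photomorbid)
```

## The problem

Excitation light in fluorescence time-lapse microscopy is a stressor. Well
below the doses that kill cells, visible light measurably slows growth —
*photomorbidity* — and thereby confounds any quantitative single-cell
experiment that runs for hours. This package treats photomorbidity as a
classical dose–effect problem: the growth rate (GR) of yeast microcolonies is
the readout, the excitation light dose per hour is the dose, and the goal of
experiment planning is to keep every channel of a multi-color experiment below
the *no-observed-effect level* (NOEL), the dose at which the growth-rate
reduction first becomes experimentally detectable.

The pipeline has five parts: light-dose accounting, growth-rate estimation,
dose–effect fitting, SNR calibration/prediction (plus photobleaching), and
multi-color planning under an additive-toxicity model. A synthetic-data
generator reproduces the statistical structure of each input so the whole
pipeline is testable without microscopy data.

## Light-dose accounting

The dose rate of a channel is

$$\mathrm{LD} = I \cdot t_E \cdot \frac{1}{t_\mathrm{Int}}
\quad [\mathrm{J\,cm^{-2}\,h^{-1}}],$$

with intensity $I$ (W cm$^{-2}$ at the sample plane), effective exposure
$t_E$ (s) and imaging interval $t_\mathrm{Int}$. Two details matter in
practice:

* **Hardware delay.** Triggered light sources illuminate the sample longer
  than the set exposure. `illumination_settings()` therefore adds a
  per-setup delay (default 0.187 s) to every exposure; at short set
  exposures this can dominate the dose, and uncorrected delays are a common
  reason published doses are underestimated. The delay is a configuration
  field, not a constant — measure it for your microscope.
* **Reciprocity.** Photomorbidity depends on the cumulative dose only, not
  on how intensity, exposure and interval are traded off against each other.
  The accounting functions treat dose rate as exactly multilinear, and the
  test suite pins this down as an invariant.

Doses can be renormalized per doubling time (`dose_per_doubling()`), the
scale on which temperature-slowed cells tolerate a constant dose per cell
cycle. Multi-channel rates are deliberately never summed into one scalar:
morbidity is wavelength-specific, and combination happens only in the
planning module.

Units are mW cm$^{-2}$, seconds, minutes throughout the inputs and
J cm$^{-2}$ (h$^{-1}$) in all outputs; the package requires explicit units
rather than guessing.

## Growth rates

`growth_rate_endpoint()` implements
$\mathrm{GR} = \log_2\!\big(N(t_\mathrm{end})/N(0)\big)/t_\mathrm{end}$,
the average rate over the observation window (default 495 min = 100 frames
at 5 min). The endpoint form is preferred over a full exponential fit
because morbidity onset can be delayed by hours; the average rate remains a
comparable effect measure whether retardation is instantaneous or delayed,
and on clean exponential data it agrees with `growth_rate_expfit()` (a
log2-linear regression) to well under 1%. Pads whose colony touches the
field-of-view border are excluded; the pads of one condition are summed
(`aggregate_pads()`) before the rate is taken. `early_window_residuals()`
fits only the first 3 h and plots residuals over the full course — the
diagnostic for when morbidity sets in.

## Dose–effect model

Growth rate versus dose rate follows a sigmoid,

$$\mathrm{GR}(\mathrm{LD}) =
\frac{\mathrm{GR}(0)}{1 + (\mathrm{LD}/\mathrm{ED}_{50})^{\tau}},$$

with $\mathrm{ED}_{50}$ the half-effect dose and $\tau$ the steepness of
onset. `fit_dose_response()` minimizes the sum of *absolute* residuals
(LAD), which is robust to occasional aberrant pads. Because the L1 objective
is non-smooth, the optimizer is a derivative-free Nelder–Mead simplex with
multi-start (ED50 at the median and maximum tested dose, $\tau \in \{1, 2,
4\}$, on log scales for positivity) followed by restart polishing; on
noiseless model data this recovers parameters to better than 0.1%.
Degenerate inputs are refused explicitly: fewer than four distinct dose
levels, or all growth rates equal ($\tau$ unidentifiable).

The NOEL has the closed form
$\mathrm{ED}_{50}\,(1/f - 1)^{1/\tau}$ at fraction $f$ (default 0.98, the
smallest reduction distinguishable from control in this assay). The
inverse-dose function is the same expression for any fraction; the forward
and inverse directions round-trip to machine precision.

Confidence intervals come from a case-resampling bootstrap (`bootstrap_ci()`),
stratified by dose level so each replicate retains the design, with
percentile intervals. A fit-native curvature interval would mirror the
original Matlab workflow, but the bootstrap is distribution-free, honest
about the LAD criterion, and deterministic given a seed. Fits are
control-normalized by default (GR0 $\approx$ 1) so experiments are
comparable.

## SNR calibration and prediction

Detectability is scored as
$\mathrm{SNR} = (\mu_\mathrm{sig} - \mu_\mathrm{bg})/\sigma_\mathrm{sig}$.
The noise term deserves a note: descriptions of this quantity sometimes
reduce to "signal over itself" when typeset carelessly; here the
denominator is explicitly the standard deviation of the cellular signal,
which the calibration protocol fits against dose alongside the means (a
shot-noise mode, $\sqrt{\mu_\mathrm{sig}}$, is available). All three
quantities are linear in dose — signal as $(B + P)\,\mathrm{LD}\cdot QE +
NR^2$ with probe rate $P$, background rate $B$, quantum efficiency $QE$ and
camera floor $NR^2$ — so `fit_channel_calibration()` fits three weighted
straight lines and `estimate_snr()` evaluates the ratio at any dose.

For targets too dim (or too numerous) to calibrate directly, the
background-corrected reference signal is rescaled by an abundance ratio
measured once with a reference fluorophore set:
$\mu_\mathrm{target} = (\mu_\mathrm{ref} - \mu_\mathrm{bg})\,r +
\mu_\mathrm{bg}$. The built-in ratios derive from the Citrine reference
brightness proportions 143 : 43 : 13 (Vph1 : Cdc12 : Whi5), i.e. $r =
43/143 \approx 0.30$ and $13/143 \approx 0.091$ — stored in the $r < 1$
orientation (target over reference) so that the same $r$ multiplies the
reference signal. `ld_for_snr()` solves the rational SNR-vs-dose function
for a target SNR (default 4, the smallest SNR at which cellular
fluorescence quantifies robustly) in closed form, refusing targets above
the asymptote $r\,\Delta\mathrm{slope}/\sigma\mathrm{-slope}$ with a typed
`infeasible_error`. `gr_at_snr_target()` then converts the per-acquisition
dose to an hourly rate at the imaging interval and reads the expected
growth fraction off the morbidity curve — the number that decides whether a
fluorophore/target pair is usable. Objective choice enters through
$\mathrm{SNR} \propto \mathrm{NA}^4/M^2$ (`objective_snr_scaling()`).

## Photobleaching

In vivo bleaching versus cumulative dose is fit as
$a e^{bx} + c e^{dx}$ ($b, d \le 0$) via Levenberg–Marquardt with a
single-exponential seed split into a fast and slow term; terms are ordered
fast-first to remove permutation ambiguity. `ld_bleach50()` returns the dose
at which fluorescence halves — closed form for one term, bracketed root
otherwise — and `bleach_safe_at_noel()` checks it against the dose
accumulated in a NOEL experiment (default 8 h). Noisy negative intensities
near full bleach are retained in the fit rather than clipped. Traces whose
log-linear trend declines by less than 1% over the observed range are
treated as non-decaying (warning and single-term fallback) rather than
forced through the two-term model.

## Multi-color planning

The effects of distinct excitation wavelengths combine multiplicatively
(Bliss independence). The interaction score is the coefficient of drug
interaction, $\mathrm{CDI} = \mathrm{GR}_{AB}/(\mathrm{GR}_A\,
\mathrm{GR}_B)$ on control-normalized rates, classified additive within
[0.8, 1.2] by pharmacological convention. Under additivity the per-channel
budget for an $n$-wavelength experiment is $0.98^{1/n}$ (0.993 for three
colors), and `max_ld_at_budget()` turns that into a per-band dose cap.

`plan_channels()` assembles the full calculation: per channel it computes
the dose needed for the target SNR, converts it to an hourly rate, sums
doses of channels sharing one excitation band (morbidity cares about the
wavelength, not the fluorophore), and compares each band against its budget
cap. The plan reports per-band slack, the combined predicted growth
fraction, and a feasibility verdict; channels whose SNR target is
unattainable are named. Emission crosstalk is *not* modeled — plans relying
on overlapping emission additionally require spectral unmixing downstream.

## Synthetic data

The generator mirrors the standard assay design: 6 dose rates plus an
unilluminated control, 5 pads per condition (35 pads), 100 frames at 5-min
intervals, 8 starting cells per pad, control doubling time 123 min, and a
dose-effect truth of ED50 = 290 J cm$^{-2}$ h$^{-1}$, $\tau$ = 1.8 (typical
cyan-light values for budding yeast on glucose). Count noise is
multiplicative lognormal (sdlog 0.05) — counts are positive and error grows
with colony size; no empirical noise model is available, and this choice
yields growth-rate scatter of a few percent of control, the scale seen in
replicate pads. An optional `onset_delay` switches sub-ED50 pads from
control-rate to dose-reduced growth after a fixed lag; this is a
phenomenological switch, not a damage-accumulation model. Fluorescence
summaries are drawn per cell (Gaussian, CV 10%) from the linear signal
model; bleach traces are the two-term decay plus additive noise on a
200-point grid.

What the generator does *not* emulate: segmentation errors, pad-to-pad
microenvironment differences, crowding effects near the capacity limit,
spectral bleed-through, and day effects between experiments. Passing
round-trip tests therefore demonstrates estimator correctness under the
assumed noise structure, not robustness to those real-world artifacts.

## Numerical choices and problem sizes

* LAD fitting: Nelder–Mead, relative tolerance $10^{-12}$, 6 starts + 2
  polish restarts; bootstrap refits start from the full-data estimate.
* Root finding (`ld_bleach50`, NOEL cross-checks): bracketing with tolerance
  $10^{-12}$.
* The test suite simulates at the default design size; the bootstrap
  coverage study uses 200 simulated experiments with 200 bootstrap
  replicates each, and recovery checks use fixed seeds.
* Ties/zero counts are rejected at construction rather than imputed; pads
  are only excluded via the explicit border flag or the capacity limit.

## Limitations

Dose–effect parameters are species-, wavelength- and medium-specific;
nothing here transfers numbers between conditions — the package transfers
*procedure*. Red-light morbidity is often unmeasurable at practical
intensities, so red channels borrow the green curve as a conservative bound.
The additive model is supported in the weakly-morbid regime relevant for
NOEL planning; strongly morbid dose combinations may interact. Background
fluorescence depends on the medium and optics and must be recalibrated per
setup.
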