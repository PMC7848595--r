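---
title: "Coupled electro-mechanical modelling of human ventricular myocytes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Coupled electro-mechanical modelling of human ventricular myocytes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model

`emcell` simulates a single human ventricular cardiomyocyte in which
electrophysiology and active contraction are strongly coupled. Two
electrophysiology backends are provided:

* **ToR-ORd** (Tomek et al. 2019): the current reference model of the human
  ventricular action potential, with a re-evaluated L-type calcium current
  (ionic-activity driving forces, 80/20 subspace/myoplasm split), a
  five-state Markov IKr, a Grandi-type INa, an instantaneous IK1, and
  calcium-sensitive plus background chloride currents.
* **ORd** (O'Hara et al. 2011) with the Dutta et al. 2017 conductance
  rescaling (IKr x1.119, IKs x1.648, IK1 x1.414, ICaL x1.018,
  INaL x2.274), kept as the predecessor backend for comparison.

Active tension comes from the **Land 2017** human contraction model:
calcium binding to troponin C (Hill exponent `n_trpn = 2`, rate
`k_trpn = 0.1/ms`, half-activation `ca50 = 0.805 uM` at extension ratio
`lambda = 1`), cooperative tropomyosin blocking/unblocking, and a
three-state crossbridge scheme (unattached/weak/strong) with distortion
variables. Tension is reported in kPa; 1 kPa = 1 mN/mm^2, so experimental
twitch amplitudes apply directly.

### Bidirectional coupling

Forward coupling: the bulk-myoplasm free calcium of the electrophysiology
model drives troponin C binding in the contraction model. Reverse coupling:
the source models' instantaneous troponin term is removed from the calcium
buffer factor (calmodulin stays instantaneous) and replaced by the dynamic
flux `J_trpn = trpnmax * dCaTRPN/dt` with `trpnmax = 0.07 mM`, the troponin
capacity of the electrophysiology models. The observable consequence —
reproduced by the package's tests — is that the action potential is
unchanged (< 1 mV RMS against the uncoupled model) while the calcium
transient gains amplitude and decays faster, moving its 90%-decay time
towards the human imaging median. There are no stretch-activated currents;
the mechano-electric feedback is purely through troponin buffering.

All single-cell protocols are isometric at `lambda = 1` (`dlambda/dt = 0`);
`lambda` is validated to [0.8, 1.2], the range over which steady developed
tension grows monotonically with length.

## Calibration of the contraction model

Driven by the (smaller, faster) coupled calcium transients instead of the
transient the contraction model was originally fitted to, the published
parameter set produces twitches of only ~4 kPa. Following the approach of
the modelling literature, exactly two parameters are recalibrated: the
Hill coefficient of cooperative tropomyosin activation (`n_tm`) and the
tropomyosin rate constant (`k_tm`, the unblocking rate). `calibrate_land()`
minimises a weighted sum of interval distances (distance to the target
interval normalised by the interval width; zero iff every biomarker is
inside its interval) over full coupled paced runs, using a coarse
log-spaced grid followed by Nelder-Mead refinement — a deterministic,
derivative-free bounded search chosen because simulated biomarkers are
noisy-smooth and cheap gradients are unavailable.

Target intervals are the package's pooling of human isometric twitch data
recorded at 1-1.2 Hz (mean +/- 2 SEM per study, union across studies):
amplitude [10.1, 25.6] kPa, time-to-peak [137, 179] ms, rt50 [101, 133] ms,
rt95 [248, 539] ms. Running the calibration (reports in
`inst/extdata/calibration/`) gives `n_tm = 2.2585`, `k_tm = 0.03862/ms`
for both backends, with every biomarker inside its interval
(amplitude 23.7 kPa, tp 148 ms, rt50 107 ms, rt95 255 ms for ToR-ORd+Land
at 1 Hz). These are the defaults loaded by
`make_mech_params(calibrated = TRUE)`; they are updated only by re-running
the calibration, never edited by hand. Calibration touches mechanics only:
the tests verify APD is unchanged to < 0.5 ms.

## Protocols and numerical choices

* **Solver**: stiff implicit integration (`deSolve::lsoda`) at
  rtol 1e-6 / atol 1e-8 (exposed via `solver_options()`). Tightening both
  tenfold moves APD90 by < 0.5 ms and peak tension by < 0.5%.
* **Stimulation**: square current pulses of -53 uA/uF for 1 ms (ToR-ORd)
  or -80 uA/uF for 0.5 ms (ORd), applied at each cycle start with the
  solver re-initialised at the pulse edges so no stimulus can be stepped
  over. Output is resampled at `dt_out = 0.5 ms`, which resolves EAD
  morphology; halving it changes APD90 by < 0.5 ms.
* **Steady state**: the sources state only "steady state was reached".
  The package's criterion — relative beat-to-beat change of APD90, calcium
  peak and tension peak below 0.05% over 10-beat windows, budget
  1500 beats — is a package decision recorded in every snapshot's
  metadata. Pre-paced snapshots ship with the package so trials start from
  steady state without re-pacing. At 0.25 Hz the criterion is not reached
  within the budget (peak tension still drifts ~0.14% per 10 beats due to
  slow sodium accumulation); the snapshot is shipped with
  `converged = FALSE` metadata, and 0.25 Hz endpoints are control-subtracted
  so the residual drift cancels.
* **Biomarkers**: all thresholds are linearly interpolated between
  samples. Time-to-peak is measured from stimulus onset; resting/diastolic
  references are the values immediately before the stimulus (not global
  minima), so abnormal beats still have defined thresholds.
* **Abnormality detectors**: an EAD is a positive membrane-potential slope
  (> 0.01 mV/ms sustained for >= 2 ms, configurable) during repolarisation
  — after the AP has repolarised 30% from its peak (which excludes the
  healthy spike-notch-dome plateau), before the next stimulus, with V
  above resting + 10 mV. Aftercontractions use the same logic on tension
  with a default slope tolerance of 0.1% of peak tension per ms. A
  contractility escape is a beat whose developed tension falls below 10%
  of the drug-free steady-state developed tension; the sources give only
  the sign rule / qualitative definition, so the numeric tolerances are
  package decisions, configurable and held fixed across compared
  conditions.
* **Electro-mechanical window**: `emw()` returns APD90 - CaTD90 with
  CaTD90 = CaT time-to-peak + rt90, the printed definition. Note that the
  qualitative statements usually attached to the EMw ("shorter under
  coupling", "shortened by IKr block") refer to the clinical
  mechanical-minus-electrical convention, i.e. to the negated quantity;
  the package's tests therefore assert those directions on
  `-emw`. With either sign the comparisons are unaffected because the
  convention is held fixed.

## Drug trials

Drug action is a simple pore block: each listed channel's conductance is
scaled by `1 - c^h/(c^h + IC50^h)`. There is no state-dependent binding.
The trial protocol follows the source exactly: drug-free steady state at
the pacing rate, drug applied, 200 further beats without re-converging, the
final 10 beats inspected for EADs, aftercontractions and escapes, and all
deltas control-subtracted at identical cycle length. Dose-response curves
summarise the percent reduction of peak developed tension; the Hill fit
fixes the maximal effect at 100% (a pore block of the driving calcium
current suppresses tension completely in the limit), leaving the
two-parameter (IC50, Hill) summaries.

The shipped potency table (`extdata/compounds_synthetic.csv`) is a
*synthetic reconstruction*: only verapamil-ICaL (0.2 uM / 0.8) and
quinidine-IKr (0.72 uM / 1.06) are anchored published values; the other
entries are representative multichannel-screening magnitudes. Fitted
tension IC50s and APD deltas therefore carry the uncertainty of that
table in addition to model error, which is the main reason some
drug-trial endpoints deviate from their reference values.

## The synthetic waveform generator

`generate_waveform()` produces closed-form traces — triangle APs and
raised-cosine transients, with optional injected EAD humps,
aftercontraction bumps or dropped beats — together with their exact
biomarkers. It emulates only the *geometry* the extractors and detectors
must handle (linear/cosine rises and decays, anomalies inside the
falling phase); it has no channel noise, no beat-to-beat variability, no
alternans and no drift. Passing these tests therefore certifies the
measurement code, not the physiology; the physiological surface is tested
separately against the simulated models and human ranges.

## Problem sizes used by the test suite

The suite runs full 200-beat drug protocols for the acceptance endpoints
but scales supporting analyses down to what a laptop CPU handles in
minutes: steady states start from shipped snapshots and are re-converged
rather than re-paced from scratch; oracle checks use hundreds (not
thousands) of random states; the inverse-crime calibration check uses
12-beat cost evaluations. These sizes are stated here as package choices
so they can be scaled up by anyone reproducing the analyses.

## Known limitations

* The component models are independent transcriptions of the published
  equation sets (see `inst/MODEL_NOTES.md`); they reproduce resting
  stability, AP/CaT/tension biomarkers inside the human experimental
  ranges, transmural orderings and the coupling phenomenology, but small
  rate-constant deviations from the originals cannot be excluded. The
  practical consequence observed: the repolarisation reserve is somewhat
  larger than in the original ToR-ORd, so EAD onset under IKr block
  occurs at higher block fractions than published.
* No tissue-level electromechanics (monodomain propagation, finite-element
  passive mechanics) — single cell only. One visible consequence: the AP
  time-to-peak of a space-clamped cell under a 1 ms square pulse is
  ~1.5 ms, below the 3-14 ms range reported for field-stimulated
  trabeculae, where conduction latency adds to the measured value.
* No sarcomere-length dynamics or after-load; contraction is isometric at
  a fixed extension ratio.
* No delayed-afterdepolarisation classification and no TdP risk
  classifier.
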