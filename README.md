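# emcell

Strongly coupled electro-mechanical simulation of human ventricular
cardiomyocytes, for pro-arrhythmia and inotropy assessment of drugs in
silico.

## What it does

`emcell` integrates the two current reference descriptions of the human
ventricular myocyte — the **ToR-ORd** electrophysiology model (with the
Dutta-modified **ORd** as an alternative backend) and the **Land 2017**
active-contraction model — into one bidirectionally coupled ODE system:
the free intracellular calcium computed by the electrophysiology drives
crossbridge cycling, and the dynamic calcium-troponin C buffering of the
contraction model replaces the electrophysiology model's instantaneous
troponin buffer, feeding back into the calcium balance:

    dCa_i/dt = B_cmdn(Ca_i) * [ J_sarcolemma + J_SR + J_diff
                                - TRPN_max * dCaTRPN/dt ]

On top of the coupled cell the package provides:

* pacing and steady-state protocols (stiff solver, compiled C right-hand
  sides, square-pulse stimulation re-initialised at pulse edges);
* biomarkers of the action potential (tp, APD50, APD90), calcium transient
  (tp, rt50, rt90) and active tension (tp, rt50, rt95), the
  electro-mechanical window, and detectors for early afterdepolarisations,
  aftercontractions and contractility escapes;
* an in-silico drug-trial engine using simple pore block,
  `scale = 1 - c^h/(c^h + IC50^h)`, with the published 200-beat protocol,
  dose-response construction and two-parameter Hill fits of tension
  reduction;
* recalibration of the contraction model against human twitch data
  (`calibrate_land()`), and a transmural calcium-sensitivity scan
  (`ca50_scan()`).

It is aimed at cardiac safety-pharmacology and electrophysiology
modellers who want a self-contained, scriptable single-cell
electro-mechanics laboratory in R.

## Worked example

```r
library(emcell)

ep    <- make_params("torord", "endo")          # ToR-ORd endocardial cell
mech  <- make_mech_params("torord")             # calibrated Land parameters
start <- steady_state_snapshot("torord", "endo", cl = 1000)

trace <- pace(start, ep, mech,
              pacing_protocol(cl = 1000, n_beats = 3, record_last = 1))
biomarkers(trace, 1)
#> <biomarker_report>
#>   AP : tp 1.5 ms, APD50 217.3 ms, APD90 270.8 ms, peak 33.1 mV, rest -88.9 mV
#>   CaT: tp 43.5 ms, rt50 156.5 ms, rt90 307.4 ms, peak 0.000466 mM, dia 7.23e-05 mM
#>   Ta : tp 148.5 ms, rt50 107.4 ms, rt95 255.6 ms, peak 23.85 kPa, dia 0.05 kPa
#>   EMw: -80.1 ms
#>   flags: EAD=FALSE, aftercontraction=FALSE, escapes=none
```

The 1 Hz steady-state endocardial beat has APD90 of 271 ms and a 24 kPa
twitch, inside the human experimental ranges used for calibration and
evaluation (APD90 178-443 ms; twitch amplitude 10-26 mN/mm^2, and
1 kPa = 1 mN/mm^2).

A drug trial applies a pore block on top of the drug-free steady state and
runs 200 further beats:

```r
drugs <- read_drug_table()     # shipped potency table (see its header)
trial <- drug_trial("torord", "endo", drugs$verapamil, conc = 1)
trial
#> <drug_trial> verapamil 1 uM on TORORD/endo+Land, CL 1000 ms
#>   outcome: normal
#>   dAPD90 +106.2 ms, dCaT peak -0.000337 mM, dTa peak -23.62 kPa, dEMw +95.5 ms
#>   EAD=FALSE, aftercontraction=FALSE, escapes=10
```

At 1 uM (about 12x the therapeutic plasma concentration) verapamil's
L-type calcium block suppresses the twitch almost completely — the
negative inotropy that makes it contraindicated in ventricular
dysfunction — so every final beat is flagged as a contractility escape,
while IKr block prolongs the APD. `dose_response_tension()` summarises
such runs into a fitted IC50/Hill pair, and `ead_onset_concentration()`
scans a concentration grid for repolarisation abnormalities.

A thin command-line interface is installed as `exec/emcell`
(`emcell pace --beats 10 --out trace.csv`, `emcell trial --drug verapamil
--conc 1`, ...).

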