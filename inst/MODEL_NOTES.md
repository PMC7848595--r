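# Model transcription notes

## Equation provenance

- **ToR-ORd** (`src/torord.c`): transcribed from Tomek, Bueno-Orovio,
  Passini et al., eLife 2019 ("Development, calibration, and validation of a
  novel human ventricular small-molecule drug screening model"), including
  the Grandi-type INa, the five-state Markov IKr, the reworked ICaL with
  ionic-activity (Davies equation) driving forces split 80/20 between
  subspace and bulk myoplasm, the instantaneous IK1, and the
  calcium-sensitive and background chloride currents. The `dss` activation
  curve is capped at 1 (as in the published code) so gating bounds hold.
- **ORd** (`src/ord.c`): O'Hara, Virag, Varro, Rudy, PLoS Comput Biol 2011,
  with the Dutta et al. 2017 (Frontiers in Physiology) conductance
  recalibration applied on the R side: IKr x1.119, IKs x1.648, IK1 x1.414,
  ICaL x1.018, INaL x2.274.
- **Land** (`src/land.c`): Land et al., J Mol Cell Cardiol 2017 human
  model: troponin C binding (Hill in Ca, rate k_trpn), cooperative
  tropomyosin blocking/unblocking, three-state crossbridge scheme
  (U/W/S) with distortion variables and length-dependence factors
  beta_0 (tension) and beta_1 (Ca50, additive in uM). Effective rates
  k_uw = 0.182/ms and k_ws = 0.012/ms correspond to the published base
  rates with their nu/mu multipliers folded in. The passive/viscoelastic
  element is omitted: all protocols here are isometric at fixed extension
  ratio, where it contributes no active tension.

The transcription was done from the publications and their public encodings
without machine verification against CellML (none was available to this
build); it is audited instead by the package's own invariant tests
(current-sum identity, dual transcription of the contraction model,
calcium bookkeeping conservation, resting stability, biomarker ranges).

## Transmural heterogeneity tables used

Relative to endo (multiplicative only):

| current | ToR-ORd epi | ToR-ORd mid | ORd epi | ORd mid |
|---------|------------|-------------|---------|---------|
| INaL    | 0.6        | 1           | 0.6     | 1       |
| Ito     | 2.0        | 2.0         | 4.0     | 4.0     |
| ICaL    | 1.2        | 2.0         | 1.2     | 2.5     |
| IKr     | 1.3        | 0.8         | 1.3     | 0.8     |
| IKs     | 1.4        | 1           | 1.4     | 1       |
| IK1     | 1.2        | 1.3         | 1.2     | 1.3     |
| INaCa   | 1.1        | 1.4         | 1.1     | 1.4     |
| INaK    | 0.9        | 0.7         | 0.9     | 0.7     |
| IKb     | 0.6        | 1           | 0.6     | 1       |

Non-conductance celltype differences: epi Ito inactivation uses the
published delta_epi factor; epi SERCA scale 1.3 and calmodulin capacity
x1.3; mid SR release flux x1.7 (folded into the release scale).

## Coupling

The combined troponin/calmodulin instantaneous buffer of the source models'
d[Ca]i/dt is split: calmodulin stays instantaneous, troponin becomes the
dynamic Land CaTRPN state. The feedback flux is
J_trpn = trpnmax * dCaTRPN/dt with trpnmax = 0.07 mM, the troponin
capacity of the source electrophysiology models. The contraction model is
driven by bulk-myoplasm free calcium (converted mM -> uM).

## State ordering

Fixed and versioned (STATE_VERSION in R/states.R); snapshots store names and
the version and are validated on load. The trailing auxiliary state `qca`
accumulates net sarcolemmal calcium influx (expressed as mM of myoplasmic
volume) and exists purely for conservation auditing; it never feeds back
into the dynamics.

## Known uncertainties

- Individual rate constants were transcribed from memory of the published
  codes; small deviations cannot be excluded. The steady-state biomarkers
  of both variants fall inside the human experimental ranges used for
  evaluation, and transmural orderings reproduce the published sequences,
  which bounds the practical impact.
- The compound potency table shipped under `extdata/` is a synthetic
  reconstruction except for the two anchored entries (see its header).
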