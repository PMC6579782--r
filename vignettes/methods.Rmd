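---
title: "Methods: emotional-oddball ERPs and phase-locking networks in erpnet"
author: "erpnet"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: emotional-oddball ERPs and phase-locking networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope and model

`erpnet` re-implements, as a tested and reusable pipeline, an EEG analysis
for probing residual emotional processing in patients with disorders of
consciousness. Three groups are modelled: healthy controls (HC), minimally
conscious state (MCS) and unresponsive wakefulness syndrome (UWS). Subjects
hear an auditory emotional oddball block of 110 stimuli — 86 neutral
standards, 12 happy deviants, 12 angry deviants — each 700 ms long with a
1500 ms interstimulus interval (2200 ms onset-to-onset). The analysis has
four layers:

1. **ERP statistics.** Condition-average waveforms per subject, then a
   mass-univariate paired t test at every (channel, timepoint) cell between
   the pooled emotional (happy + angry) and neutral conditions. p-values
   come from the sign-flip permutation null (exact enumeration of all 2^n
   flips when n <= 12, otherwise 1000 random flips with the add-one
   correction p = (b+1)/(m+1)), and are adjusted with the
   Benjamini–Yekutieli step-up procedure (harmonic-sum factor
   c(m) = sum 1/i), which controls the FDR under arbitrary dependence —
   appropriate because neighbouring EEG cells are strongly correlated.
2. **Phase-locking networks.** Band-passed analytic-signal phase per trial,
   channel and timepoint; across-trial phase-locking value
   PLV(t) = |K^-1 sum_k exp(i dphi_k(t))| per electrode pair, averaged over
   the 0–1000 ms post-stimulus window; one symmetric PLV matrix per subject
   and condition over the 20 scalp channels (mastoids excluded).
3. **Weighted graph properties.** Onnela clustering coefficient C
   (max-normalized geometric-mean triangle intensity), characteristic path
   length L and Latora–Marchiori global/local efficiencies Ge/Le with edge
   length 1/w, plus optional small-worldness sigma against
   degree-preserving rewired nulls. Matrices stay fully weighted; no
   threshold is applied.
4. **Group inference.** A 3 (group) x 2 (condition) mixed repeated-measures
   ANOVA per network property (between: group; within: condition), with
   Mauchly's sphericity test and the Greenhouse–Geisser correction (for the
   2-level condition factor epsilon is exactly 1 and Mauchly is not
   applicable), Bonferroni post hocs, simple effects, and edge-wise paired
   t contrasts on the PLV matrices with uncorrected (p < 0.05) and
   Bonferroni (p < 0.05/m, m = 190 electrode pairs) masks.

## The synthetic-data generator

Patient EEG of this kind is rarely shareable, so the package ships a
generator whose defaults emulate the design conditions: 15
subjects per group, 500 Hz sampling, a 22-channel 10–20 montage (20 scalp
electrodes plus M1/M2 mastoids), and the 86/12/12 block. Each subject is

* 1/f background noise (spectral synthesis, 10 uV RMS per channel — a
  typical broadband EEG amplitude in the 0.1–30 Hz band);
* per-event ERP templates scaled by group- and condition-specific
  amplitudes: N1, a negative Gaussian at 150 ms (SD 20 ms) over frontal
  channels; P3a, a positive Gaussian at 300 ms (SD 45 ms), frontal; LPP, a
  sustained 400–1000 ms plateau with raised-cosine ramps over a broad
  central/parietal-occipital topography (the late positive complex is a
  spatially extended component, so central electrodes carry weight 0.6–0.7
  and parietal-occipital electrodes 0.65–1);
* a shared 10 Hz oscillation (8 uV, 50 ms cosine tapers) added to both
  members of each coupled electrode pair during epochs of the stated
  condition, with a von Mises phase offset of concentration kappa applied
  to the second channel. This construction gives a closed-form expected
  PLV — the Bessel ratio I1(kappa)/I0(kappa) — so coupling recovery can be
  tested quantitatively.

Group profiles (chosen once, as plausible exaggerations of the classic
group signatures, and not revisited): HC carry an emotion-enhanced LPP
(0.5 vs 6 uV) and strong emotional coupling (kappa = 3) on eight
fronto-/parieto-occipital pairs; MCS an emotion-sensitive P3a (1 vs 4 uV)
and weak temporal coupling (kappa = 1, three pairs); UWS only an enhanced
N1 (-1.5 vs -3 uV) with marginal diffuse coupling (kappa = 0.2).

What the generator does **not** emulate: volume conduction and reference
leakage, ocular/muscle artifact physiology (artifact rejection is exercised
with injected amplitude spikes instead), inter-subject amplitude and
latency variability beyond what the noise induces, and realistic head-model
topographies. Passing tests therefore demonstrate the correctness of the
statistical machinery under the stated model, not its behaviour on real
patient EEG.

One consequence of using deterministic ERP templates is worth noting: any
evoked component is itself phase-locked across trials, so condition
differences in ERP amplitude also shift PLV — in the same direction as the
injected coupling. This mirrors the well-known evoked contribution to
event-related phase locking in real data.

## Numerical choices

* **Zero-phase filtering.** The preprocessing chain is a 4th-order
  Butterworth high-pass at 0.1 Hz, a 4th-order low-pass at 30 Hz and a
  2nd-order 50 Hz notch (Q = 30), all zero-phase. Filters are designed in
  zero-pole-gain form (the 0.1 Hz transfer-function polynomial is
  ill-conditioned at a 4e-4 normalized cutoff) and the forward–backward
  magnitude-squared response |H(w)|^2 is applied spectrally after
  even-reflection padding sized from the slowest pole's time constant.
  This equals the steady-state result of a filtfilt pass while avoiding
  the seconds-long edge transients a 0.1 Hz IIR high-pass produces in the
  time domain; measured passband gain is 1 within 0.1% and the 50 Hz
  residual is about 2%.
* **Epoch convention.** Half-open windows [-200, 1000) ms relative to
  onset, 0-based in time so that at 500 Hz every epoch has exactly 600
  samples; baseline [-200, 0) ms, subtracted per trial and channel.
  Stated explicitly because closed-bracket notation is ambiguous at the
  endpoint.
* **PLV band.** The phase-extraction band defaults to 1–30 Hz in the
  pipeline. The low edge must complete at least one cycle within the
  1.2 s epoch (a hard precondition of `instantaneousPhase`); 0.1 Hz would
  need 10 s epochs. The band is configurable for narrow-band analyses; the
  generator's coupling frequency (10 Hz) sits comfortably inside it.
* **PLV trial-count equalization.** The finite-trial PLV estimator has a
  positive noise floor E[R] ~ sqrt(pi)/(2 sqrt(K)). With 86 neutral vs 24
  pooled-emotional trials this floor differs by condition (~0.10 vs
  ~0.18) and would masquerade as a condition effect on every edge, so the
  pipeline subsamples the larger condition to the smaller count (seeded,
  reproducible) before estimating PLV — standard practice in
  event-related PLV work. For the same reason, parameter-recovery tests
  compare the measured PLV against the finite-K Monte-Carlo expectation
  of the von Mises model rather than the asymptotic Bessel ratio (at
  kappa = 0 the bias never vanishes: the Bessel ratio is 0 while E[R] at
  K = 86 is about 0.095).
* **Artifact rejection.** ICA is not part of this package (it is an
  external algorithm, not this pipeline's contribution); epochs are
  rejected when any scalp channel exceeds 150 uV peak-to-peak (the
  documented, configurable default; no universal threshold exists), and
  a hook exists for inserting an external decomposition before epoching.
  Bad channels are rebuilt by inverse-great-circle-distance weighted
  averaging of the remaining scalp channels.
* **Permutation / FDR family.** The FDR family is all channel x timepoint
  cells of one contrast (12 000 at full scale). With 1000 permutations the
  smallest attainable p is 1/1001, so a BY-significant mask requires a
  spatially extended effect (roughly a fifth of the family at the minimum
  p); this is a property of the published procedure itself, reproduced
  faithfully rather than patched.
* **ANOVA engine.** The mixed-design table is computed via a multivariate
  linear model with Type III sums of squares and an
  orthonormal-contrast within-subject design (the SPSS convention used in
  this literature); Mauchly's W and Greenhouse–Geisser epsilon are
  computed in-package from the contrast covariance. F is reported as 0
  when an effect's sum of squares vanishes and as Inf (with a
  `degenerate` flag) when an error stratum has zero variance. Tests
  verify equivalence with a hand-rolled split-plot sums-of-squares oracle
  to 1e-8 on balanced tables.
* **Edge-wise statistic.** Connectivity maps in this literature are often
  reported only with significance thresholds; paired (or pooled
  two-sample) t tests are used here to mirror the property-level
  parametrics, documented as this package's assumption.
* **P3a window.** Conventions vary; 250–400 ms frontal is the
  configurable default.

## Problem sizes used by the test suite

The acceptance suite runs the full design conditions where the check is
about the design itself (45 subjects, 110-stimulus blocks for the
three-group pattern; 200 null simulations of 20 subjects x 200 cells for
FDR control; 50 simulated subjects per kappa for PLV recovery; 100
eight-node graphs for the metric oracles). Unit tests use smaller blocks
(4–24 events, 4–6 channels, 100–250 Hz) chosen so each property remains
sharply testable.

## Known limitations

* The spectral zero-phase filter assumes offline (whole-recording) data;
  it is not a causal/online filter.
* EDF support covers EDF/EDF+C with a single annotation signal and equal
  per-signal rates — sufficient for this pipeline's exports, not a general
  EDF browser.
* The mixed ANOVA handles one between- and one within-subject factor (the
  study design); it is not a general factorial engine.
* Graph metrics assume non-negative weights; PLV matrices satisfy this by
  construction.
* Small-worldness uses weight-shuffling onto degree-preserving rewired
  edges; other null models (strength-preserving, spatial) are out of
  scope.
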