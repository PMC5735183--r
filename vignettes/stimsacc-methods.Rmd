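---
title: "Methods: saccade analysis for prefrontal microstimulation experiments"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: saccade analysis for prefrontal microstimulation experiments}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stimsacc)
```

## The scientific setting

`stimsacc` analyzes oculomotor data from experiments in which single
electrodes of a chronically implanted microelectrode grid in prefrontal
cortex (the 8Av/45 region between the frontal eye fields and the ventral
prearcuate area) are electrically stimulated while a monkey performs a
center-out saccade task: after 800 ms of central fixation the fixation
point jumps 7 degrees left or right and the animal saccades to it.
Stimulation (100 or 250 uA) is delivered on half of the trials of each
electrode's block, concurrently with the jump. Three families of questions
are addressed:

1. **Evoked saccades.** Does stimulation *directly* trigger saccades, on
   which electrodes, and how do evoked vectors depend on current?
2. **Latency effects.** Does stimulation change the reaction time of the
   *voluntary* task saccade, separately for saccades directed into the
   hemifield contralateral ("contraversive") or ipsilateral
   ("ipsiversive") to the stimulated hemisphere, and does the effect
   depend on the rostro-caudal position of the electrode?
3. **Kinematics.** Does stimulation change saccade peak velocity,
   amplitude, or endpoint accuracy?

Because raw recordings from such experiments are not publicly deposited,
the package pairs the analysis pipeline with a synthetic eye-trace
generator whose defaults encode the study conditions. Every stage of the
pipeline is validated by recovering what the generator injected.

## The synthetic-data generator

`sim_config()` + `simulate_session()` produce per-trial gaze traces
(500 Hz, degrees), trial metadata, an electrode map and a ground-truth
table.

**Saccade waveform.** Saccades translate the gaze along a straight line
with the raised-cosine velocity profile
$s(t) = A\,(t/D - \sin(2\pi t/D)/(2\pi))$, which starts and ends at zero
velocity and peaks at $2A/D$ in mid-flight. Duration follows a linear main
sequence $D = d_0 + d_1 A$ with defaults $d_0 = 21$ ms, $d_1 = 2.2$
ms/deg, giving a 7-degree saccade a duration of 36.4 ms and a peak
velocity of about 385 deg/s — typical primate values. Both constants are
configurable (`main_sequence`).

**Latencies.** Task-saccade latencies are ex-Gaussian (Gaussian plus
exponential tail), the standard right-skewed model for saccadic reaction
times: `ipsi ~ exG(mu = 186, sigma = 25, tau = 40)` ms and
`mu_contra = mu_ipsi - 26` ms by default, encoding the 26 ms baseline
advantage of contraversive saccades the task conditions assume. On
stimulated trials a configurable shift (the *effect map*, keyed by
electrode group x current x direction) is added: by default ipsiversive
saccades are speeded everywhere on the array (-9 ms at 100 uA, -22 ms at
250 uA) while contraversive saccades are delayed only under caudal
stimulation (+4 / +25 ms). Draws are redrawn while a shifted latency
would fall at or below 10 ms, a floor that is hit with negligible
probability at the defaults.

**Evoked saccades.** A cluster of seven electrodes on the caudal border
of the grid can evoke saccades on stimulated trials: four "robust" sites
evoke at both currents (probability 0.5 at 100 uA, 0.85 at 250 uA —
chosen so the expected evoked-frequency odds ratio between currents is
about 0.18) and three peripheral sites essentially only at the high
current (0.05 vs 0.7). Evoked vectors point into the contralateral
hemifield: direction is von Mises around an electrode-specific mean
(kappa = 20), rotated by +8 degrees at the high current; amplitude is
Gaussian around an electrode-specific mean scaled by 1.3 at the high
current. Evoked onset is uniform in [20, 60] ms after stimulation onset —
inside the 100 ms evoked window but away from its edges, so window-edge
ambiguity cannot contaminate recovery tests. The subsequent task saccade
then starts from the evoked endpoint.

**Noise and sessions.** Isotropic Gaussian noise (sd 0.05 deg) is added
to every sample; task saccades land on the target with an additional
per-axis scatter of 0.35 deg, giving realistic non-zero endpoint errors.
A session runs one 20-trial block per electrode x current with exactly
half the trials stimulated and left/right jumps balanced within one trial
per block; the default 96-electrode, two-current session has 3840 trials.
Optional track-loss gaps (`blink_rate`) inject NaN samples for
robustness testing; they are off by default.

**What the generator does not emulate.** Fixational drift and
microsaccades, smooth pursuit, saccade curvature, main-sequence
variability (duration is deterministic given amplitude), per-subject
heterogeneity (one synthetic subject), error trials (all outcomes are
"correct"), and any electrical or neural signal — stimulation exists only
as metadata, since the analysis never inspects a waveform. Passing the
validation suite therefore demonstrates the *pipeline's* correctness under
the stated statistical structure, not robustness to every artifact of real
eye-tracking data.

## Saccade detection

Speed is the Euclidean norm of central-difference velocities (one-sided
at the trace edges), optionally boxcar-smoothed. A saccade is a maximal
run of samples with smoothed speed above 100 deg/s; runs separated by
sub-threshold gaps shorter than 10 ms are merged and runs shorter than
6 ms are discarded. Onset is the first suprathreshold sample, offset the
last plus one sample. Candidate runs touching missing (NaN) samples are
excluded with a logged reason, never interpolated.

**Why a 30 ms smoothing window.** A fixed 100 deg/s criterion detects a
7-degree raised-cosine saccade only ~6 ms after its kinematic onset (the
time speed needs to reach the criterion), so any narrow smoother leaves a
~6-7 ms systematic onset lag and clips ~5% of the amplitude at both ends.
A centered boxcar that is wide relative to this rise time (15 samples =
30 ms at 500 Hz) advances the detected crossing towards the kinematic
onset and symmetrically extends the offset: measured on noiseless traces
across sub-sample onset phases, the mean onset error drops from 6.7 ms
(5-sample window) to 2.9 ms and the amplitude bias to 0.5%. The window is
still an order of magnitude shorter than inter-saccade intervals and
leaves the fixation-noise false-alarm rate at zero. Because wide smoothing
biases the *smoothed* peak low, peak velocity is always measured on the
unsmoothed central-difference speed. The window is a configurable
argument of every detection entry point.

## Classification and exclusion rules

A saccade is **evoked** if initiated within 100 ms of stimulation onset
(latency in [0, 100) ms) with duration <= 75 ms, and **task-related** if
initiated 100-400 ms after the jump with duration < 75 ms; everything
else is **other**. The two windows share the 100 ms boundary; taking the
evoked window right-open and the task window left-closed (and the
duration edge <= 75 vs < 75, both read literally from their definitions)
makes the classes provably disjoint. Stimulation coincides with the jump,
so one reference time serves both. Only the first task-classified saccade
of a trial enters latency analyses.

An electrode counts as *saccade-evoking* at a current when at least 30%
of at least 10 stimulation trials show an evoked saccade — the
generalization of "3 of 10" that reduces to it exactly at the standard
block size. Electrodes evoking at the highest current, and electrodes
flagged broken, are excluded: their *stimulation* trials are removed from
all latency, spatial and kinematics analyses. Their interleaved control
trials are retained, since no stimulation was delivered on them; the
spatial analysis, which pairs each electrode's stimulation trials with
its own block's controls, drops excluded electrodes entirely.

Evoked-saccade endpoints are summarized by the 95% confidence ellipse of
a bivariate-normal fit: center at the mean, axes along the eigenvectors
of the sample covariance, semi-axes $\sqrt{\chi^2_2(0.95)\,\lambda_i}$.

## Statistical procedures

**Reciprocal transform.** Latency tests run primarily on rates
$1000/\mathrm{RT}$ (1/s), which normalizes the right-skewed RT
distribution; mean and median differences are always reported in raw
milliseconds alongside, and raw-scale t and Wilcoxon rank-sum companions
are computed for robustness.

**t-tests.** The pooled-variance Student form is the default (matching
the convention of the tool family these analyses descend from); Welch is
available behind a flag. Zero-variance inputs yield an explicitly flagged
degenerate result rather than a silent NaN.

**Fisher's exact test** enumerates the full hypergeometric support of
the 2x2 table with fixed margins; the two-sided p-value sums all tables
no more probable than the observed one, with a 1e-7 relative slack
absorbing floating-point ties. The odds ratio is the sample
cross-product ratio (0 or infinity when degenerate), not the conditional
MLE.

**Circular two-way ANOVA (Harrison-Kanji).** Directional responses are
decomposed into two factor effects and an interaction via squared
resultant lengths. The concentration kappa is estimated from the grand
mean resultant length (Fisher's piecewise approximation). For kappa > 2
the F approximation with the $1 + 3/(8\kappa)$ correction applies; below
that the chi-squared approximation is used and the result is flagged
unreliable. Because the asymptotic regimes are approximate, a seeded
permutation companion p-value (shuffling responses across cells; 9999
permutations by default) is always available and the calibration tests
require parametric and permutation decisions to agree. A single-level
second factor collapses its term to df 0 instead of failing; empty cells
under an interaction design are an explicit error.

**Linear two-way ANOVA** (for evoked amplitudes) uses Type II sums of
squares by default: identical to the classical decomposition on balanced
designs, order-invariant on unbalanced ones, with Type I/III behind a
flag since the convention for unbalanced evoked counts is genuinely
underdetermined.

**Multiplicity.** The four spatial tests (group x direction) use
Bonferroni alpha 0.05/4 = 0.0125; each kinematics measure's family of
eight comparisons (2 directions x 2 currents, 2 directions pooled over
current, 2 currents pooled over direction) uses 0.05/8 = 0.00625.

## The four analyses and their data flow

`run_full()` executes detection, classification, electrode exclusion and
then:

- **Evoked analysis** — per electrode x current evoked counts and
  inclusion flags; restricted to electrodes evoking at both currents:
  Fisher test of evoked frequency vs current, circular ANOVA of direction
  ~ electrode x current, linear ANOVA of amplitude; and the same three
  with currents pooled and the *instructed* jump direction as second
  factor (a negative control: instructed direction should explain
  nothing about the evoked movement).
- **Latency analysis** — baseline contra-vs-ipsi comparison on control
  trials (overall and per block current), then stimulation-vs-control per
  direction x current. Control trials are grouped by their block's
  current, i.e. the current of the interleaved stimulation trials.
- **Spatial analysis** — at the strongest current only: per electrode
  and direction, mean stimulated latency vs the mean of the same block's
  control trials (block-local controls; session-wide pooling was the
  plausible alternative, but block-local pairing is what "interleaved
  controls" denotes and it cancels slow drifts). Group-level paired
  t-tests across electrodes are run on these per-electrode means on the
  raw millisecond scale — they are already averages, approximately
  normal, and the plotted quantity. Between-group two-sample t-tests
  compare per-electrode effects per direction.
- **Kinematics analysis** — stimulated vs control two-sample t-tests on
  peak velocity, amplitude and endpoint error per subset family above.

Every trial is accounted for in a filter ledger (`trials_in` equals
`trials_kept` plus the per-filter exclusion counts), and the report
(JSON plus CSV tables) carries the seed, thresholds and package version
so a run is exactly reproducible: the same seed yields a byte-identical
`report.json`.

## Validation strategy and problem sizes

The test suite validates each stage against independent oracles (dense
resampling for kinematics, exhaustive enumeration for Fisher, Watson-
Williams for the collapsed circular design, hand-computed sums of squares
for the linear ANOVA) and the pipeline end-to-end against generator
ground truth. The package's chosen validation sizes: detector recovery on
a 1008-trial session; circular-ANOVA calibration with 2000 null
replicates (2x2, 20 observations per cell, kappa 5) and 200 mixed
datasets for permutation agreement; end-to-end recovery on 100 seeded
replicates of the full default session (~480 stimulated trials per
direction x current); null calibration on 200 seeded replicates of an
8-electrode no-effect session. At ~480 trials per condition a single
condition estimate carries about 3 ms of sampling error, so per-seed
estimates are checked for coverage of a +/-5 ms band around the injected
effect while the across-seed bias must stay below 2 ms.

## Known limitations

- The velocity criterion cannot time saccade onset more precisely than
  the speed rise time allows; the residual ~2-3 ms onset lag is inherent
  to single-threshold detection, and latencies inherit it (it cancels in
  all stimulated-vs-control contrasts).
- The chi-squared regime of the circular ANOVA (kappa < 2) is known to be
  poorly calibrated; results there should be read from the permutation
  p-values only.
- Evoked and task saccades closer than the merge gap can fuse into one
  "other"-classified event; this costs a small fraction of trials on
  evoking electrodes, which are excluded from latency analyses anyway.
- The generator's single-subject default cannot exhibit between-animal
  heterogeneity; analyses pool all trials.
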