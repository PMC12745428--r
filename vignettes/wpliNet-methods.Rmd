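---
title: "Motor-task EEG brain networks with wpliNet: models, parameters, design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Motor-task EEG brain networks with wpliNet}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wpliNet)
```

## The analysis in one paragraph

wpliNet implements a sensor-level functional brain-network analysis for
multi-channel motor-task EEG, aimed at group comparisons between stroke
patients with upper-limb spasticity and healthy controls. Continuous
recordings over the 19-electrode international 10-20 montage are
conditioned deterministically (all stages pure functions) (zero-phase FIR band-pass 0.1-45 Hz,
49-51 Hz notch, decimation, linked-ear re-referencing, cue-locked 5-s
epochs with a 1-s pre-movement baseline, and lateral mirroring of
right-affected subjects). Phase synchrony between every channel pair is
estimated with the weighted phase lag index,

$$\mathrm{wPLI}_{xy} \;=\; \frac{\bigl|\,E[\Im(S_{xy})]\,\bigr|}{E\bigl[|\Im(S_{xy})|\bigr]},$$

where $S_{xy} = C_x C_y^{*}$ is the short-time Fourier cross-spectrum
and the expectation pools trials (and, by default, the sliding analysis
windows within the 0-4 s action period). Because a zero-lag (volume
conducted) component contributes only to the real part of $S_{xy}$, the
estimator is insensitive to instantaneous mixing - the property that
motivates it over plain coherence. Band-averaged 19x19 wPLI matrices
(delta 2-4, theta 4-8, alpha 8-13, beta 13-30 Hz) are binarized at seven
sparsity levels (17-47 % of the 171 possible edges, in 5 % steps), and
each binary graph is summarized by node degree, clustering coefficient
(CC), characteristic path length (L), local efficiency (LE), global
efficiency (GE), and small-worldness $\mathrm{SW} = (C/C_{rand}) /
(L/L_{rand})$ against degree-preserving rewired references. Group
inference runs per task x band x metric: Shapiro-Wilk gates each
comparison into a pooled-variance t-test or a Mann-Whitney U test,
Cohen's d is always reported, p-values are Benjamini-Hochberg adjusted
across the full comparison grid of a run, and network metrics are
Spearman-correlated with Modified Ashworth Scale (MAS) grades inside
the patient group.

## Key parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| band-pass edges | 0.1-45 | Hz | removes drift and high-frequency noise while spanning all analysis bands |
| notch | 49-51 | Hz | 50 Hz mains region |
| resampling target | 500 | Hz | halves data volume; Nyquist stays far above 30 Hz |
| epoch window | [-1, +4) | s | 1 s pre-movement baseline, 4 s action period |
| STFT window / hop | 0.4 / 0.2 | s | Hann taper; 50 % overlap trades variance for temporal coverage |
| frequency grid | 1-30, step 1 | Hz | windows are zero-padded to one second of samples so the 1-Hz grid is exact (a 0.4 s window natively yields 2.5 Hz spacing) |
| sparsity profile | 0.17-0.47 by 0.05 | fraction | equal edge counts across subjects; sparse enough to stay informative, dense enough to stay connected for structured matrices |
| random references | 100 | graphs | degree-preserving double-edge swaps, at least 10x the edge count of attempted swaps each |
| normality gate | 0.05 | alpha | both groups must pass Shapiro-Wilk for the t-branch |
| MAS coding | 0, 1, 1.5, 2 | ordinal codes | conventional midpoint coding of the 1+ grade |

Conventions for degenerate cases are explicit: nodes of degree < 2 have
CC and LE contributions of 0 (the defining formulas divide by
$k(k-1)$); unreachable pairs contribute $1/\infty = 0$ to GE and are
excluded from L (with their count logged); network means always divide
by all 19 nodes; ties at a sparsity cut are broken by fixed
lexicographic node order, so thresholding is deterministic; a wPLI
denominator of zero (no imaginary mass at all) yields 0 by declared
convention. Band edges shared by neighboring bands (4, 8, 13 Hz) are
owned half-open by the upper band, and beta additionally owns its 30 Hz
edge, so the four bands tile the grid without double counting. Whether
the wPLI expectation pools windows or averages per-window estimates is
exposed as a switch (`pool_windows`), pooled by default.

## The synthetic cohort generator

No public data accompany the study conditions this package models, so
the generator is a first-class module: every downstream stage is tested
against cohorts with known ground truth. A recording is a sum of a
band-specific oscillator field, optionally smeared by zero-lag
nearest-neighbor mixing over a fixed 10-20 scalp adjacency
(`mixing_strength`, default 0.2) that emulates instantaneous volume
conduction - precisely the nuisance wPLI must reject - plus independent
per-electrode sensor noise (`noise_sd`, default 2 relative to unit
driver amplitude; calibrated per sample at a 250 Hz reference rate and
scaled with the square root of the simulation rate so the noise
spectral density, and with it every per-bin signal-to-noise ratio, is
invariant to the rate the cohort is generated at). Only the neural
field is mixed; sensor noise enters at the electrode. Each oscillator
process draws a fresh uniform phase per trial and then drifts by a
Brownian phase walk (2 rad per square-root second) shared by all
channels it drives, so its lag structure is constant while successive
analysis windows decorrelate, as the finite coherence time of real EEG
rhythms makes them do. Within a trial the pairwise lag never changes -
the consistency wPLI detects - while trial-to-trial phases are
independent, so zero-lag artifacts average out.

The default ("control") interaction structure in the alpha and beta
bands has three graded tiers: two hemispheric ring lattices between
scalp neighbors (strength 1.0; triangle-free, confined to one
hemisphere), a ring-second-neighbor chord tier (0.45) whose triangles
carry the network's clustering, and a hub-star process in which the
vertex electrode Cz drives all other nodes at phase offsets staggered
over 30-150 degrees (0.5) - the interhemispheric integration backbone
that keeps every node within two hops. Patients are modeled by
multiplying all coupling strengths by a subject factor
$f = 1 - (1-a)u$, $u \sim U(0.85, 1.15)$ around the cohort attenuation
$a$ (default 0.3), clipped to $[0,1]$; at $a = 1$ the factor is exactly
1, making the groups exchangeable. The narrow $\pm 15\,\%$ spread
mirrors a cohort restricted to moderate spasticity (MAS 1 to 2) and was
fixed at design time by a pilot power analysis so that planted effects
are of the same order as the very large published group effects
(d between about 2.6 and 4.4). MAS-like grades are assigned by ranking
the true factors into the four grades 2, 1+, 1, 0, so severity
co-varies monotonically with attenuation by construction; one patient
in eight is right-affected and is mirrored during preprocessing.

Attenuation acts through the wPLI noise floor: the weak chord and star
tiers of a patient sink under the floor while the strong rings survive,
so patient networks lose their triangle tier and their interhemispheric
backbone, drifting toward noise-ranked topologies - lower CC, LE and GE
than controls with small-worldness relatively preserved, the
qualitative pattern reported for this clinical population. Two
properties of this mechanism deserve emphasis. First, because graphs
are built by rank thresholding at a fixed edge count, a patient's graph
is always "control ranking plus noise fill", and random fill is nearly
as globally efficient as any structured 19-node design: the aggregate
GE of a diameter-2 hub design is at most about 0.66 versus about 0.62
for noise-ranked graphs. The planted GE effect therefore sits close to
a structural ceiling, and its recovery rate is intrinsically more
fragile than that of CC or LE. Second, what the generator does *not*
model - real head-volume conduction with a leadfield, artifacts,
non-stationary task dynamics, heterogeneous lesions - means a passing
recovery suite demonstrates the pipeline's correctness and statistical
calibration on signals with known lagged coupling, not clinical
validity on patient EEG.

## Problem sizes used by the tests and the acceptance script

Full-scale study conditions (the package defaults) are 8 subjects per
group, three tasks, 20 trials per task at 1,000 Hz downsampled to
500 Hz, four bands, and 100 random-reference realizations. The test
suite and the acceptance script run the same pipeline at reduced sizes
chosen as a deliberate design point: one task, 8 trials per subject at
250 Hz, the alpha and beta bands, and 3-20 reference realizations.
Eight trials is a genuine optimum of the recovery experiment, not just
a cost saving - with fewer trials the estimator cannot rank the
control tiers faithfully, with more the patients' attenuated tiers
re-emerge from the noise floor, and both flanks lose power. Replicate
recovery runs (`replicateRecovery()`) enter the estimator directly at
the generation rate: the synthetic signals are already band-limited, so
the FIR/notch/resampling stage - exercised end to end by the demo
pipeline runs and the preprocessing tests - would be a scientific no-op
there.

## Numerical choices

* **Filtering.** Windowed-sinc (Hamming) FIR kernels from a
  transition-width heuristic (about $3.3 f_s/\Delta f$ taps), applied
  by FFT overlap convolution with the group delay removed, so filtering
  is zero-phase and cue alignment is preserved; signal edges use
  reflective padding. The order is capped at a third of the signal
  length.
* **Epoching.** Boundary-crossing epochs are dropped, never padded;
  the baseline window $[-1, 0)$ s is half-open - the cue sample belongs
  to the action period. Only the post-cue action period enters
  connectivity.
* **Thresholding.** Edge counts are `round(s * 171)`; a disconnected
  result warns but proceeds under the documented conventions.
* **Random references.** Seeded double-edge-swap rewiring via igraph
  keeps every degree sequence exactly; for a complete graph (no swap
  possible) the graph's own metrics are returned with a warning, making
  SW exactly 1.
* **Determinism.** One master seed per run; every stage and replicate
  derives child seeds from it, and library code restores the caller's
  RNG state, so identical configurations give byte-identical metric and
  statistics tables.

## Open design points and how they were resolved

* The 21-channel recording montage versus the 19-node analysis montage:
  fixed to the 19 listed nodes plus A1/A2 references; re-referencing
  consumes the references.
* The paper-level choice of which MAS column drives the severity
  correlation is configurable (`mas_column`), defaulting to the upper
  limb.
* The FDR family defaults to the full band x metric x task grid of one
  run; per-task families are available by flag.
* Signed-rank alternatives to Mann-Whitney apply to paired designs;
  this design has none, so only Mann-Whitney is implemented.
* Aggregation across the seven sparsity levels uses the plain mean
  (area-under-curve equivalent for evenly spaced levels); per-level
  values are always retained so either analysis can be reproduced.

## Known limitations

Interactive artifact removal (ICA with component classification) is
intentionally out of scope; real data should be pre-cleaned upstream.
The generator's white-noise background makes its wPLI null cleaner than
real EEG's 1/f background. Global-efficiency group effects operate near
the structural ceiling discussed above, so their replicate-to-replicate
recovery rate is the most sensitive of the suite; clustering and local
efficiency effects are robust. Sensor-level networks say nothing about
sources, and nothing here performs source localization.
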