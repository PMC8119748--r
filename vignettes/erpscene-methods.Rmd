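---
title: "Models and methods behind erpscene"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind erpscene}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(erpscene)
```

## The experiment this package models

`erpscene` implements the analysis chain of a visual target-detection
paradigm with natural-scene stimuli: observers view aerial image patches and
report whether a vehicle is present, under two attention regimes — a
*single task* (detection only) and a *dual task* (detection plus a
scene-similarity question on one third of trials that forces active
observation of the background). Stimuli come in two background complexity
levels (simple vs complex scenes), and targets are rare relative to
non-targets (1:3, the classic oddball arrangement). EEG is recorded from 63
scalp channels (10-10 layout, Iz reference) at 1,000 Hz. Two event-related
potential (ERP) components carry the analysis:

* **LOP** (late occipital positivity): a positive deflection over occipital
  electrodes (O1, O2, PO3, PO4, PO7, PO8) around 350 ms, read as an index of
  attentional cueing; condition effects appear in its amplitude.
* **CPP** (centro-parietal positivity): a late positivity over Cz, CPz, Pz,
  CP1, CP2 between roughly 400 and 650 ms, read as sensory-evidence
  accumulation; background complexity delays its peak (520 ms for simple vs
  608 ms for complex scenes, pooled over tasks), and the dual task delays it
  further.

Because raw recordings of such studies are rarely redistributable, the
package pairs the analysis chain with a seeded synthetic-data generator, so
every stage is testable end to end at desk scale.

## Stimulus screening

Candidate 240 x 240 8-bit RGB patches are scored on four measures:

* histogram (Shannon) entropy of the 256-bin gray-level histogram, in bits,
  with gray = round(0.299 R + 0.587 G + 0.114 B);
* gray-level uniformity, defined here as the mean within-tile population SD
  over non-overlapping 16 x 16 tiles. The classical uniformity index this
  stands in for is not uniquely defined in the literature we follow; our
  variant preserves its direction (larger = more heterogeneous texture) and
  is exposed as a swappable scoring function;
* brightness, the HSI intensity mean (R + G + B) / (3 * 255), in [0, 1];
* vehicle size, the absolute shoelace area of the 4-point location
  quadrilateral (winding-normalized), target patches only.

Outliers are removed by iterated interquartile fences: for each measure in
the fixed order entropy, uniformity, brightness, size, patches outside
[Q1 − 1.5 IQR, Q3 + 1.5 IQR] are dropped and quartiles recomputed from the
survivors; the sweep repeats until a full pass removes nothing. Quartiles
use the linear-interpolation convention (R type 7) — fence membership at
the boundary depends on the convention, so it is fixed and documented;
boundary values are kept. The removal order within a pass is configurable
since only "sequential" removal is specified by the tradition we follow.

Design assembly reserves 20 patches per type for practicing (one random
rotation each, split 10/10 between tasks), then builds the testing set from
the remaining 300 targets per complexity (1 rotation each) and 300
non-targets per complexity (3 distinct rotations each): 600 target and
1,800 non-target trials. Trials are split equally by type between tasks,
then sessions, then randomized into three 200-trial single-task or five
120-trial dual-task blocks per session; each dual-task session flags 50
trials per type (one third of its trials) for a similarity question.

## Synthetic data generator

`synth_config()` holds the study conditions. Values printed by the source
literature are defaults: CPP scene latencies 520/608 ms, reaction-time
means 0.599/0.811/0.998/1.267 s and detection accuracies 0.992/0.970/
0.990/0.978 per task x scene cell, similarity accuracy 0.857/0.853,
inter-stimulus interval uniform on 1.25–1.5 s, 63-channel montage at
1,000 Hz. Where no value is printed we chose once, on field-typical
grounds, and did not revisit:

* **Component shape.** ERP kernels are Gaussians in time (SD `width_ms`:
  50 ms LOP, 60 ms CPP) scaled by fixed spatial weight profiles (weight 1 on
  the component's cluster, 0.3 on immediate neighbors, 0 elsewhere — in
  particular 0 on the other component's cluster, so cluster means measure
  one component each). Gaussians admit closed-form checks (peak location,
  half-maximum crossings at latency ± width √(2 ln 2)).
* **Task effect on CPP latency**: ±20 ms around the per-scene mean (single
  earlier, dual later), so the pooled scene means stay exactly at 520/608 ms
  while the dual > single latency contrast also holds.
* **Amplitudes** (µV, at the cluster): CPP 8 for targets, 5 (single) / 6.5
  (dual) for non-targets; LOP 4–6.5 patterned so targets, complex
  backgrounds and the single task raise it. These reproduce the qualitative
  amplitude contrasts the statistics are meant to detect.
* **Between-participant dispersion**: normal random effects drawn once per
  participant — latency SD 25 ms (CPP) / 15 ms (LOP), amplitude SD 1 /
  0.8 µV. The reported group dispersions of jackknife latency analyses are
  not uniquely invertible to a between-subject SD, so this is a calibration
  choice, not an estimate.
* **Noise**: per-channel pink noise (power ∝ 1/f, generated by the standard
  pole-zero "pinking" cascade; the spectral exponent is configurable, other
  exponents use FFT shaping) at 8 µV SD plus white noise at 4 µV SD.
  Channels are spatially independent — real EEG noise is spatially
  correlated, which is one of the ways the generator is *less* favorable
  than real data to cluster averaging, and one of the ways it is simpler.
* **Blinks**: a half-sine of a 4 Hz cycle (~125 ms), 100 µV, weighted onto
  frontal channels, added to a fraction `artifact_rate` (default 5%) of
  epochs at a random latency. Their only purpose is to exercise epoch
  rejection; they are deliberately rare, because probability-based
  rejection criteria detect artifacts through their rarity.
* **Behavior**: trial RT is lognormal around a per-participant,
  per-condition median; a single participant-level latent speed factor is
  scaled by each condition's coefficient of variation (taken from the
  condition table), reproducing both the condition means and the
  across-participant SDs. Detection correctness is Bernoulli per condition;
  similarity correctness is Bernoulli with a per-participant accuracy drawn
  from N(condition mean, 0.067), truncated to [0.5, 1]. An optional switch
  couples RT to the trial's CPP latency instead (off by default: the link
  is a hypothesis, not a measurement).
* **Timeline**: onsets advance by RT + ISI and are aligned to a 4 ms grid
  so that downsampling to 250 Hz never shifts an event. The dual-task
  question period is *not* inserted into the continuous timeline; question
  flags and answers live in the events table only. Trials per bin default
  to 16 per participant — per-bin trial counts surviving rejection are not
  published for the paradigm, and 16 keeps a 48-participant run at desk
  scale while leaving single-participant waveforms realistically noisy.
* **Determinism**: every stage seeds its RNG from the master seed via a
  documented fan-out (seed * 1103 + stage-id * 10007 + index * 101, mod a
  prime below 2^31), so identical configurations are byte-identical and
  participants are independent streams.

Synthetic stimulus patches are smooth low-frequency textures (simple) or
the same plus mid- and fine-scale high-contrast structure (complex), with
brightness and vehicle-size distributions shared across levels — so
entropy/uniformity separate the groups while brightness/size do not,
which is exactly the pattern the screening statistics should report. They
are statistical stand-ins, not imagery: passing tests show the *screening
chain* behaves correctly, not that any particular image corpus would
survive it.

## Preprocessing

The stage order is fixed: resample/filter → average re-reference → epoch →
baseline → probability-based rejection (re-referencing and baselining are
idempotent). Resampling to 250 Hz uses an 81-tap symmetric windowed-sinc
anti-alias low-pass (cut at 80% of the target Nyquist), zero-phase by
symmetry, evaluated only at kept samples; the band-pass (0.5–100 Hz,
4th-order Butterworth) and 50 Hz notch (2nd-order band-stop, ±2 Hz) run
forward-backward, so no stage introduces delay. Epochs span [−200, +1000)
ms (300 samples at 250 Hz); the per-channel mean over [−200, 0) ms is
subtracted — the half-open edge excludes the onset sample. "All scalp
electrodes" excludes the recording reference from the average.

One distortion is worth knowing about: a 0.5 Hz high-pass removes a few
percent of a component as wide as the CPP, producing a symmetric undershoot
of up to ~8% of the peak. Peak *latencies* are unbiased (the undershoot is
symmetric); peak amplitudes are slightly conservative. The recoverability
tests therefore compare pipeline output against the kernel passed through
the closed-form filter magnitude response rather than the raw kernel.

Joint-probability rejection is specified concretely because only SD
thresholds are conventional: per channel, an epoch's joint log-probability
is the sum over samples of the log empirical density of that channel's
values (histogram over all epochs, 100 bins, floor 1e−12); z-scored across
epochs, an epoch is flagged if any channel exceeds 6 SD or the
channel-summed log-probability exceeds 2 SD. Flags are kept, never
deleted, so rejection fractions are reportable statistics. With Gaussian
data the 2 SD global rule flags ≈5% of clean epochs — consistent with the
rejection rates such pipelines report in practice. An `ica_hook` slot
exists for component-based artifact correction, but the default pipeline
performs none: independent-component selection is a manual, inherently
non-reproducible step and is out of scope.

## Statistics

* **Bin ERPs**: retained, behaviorally correct epochs are averaged within
  participant x bin, then over cluster channels.
* **Pointwise comparisons**: two-tailed two-sample t-tests with pooled
  variance at every time point (the tradition we follow asserts normality
  and equal variances), Benjamini–Hochberg step-up over the trace at
  q = 0.05, maximal runs of significant samples reported as intervals. A
  time point with zero pooled variance reports p = 1.
* **Peak measures**: maximum within the component window (both components
  are positive), earliest sample on ties. Windows: CPP 400–650 ms from the
  component's definition; LOP 250–450 ms, a choice bracketing the ~350 ms
  peak with the same margin, since no window is printed for it. Both are
  arguments, not constants.
* **Jackknife latency test**: leave-one-out grand averages per group, peak
  latency of each; group variance (n−1)/n Σ(Lᵢ−L̄)²; SE of the difference
  √(var_A + var_B); t = (difference of full grand-average latencies)/SE on
  n_A + n_B − 2 df, two-tailed. The df convention is our documented choice;
  the source tradition does not print one. For *linear* statistics this SE
  provably collapses to the ordinary two-sample SE of participant means —
  a closed-form identity the tests verify to 1e−9. When the SE is exactly
  zero with a nonzero difference (noiseless fixtures), p is reported below
  the machine floor with a flag.

  One numerical point deserves emphasis: the jackknife variance formula
  assumes a statistic that responds *smoothly* to the data, and a raw
  sample-grid argmax does not — when the grand-average top is broad,
  leave-one-out perturbations make the argmax hop between near-tied
  samples, and the (n−1)-inflation turns those hops into an SE that is
  orders of magnitude too large (the same reason the jackknife fails for
  the median). Subaverage latencies are therefore measured after a mild
  moving-average smoothing (default 28 ms, a ~16 Hz equivalent — within
  the conventional 10–20 Hz low-pass range for ERP peak measurement) with
  parabolic vertex interpolation between samples; both are arguments.
  `peak_measure()` itself keeps the plain grid argmax with the
  earliest-sample tie rule.
* **Performance splits**: participants ranked on detection RT (shorter =
  better) or similarity accuracy (higher = better); extreme k = 16 (or 12)
  per group, ties broken by participant id.
* Within-participant condition contrasts are analyzed with *two-sample*
  tests throughout, mirroring the procedure of the paradigm we reproduce,
  not substituting paired tests.

## Problem sizes and what the tests show

The package's own verification runs at deliberately chosen desk scales:
parameter recovery uses the full default configuration (48 participants,
16 trials/bin, 63 channels); the FDR null control uses 200 Monte-Carlo
repetitions of 12-vs-12 participant-level waveforms drawn by
`simulate_participant_waveforms()` — kernels plus participant effects plus
smooth residual noise at the SD that survives trial averaging — rather
than 200 full EEG syntheses, which would add nothing to the null behavior
of the statistic; oracle-equivalence checks run on 5-participant,
10-sample toys where brute force is exact. Passing these shows the chain
is implemented correctly and recovers what was injected under the stated
noise model; it does not certify performance on real recordings, whose
noise is spatially correlated, non-stationary, and contaminated by
artifact classes the generator does not emulate (saccades, muscle, drift).

## Known limitations

* No ICA/component artifact correction; no channel interpolation or
  bad-channel detection.
* The uniformity index is a faithful-direction stand-in, not the exact
  classical formula; absolute score values are not comparable across
  definitions.
* BrainVision support covers the float32 multiplexed profile the package
  itself writes; EDF is not implemented.
* The jackknife p-value's df convention and the LOP window are documented
  choices; sensitivity to both is easy to probe since they are arguments.
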