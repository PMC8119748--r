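# erpscene

Simulation and analysis of scene-complexity ERP experiments: an R package
for visual target-detection paradigms in which observers search natural
scenes (aerial image patches) for vehicles while 63-channel EEG is
recorded, under single-task (detection only) and dual-task (detection +
background observation) conditions and two background complexity levels.

The package covers the full chain such a study needs, each stage testable
in isolation:

* **Stimulus screening** — histogram entropy, gray-level uniformity
  (mean within-tile SD), HSI brightness, shoelace vehicle size; iterated
  1.5 x IQR outlier removal; balanced set construction and the oddball
  design arithmetic (600 target : 1,800 non-target testing trials, 3 x 200
  single-task and 5 x 120 dual-task blocks per session, 50 similarity
  questions per type per dual-task session).
* **EEG preprocessing** — zero-phase resampling to 250 Hz, 0.5–100 Hz
  band-pass + 50 Hz notch, average re-reference, [−200, 1000) ms epochs
  with [−200, 0) ms baseline, and joint-probability epoch rejection
  (6 SD per channel, 2 SD global).
* **ERP statistics** — per-bin cluster waveforms (occipital and
  centro-parietal clusters), pointwise two-sample t traces with
  Benjamini–Hochberg FDR control and significant-interval extraction, peak
  amplitude/latency measures (LOP window 250–450 ms, CPP 400–650 ms), the
  two-sample **jackknife peak-latency test**

  t = (L̂_A − L̂_B) / sqrt(σ̂²_A + σ̂²_B),  σ̂²_g = ((n_g−1)/n_g) Σᵢ (L_g,−i − L̄_g)²,

  where L_g,−i is the peak latency of the leave-one-out grand average, and
  high/low performer splits (k = 16 or 12).
* **Behavioral statistics** — per-condition RT / detection accuracy /
  similarity correction-rate summaries and two-sample comparisons.
* **Synthetic data** — a seeded generator for stimulus patches with
  controllable complexity, continuous EEG (Gaussian LOP/CPP kernels +
  1/f and white noise + blink artifacts) with a BIDS-like events table,
  and behavioral records; defaults encode the study conditions
  (CPP latency 520 ms simple vs 608 ms complex scenes, RT 0.599–1.267 s,
  similarity accuracy 85.5%, ISI 1.25–1.5 s).

## Worked example

```r
library(erpscene)

cfg <- synth_config(n_participants = 6, n_trials_per_bin = 8, seed = 42)
cp  <- cluster_spec("centro-parietal")

erps <- lapply(seq_len(cfg$n_participants), function(i) {
  ses <- generate_session(cfg, i)          # continuous EEG + events
  ep  <- preprocess_session(ses)           # filter, re-ref, epoch, reject
  bin_average(ep, cp, sprintf("P%02d", i)) # per-bin cluster waveforms
})

bins <- condition_bins()
A <- erp_stack(erps, bins$bin[bins$scene == "simple"])
B <- erp_stack(erps, bins$bin[bins$scene == "complex"])
jackknife_latency_test(A, B, attr(A, "time_ms"), component = "CPP")
```

```
<jackknife_result> CPP latency: 534.194 vs 610.454 (diff -76.2608), SE 6.57952
  t(10) = -11.591, two-tailed p = 4.046e-07
```

The grand-average CPP peaks near the configured 520 ms for simple and
608 ms for complex scenes (at n = 6 the between-participant latency
jitter still shows); the jackknife SE from leave-one-out subaverages puts
the ~76 ms scene effect far from chance. At the full study size
(48 participants) the recovered latencies fall within a few ms of the
configured values.

Behavioral side:

```r
cfg48 <- synth_config(seed = 42)   # full default study, 48 participants
rec <- do.call(rbind, lapply(1:48, function(i) generate_behavior_records(cfg48, i)))
summarize_behavior(rec)
compare_behavior(rec[rec$task == "single", ], "scene", "rt")
```

```
<behavior_summary> group means +/- SD across participants
  dual / complex: RT 1.392 +/- 0.473 s, Acc-VD 0.975 +/- 0.025, Acc-SJ 0.844 +/- 0.134
  single / complex: RT 0.863 +/- 0.204 s, Acc-VD 0.975 +/- 0.029
  dual / simple: RT 1.091 +/- 0.380 s, Acc-VD 0.995 +/- 0.013, Acc-SJ 0.879 +/- 0.107
  single / simple: RT 0.631 +/- 0.103 s, Acc-VD 0.994 +/- 0.014
<behavior_test> rt by scene: complex 0.863 +/- 0.204 vs simple 0.631 +/- 0.103
  t(94) = 7.053, two-tailed p = 2.927e-10
```

The table mirrors the condition structure the statistics expect: complex
scenes slow detection and lower its accuracy, the dual task slows it
further, and scene-similarity judgments sit far above the 50% chance
level.

An end-to-end run (stimuli → screening → design → sessions →
preprocessing → statistics, with a reproducibility manifest) is
`run_end_to_end(cfg, out_dir)`; a thin command-line front end lives in
`inst/scripts/erpscene.R`.

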