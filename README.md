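# mriecg

Tools for quantifying how the static magnetic field of an MRI scanner
distorts the 12-lead electrocardiogram, and for deciding what remains
clinically interpretable inside the bore.

## The problem

Blood flowing through a static field **B₀** — fastest in the aortic arch
during systole — induces a magnetohydrodynamic (MHD) voltage on surface ECG
electrodes. The induced voltage is proportional to field strength and
follows the aortic flow waveform, so it lands mostly on the **ST segment**
(J point to J + 80 ms), exactly where myocardial ischemia is read. A second
distortion source, motion of the lead wires in the field (dominated by
respiration), appears as beat-to-beat variability across the whole beat.
Quantifying both — error of the averaged beat versus a reference recorded
outside the scanner room, and per-sample standard deviation across beats —
tells you at which field strength and table position the J point, the P
wave, and the QRS complex stay readable.

`mriecg` implements the full measurement pipeline:

* **Synthetic 12-lead generator** (`synthetic_config()`,
  `generate_recording()`): sum-of-Gaussians beats on 8 independent leads
  (derived limb leads exact by construction), MHD distortion that is linear
  in field strength and time-locked to an aortic flow curve (flow peak
  114 ms after the J point, distortion peak 29 ms after peak flow),
  respiration-locked baseline wander and MHD amplitude modulation, PVCs,
  white noise, and injectable ischemic J-point deviations — with full
  ground truth.
* **Beat pipeline** (`bandpass_filter()`, `detect_qrs()`,
  `define_beat_window()`, `assign_templates()`, `align_and_average()`,
  `process_recording()`): 0.67–150 Hz zero-phase band-pass, manual-threshold
  QRS detection, normalised cross-correlation template classification
  (sinus vs PVC), and aligned averaging with per-sample SD.
* **Error metric** (`compute_error_report()`): vertical L1 alignment over
  P onset → first ⅓ of QRS, sign-aware 5% QRS-peak truncation, ±5 ms
  minimum-difference fine alignment; interval maxima for whole beat / PR /
  QRS / ST plus the J-point error, summarised per subject by the worst
  lead. `flow_distortion_timing()` registers a flow curve to the beat
  (first frame 10 ms before the QRS peak) and times the distortion peak.
* **Ischemia + statistics** (`st_deviation()`, `classify_ischemia()`,
  `pair_group_error()`, `bland_altman()`, `r_squared()`,
  `wilcoxon_rank_sum()`, `bonferroni_flags()`): TP-baseline-referenced
  J-point deviation, the ≥0.1 mV in ≥2 anatomically contiguous leads rule,
  lead-group error via pairwise minima, Bland–Altman agreement, and an
  exactly enumerated rank-sum test for small samples.
* **IO + study driver** (`read_recording()`, `read_marks()`,
  `run_study()`, `exec/mriecg`): delimited waveform/annotation formats,
  YAML study configs, and a CLI with `simulate`, `process`, `compare`,
  `ischemia`, `flow-timing`, `report` subcommands.

## Worked example

Simulate a subject outside the scanner room and at 0.55 T isocenter,
average both recordings, and compare:

```r
library(mriecg)

ref <- generate_recording(synthetic_config(seed = 101,
                                           location = "outside",
                                           field_t = 0))
iso <- generate_recording(synthetic_config(seed = 102,
                                           location = "isocenter",
                                           field_t = 0.55))
p_ref <- process_recording(ref$recording, ref$truth$marks_rel,
                           truth = ref$truth)
p_iso <- process_recording(iso$recording, iso$truth$marks_rel,
                           truth = iso$truth)

rep <- compute_error_report(p_iso$averaged, p_ref$averaged, p_ref$marks)
print(rep$summary, digits = 2)
#>   interval max_error max_error_lead max_sd max_sd_lead
#> 1    whole    0.1465              I 0.0197           I
#> 2       PR    0.0027             V6 0.0085         III
#> 3      QRS    0.0066              I 0.0082         III
#> 4       ST    0.0752              I 0.0109           I
#> 5        J    0.0020            III     NA        <NA>
```

Distortion concentrates on the ST segment of lead I (0.075 mV at 0.55 T
isocenter) while the PR and QRS intervals stay near-clean (< 0.01 mV) and
the J point itself is barely affected (0.002 mV) — the MHD pulse peaks well
after the J point:

```r
ft <- flow_distortion_timing(iso$truth$flow, p_iso$averaged,
                             p_ref$averaged, p_ref$marks)
round(ft, 1)
#>    flow_peak_after_j_ms dist_peak_after_flow_ms
#>                   106.7                    29.3
```

(True generator values 114 and 29 ms, recovered at the 33 ms flow-frame
resolution.) The ischemia rule on the isocenter beat:

```r
classify_ischemia(st_deviation(p_iso$averaged, p_iso$marks))$ischemic
#> [1] FALSE
```

A multi-subject, multi-condition study (error medians by field × location,
Wilcoxon/Bonferroni comparisons, ST-deviation agreement) is one call:
`run_study()` on a config like the one in `read_study_config()`'s help, or
from the shell:

```sh
Rscript exec/mriecg report --config study.yaml --out-dir reports/
```

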