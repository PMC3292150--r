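# semgfatigue

Muscle-fatigue **prediction and detection** from surface electromyography
(sEMG) recorded during isometric contraction — for biomedical signal
processing researchers and engineers prototyping wearable fatigue monitors.

During a sustained contraction the sEMG spectrum compresses (median
frequency ↓) while amplitude grows, and the limb kinematics deteriorate:
first small oscillations, then failure to hold the joint angle. This
package implements a full pipeline built around the intermediate
**Transition-to-Fatigue (TF)** state, whose detection is what turns fatigue
*detection* into fatigue *prediction*:

- **Fuzzy labeling** — a six-rule type-1 fuzzy classifier labels every
  second NF / TF / F from the elbow angle (boundaries 86.5° and 89°) and
  its 4-s-block oscillation SD (Low/High crossing at 0.6°), product
  inference, winner-take-all with severe-wins ties.
- **Features** — per 1-s window: instantaneous median frequency
  `IMDF = first f with cumulative periodogram power ≥ ½ total`, Welch total
  band power, Dimitrov's spectral index
  `FI_nsm^X = ∫f⁻¹PS(f)df / ∫f^X PS(f)df` over 8–500 Hz, a depth-12 db3
  wavelet approximation energy, and the headline composite

  `spectro_std(t) = rolling-SD₃[ z(power) − z(IMDF) ]`

  (the "1D spectro" stream is the standardized band-power minus standardized
  median frequency — it rises as fatigue develops; its causal 3-s rolling SD
  spikes at the TF onset).
- **Classification** — Fisher LDA (`W ∝ Sw⁻¹(μ₊−μ₋)`, midpoint bias, sign
  decision) per feature and class pair (NF/TF, TF/F), trained
  longitudinally: earlier seconds train, later seconds test.
- **Evaluation** — second-denominated confusion matrices with TP/FP/TN/FN/
  precision/accuracy rates, a spread-over-centroid-distance separability
  index (plus the textbook Davies–Bouldin index as `dbi_canonical`), and
  per-subject percent-correct comparison reports with improvement deltas
  and paired t-tests.
- **Synthetic trials** — a seeded generator of fatiguing-contraction trials
  (spectrally compressing band-limited sEMG + degrading goniometer trace)
  with ground-truth labels, so the whole pipeline is testable without the
  original recordings.

## Worked example

```r
library(semgfatigue)

gen <- generate_trial(synthetic_config(seed = 42))
gen$trial
#> <semg_trial> subject s1 trial t1 -- 360000 samples @ 2000 Hz ( 180 s )
gen$labels
#> <label_series> 180 windows of 1 s: 100/50/30 (NF/TF/F)

# label from kinematics alone and compare with ground truth
lab <- label_trial(gen$trial)
mean(as.character(lab$labels) == as.character(gen$labels$labels))
#> [1] 0.9888889

# the headline feature, and its mean per true phase
ss <- spectro_std(gen$trial)
ss
#> <feature_series> spectro_std -- 178 windows, range [ 0.06692 , 1.361 ]
ph <- as.character(gen$labels$labels)[match(round(ss$times), 0:179)]
tapply(ss$values, ph, mean)
#>         F        NF        TF
#> 0.5529750 0.4300344 0.5967168

# confusion rates, published-matrix example (a=16, b=1, c=8, d=11 seconds)
rates(confusion_matrix(16, 1, 8, 11))$tp
#> [1] 0.5789474
```

The labeler recovers 98.9% of the ground-truth seconds from kinematics
alone, and `spectro_std` is visibly elevated in the Transition-to-Fatigue
phase relative to Non-Fatigue (0.60 vs 0.43) — the spike behavior the
feature was designed around. The TP rate 11/19 ≈ 0.58 reproduces the
published confusion arithmetic.

End-to-end run (simulate → label → extract → classify → report), fully
reproducible per seed:

```r
cfg <- read_pipeline_config(system.file("extdata", "quickstart.yaml",
                                        package = "semgfatigue"))
run_pipeline(cfg, out_dir = "semg_run", seed = 1)
```

which writes trial/label/feature CSVs, `classification.csv`, `report.md`
(per-pair AVG/STDEV tables, confusion matrices in seconds, improvement
deltas) and a `manifest.json` provenance record. The same is available from
the shell via the installed `exec/semgfatigue` script:

```sh
semgfatigue run --config quickstart.yaml --out semg_run --seed 1
```

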