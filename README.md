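# pascl — Photoacoustic Spectral Analysis with Supervised Contrastive Classifiers

Multi-wavelength photoacoustic (PA) spectroscopy records, for each tissue
detection point, the acoustic power spectral density generated by pulsed
optical excitation at many wavelengths. Each point becomes a 77 × 90
matrix — 77 excitation wavelengths (690–950 nm and 1200–1690 nm, Δλ =
10 nm) by 90 acoustic frequency bins (1.0–9.9 MHz at 0.1 MHz) — whose
structure encodes absorber content and micro-heterogeneity, both of which
change in prostate cancer. `pascl` implements the full analysis chain for
classifying such matrices as normal vs tumour, for researchers studying
PA spectral classification protocols and the robustness of learned
features:

* **Synthetic cohorts** with class-dependent spectral slope and band
  offsets, a tumour frequency signature invisible to first-order fits,
  per-patient random effects, per-shot pulse-energy jitter, and
  per-system calibration gains — so every downstream stage is testable
  without clinical data (none are deposited).
* **Preprocessing**: Welch PSD (Hamming 2500, 90 % overlap, fs 250 MHz ⇒
  0.1 MHz resolution), band selection with transducer / pulse-energy
  calibration, and the classical linear-fit features per wavelength —
  slope *a* (dB/MHz), intercept *b* (dB) and median (the fitted value at
  the band's median frequency, 5.45 MHz): `S(f) ≈ a·f + b`.
* **Three classifier variants** sharing one small CNN encoder
  (77×90 → 64×77×90 → 64×38×45 → 4×38×45 → 4×12×15 → 256 → 2;
  188,038 parameters): plain cross-entropy (`cnn`), two-stage supervised
  contrastive learning with a 4-unit projector then a linear probe
  (`sc`), and a combined loss `SCL·ratio + CEL·(1 − ratio)`
  (`scl_adjust`). The supervised contrastive loss over a batch of
  embeddings `z_i` with labels `y_i` uses temperature-scaled cosine
  similarities (t = 0.5):

  `SCL = −Σ_i 1/(M_{y_i}−1) Σ_{j≠i, y_j=y_i} ln[ exp(s_ij/t) / (exp(s_ij/t) + Σ_{y_k≠y_i} exp(s_ik/t)) ]`

* **Protocols**: patient-grouped 7/2/3 splits (no volunteer in two
  partitions), seeded SGD (seed 42, 20 epochs), random hyperparameter
  search, the five-metric score (mean of accuracy, precision, recall,
  specificity, rank-AUC), 10×10 subsampled evaluation with Welch
  t-tests, silhouette of the 2-d head outputs, noise-injection
  robustness on clean-correct samples, and independent-per-system
  transfer decline `100·(score₁ − score₂)/score₁`.
* **Classical baselines**: Youden-threshold rules on slope/median at
  700 / 1210 / 1370 nm, shrinkage LDA / QDA, and validation-driven
  single-feature screening over all 6930 cells.

## Worked example

```r
library(pascl)

cohort <- generate_cohort(cohort_spec(seed = 1))          # two systems
sys1   <- subset_cohort(cohort, cohort$meta$system_id == 1)
splits <- split_cohort(sys1, seed = 2)                    # by patient

model <- train_model(build_model("scl_adjust", seed = 42),
                     splits$train, default_train_config("scl_adjust"))
ev <- evaluate_model(model, splits$test)
round(unlist(ev$metrics[c("accuracy", "precision", "recall",
                          "specificity", "auc", "score")]), 3)
#>    accuracy   precision      recall specificity         auc       score
#>           1           1           1           1           1           1

rob <- robustness_eval(model, splits$test,
                       noise_spec("uniform", 0.4, replicates = 10, seed = 3))
round(c(noise_accuracy = rob$accuracy, silhouette = rob$silhouette), 3)
#> noise_accuracy     silhouette
#>          0.336         -0.140
```

The clean five-metric score on this small held-out set saturates at 1 —
synthetic cohorts at desk scale are separable for the deep models; the
interesting contrasts appear under noise (above: a uniform perturbation
at 40 % of the sample's peak amplitude destroys two thirds of the
clean-correct predictions and scatters the embedding, silhouette
−0.14) and under cross-system transfer. A full
experiment — simulate, split, train all variants, evaluate, robustness
sweep, baselines, transfer — is one call:

```r
run_pipeline("experiment_dir", seed = 42)
```

and writes `metrics.csv`, `robustness.csv`, `baselines.csv`,
`transfer.csv`, `history.csv`, `report.json` plus the dataset and split
metadata needed to reproduce it byte-for-byte.

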