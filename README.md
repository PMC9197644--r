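# ielm — imbalance-aware ELM ensembles for EEG stress classification

Psychophysiological stress levels estimated from EEG are intrinsically
imbalanced: most subjects sit in a tolerable "moderate" band, and the
clinically interesting "high stress" group is a small minority (on the
order of 12% of segments). Ordinary classifiers trained for overall
accuracy quietly sacrifice exactly that minority class. This package
implements, end to end and on synthetic data, a pipeline for three-class
stress assessment from single-channel EEG that is built around the
minority class:

1. **Signal layer** — segment I/O in plain delimited text, detrend /
   clip preprocessing, and zero-phase decomposition into the five rhythm
   bands δ (0.5–4 Hz), θ (4–7), α (8–15), β (16–31), γ (32–45).
2. **Features** — four nonlinear descriptors per band: rescaled-range
   Hurst exponent, fluctuation index (mean |Δx|), sample entropy
   (m = 2, r = 0.2·SD) and permutation entropy (order 3), giving a 20-dim
   vector per segment.
3. **Fusion** — accuracy-proportional feature weighting per band,
   `w_i = f_i / (f_1 + f_2 + f_3 + f_4)`,
   where `f_i` is the single-feature classification accuracy.
4. **Classifiers** — extreme learning machines (random sigmoid hidden
   layer, ridge-solved output weights
   `β = (I/γ + HᵀWH)⁻¹ HᵀW Tᵀ`), label-weighted targets that inflate the
   minority positive target by the class ratio `n_major / n_c` (or its
   square), classic AdaBoost, and the **IELM** ensemble: boosting whose
   weight distribution is an n × q matrix over one-hot labels,
   initialised from per-label imbalance ratios `R_j = max(S⁺,S⁻)/min(S⁺,S⁻)`
   (minority side raised by √R_j) and updated per (label, class) block,
   each block holding fixed mass 1/(2q). Block coefficients are
   `ς = ½·ln(correct mass / wrong mass)`.
5. **Evaluation** — accuracy, per-class recall, macro recall, confusion
   matrices, and relative-improvement arithmetic.
6. **Synthetic generator** — seeded EEG segments (band-limited noise
   with class-dependent β/γ amplitudes plus fractional Gaussian noise
   with class-dependent Hurst exponents, via exact circulant embedding)
   and Gaussian feature-space fixtures with the 12/46/42% stress mix, so
   everything above is testable without recorded data.

## Worked example

```r
library(ielm)

cfg  <- synthetic_config(n_segments = 120, duration_s = 4, seed = 42)
segs <- generate_segments(cfg)          # labelled synthetic EEG
tab  <- extract_feature_table(segs)     # 120 x (3 meta + 20 features)

tr   <- stratified_split(tab$label, 0.7, seed = 42, subjects = tab$subject_id)
feat <- setdiff(names(tab), c("segment_id", "subject_id", "label"))
sc   <- minmax_scale(tab[tr, feat], tab[!tr, feat])

fit  <- train_ielm(sc[[1]], tab$label[tr], rounds = 10, L = 100, seed = 42)
evaluate_classification(predict(fit, sc[[2]])$class, tab$label[!tr])
#> <eval_report> n = 36  accuracy = 1.0000  macro recall = 1.0000
#> per-class recall:
#>     high      low moderate
#>        1        1        1

base <- lw_elm(sc[[1]], tab$label[tr], L = 100, seed = 43, scheme = NULL)
evaluate_classification(predict(base, sc[[2]])$class, tab$label[!tr])
#> <eval_report> n = 36  accuracy = 0.8611  macro recall = 0.8381
#> per-class recall:
#>     high      low moderate
#>   0.7143   1.0000   0.8000
```

On the same held-out segments the plain ELM recovers only 71% of the
high-stress minority while the boosted, label-weighted ensemble recovers
all of it — the imbalance pathology and its repair in one run.

The accuracy-weighted fusion step, from the shipped per-band
single-feature accuracy table:

```r
acc <- read_weight_table(system.file("extdata",
        "ielm_band_feature_accuracy.csv", package = "ielm"))
attr(weight_table_from_accuracy_table(acc), "rounded")
#>         alpha   beta  gamma  delta  theta
#> hurst  0.2556 0.2582 0.2927 0.2281 0.2653
#> fluct  0.2673 0.3007 0.2913 0.2808 0.3084
#> sampen 0.2363 0.2212 0.1965 0.2250 0.2033
#> permen 0.2408 0.2198 0.2195 0.2661 0.2230
```

## Command line

A thin wrapper over the same functions is installed as `exec/ielm`:

```sh
Rscript exec/ielm e2e --out run1 --seed 7 --n 60 --rounds 5
Rscript exec/ielm weights --acc inst/extdata/ielm_band_feature_accuracy.csv --out weights.csv
```

Subcommands: `simulate`, `extract`, `weights`, `train`, `evaluate`,
`e2e`. All randomness in a run flows from `--seed`.

## Limitations

The synthetic generator reproduces the statistical structure the
features consume (band power, long-range dependence, class imbalance),
not physiological EEG; see the methods vignette
(`vignettes/ielm-methods.Rmd`) for the model, parameter defaults and
design decisions.
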