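# lpica — Linear Poisson ICA for MALDI-ToF mass spectra

MALDI-ToF spectra of biological samples are noisy, variable, and — because
peak heights count discrete ion events — better described by Poisson than
by Gaussian noise. `lpica` quantifies **binary biological mixtures** (e.g.
two milks, or brain and liver lipid extracts) from such spectra by fitting
a **Linear Poisson Model**: each binned spectrum is a non-negative
weighted sum of probability-mass-function components,

    m_i = Σ_k Q_k · P(i|k),     h_i ~ Poisson(m_i),

estimated by EM — a Poisson-compatible form of independent component
analysis (LP-ICA). On top of the decomposition the package provides:

* **preprocessing** — alignment, baseline correction, significant-peak
  binning, spectrum filtering (`align_spectrum`, `baseline_correct`,
  `detect_peak_bins`, `integrate_peaks`, `filter_spectra`);
* **MAX SEP** — maximal pairwise subtraction that reduces the linear
  degeneracy of the components so they map onto physical sub-spectra
  (`max_sep`, `simplicity_report`);
* **quantification** — component-to-class assignment, efficiency-weight
  calibration against ground-truth proportions, per-spectrum proportion
  predictions with errors propagated through the observed Fisher
  information, and multi-restart ensembles (`assign_components`,
  `calibrate`, `predict_proportion`, `ensemble_predict`);
* **noise validation** — Bland–Altman scatter of residuals versus
  expected intensity with a power-law fit `Var(x) = a·x^b` (`b = 1` is
  the Poisson signature, `a` the gain), and pull distributions that check
  predicted errors against truth (`bland_altman_points`, `fit_power_law`,
  `pull_statistics`);
* **a single-peak benchmark** — peak-ratio calibration, the conventional
  baseline LP-ICA is compared against (`compute_ratios`,
  `rank_and_calibrate`);
* **a synthetic-spectrum generator** emulating the binary dilution-series
  design (11 proportions × 8 replicates) so every stage is testable
  without instrument data (`make_class_pmfs`, `generate_corpus`,
  `add_profile_artifacts`).

See `vignettes/lpica-methods.Rmd` for the model, the numerical choices
and their rationale.

## Worked example

```r
library(lpica)

pmfs <- make_class_pmfs(seed = 1)               # two classes + contaminant
sim  <- generate_corpus(pmfs, seed = 2)          # 88 spectra, 11 x 8 design

model <- train_restarts(sim$corpus, K = 3, restarts = 10, seed = 3)$best
model <- max_sep_model(model, sim$corpus)        # separate + refit
refit <- fit_corpus(sim$corpus, model)
model
#> lpm_model: K = 3 components over 60 bins, chi2/dof = 0.941 (seed 10)

assignment <- assign_components(refit$fits, sim$truth)
cal <- calibrate(refit$fits, sim$truth, assignment)
cal
#> class_calibration: 2 A / 1 B / 0 rejected; slope 1.000, intercept -0.001, precision 0.0054
efficiency_ratio(cal)                            # generator used e_B = 0.5
#> [1] 1.99

pred <- predict_proportions(refit$fits, cal, corpus_ids(sim$corpus))
pull_statistics(pred$unclipped, sim$truth$fraction_A, pred$predicted_error)
#> pull_stats: mean -0.001, std 0.860 (n = 88)

fit_power_law(bland_altman_points(sim$corpus, model, refit$fits))
#> power_law_fit: Var(x) = a * x^b with a = 1.03 +/- 0.066, b = 0.977 +/- 0.013
```

Reading the numbers: `chi2/dof ≈ 1` says the Poisson model fits at gain 1;
the calibration recovers the generator's factor-2 class-B efficiency
deficit (`w_B/w_A ≈ 2`) and predicts mixture proportions to ±0.5% on this
corpus; the pull width ≈ 0.86 says the propagated per-spectrum errors
slightly over-cover the observed deviations; and the Bland–Altman
exponent `b ≈ 1` confirms residuals growing with the square root of the
signal — the Poisson signature that motivates the model. For comparison,
the best single-peak calibration on the same corpus
(`rank_and_calibrate(compute_ratios(sim$corpus), ...)`) reaches a
precision of only ±17%.

The full workflow — order selection by the χ²/dof plateau, separation,
calibration, prediction, validation, benchmark — is one call:
`run_pipeline(pipeline_config(seed = 1, out_dir = "report"))`.

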