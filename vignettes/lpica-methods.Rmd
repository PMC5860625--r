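---
title: "Linear Poisson ICA for MALDI-ToF mixture quantification: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linear Poisson ICA for MALDI-ToF mixture quantification: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lpica)
```

# The model

A preprocessed MALDI-ToF spectrum is a histogram of ion counts over
retained peak bins.  `lpica` models each histogram as a non-negative
weighted sum of probability mass functions (PMFs),

$$ m_i \;=\; \sum_{k=1}^{K} Q_k \, P(i \mid k), \qquad
   Q_k \ge 0,\; \sum_i P(i \mid k) = 1 , $$

with each bin count $h_i$ an independent Poisson draw around $m_i$.  Each
component $P(\cdot \mid k)$ is one *sub-spectrum*: a correlated set of
peaks that rises and falls together (a tissue class's lipid signature, an
ionisation mode, a contaminant).  Unlike PCA/ICA on unit vectors, the
mixture-of-PMFs form permits only non-negative coefficients — appropriate
for counting data — and carries a predictive error theory.

Parameters are maximum-likelihood estimates of the Poisson log-likelihood
$\ell = \sum_i [\, h_i \log m_i - m_i \,]$ obtained by
expectation-maximisation.  With components fixed (`fit_weights()`), the
update

$$ Q_k \leftarrow Q_k \sum_i P(i\mid k)\, h_i / m_i $$

never decreases $\ell$ and conserves $\sum_i m_i = \sum_k Q_k$ exactly.
Training (`train_components()`) alternates this step with the constrained
M-step for the shared components,
$P(i \mid k) \propto \sum_s h_{si}\, r_{sik}$ with responsibilities
$r_{sik} = Q_{sk} P(i\mid k)/m_{si}$, renormalised to sum 1 — the
canonical EM for a mixture of multinomials driven by Poisson totals, and a
Poisson-compatible form of independent component analysis.  Tests assert
the monotonicity of the recorded likelihood trace on every run, and that
two-component fits coincide with an exhaustive likelihood grid search on
small problems.

## Numerical choices

* **Convergence** — relative log-likelihood change below `tol` (default
  `1e-8` for training, `1e-10` for weight fits) or 10,000 iterations.
* **Probability floor and hard zeros** — during EM, component
  probabilities are floored at $10^{-12}$ on the corpus support to avoid
  $-\infty$ likelihoods; after convergence, probabilities below $10^{-7}$
  are snapped to exact zeros and the PMF renormalised.  The threshold must
  clear the floor even after MAX SEP renormalisations inflate it; exact
  zeros matter both for the simple-structure criteria and so that
  empty-model bins are excluded from the Bland–Altman scatter rather than
  appearing as meaningless $\sim 10^{-4}$-event expectations.
* **Boundary weights** — multiplicative updates approach a zero-weight
  optimum only asymptotically.  After convergence a small weight
  ($<10^{-3}$ of the total) is moved to exactly zero when the likelihood
  gradient at the boundary is non-positive, i.e. when zero genuinely is
  the constrained optimum.
* **Degenerate inputs** — an all-zero histogram fits to all-zero weights;
  a component that is zero everywhere is an error; ties in the assignment
  search resolve to the first (smallest-index) labelling.

## Model order

The number of components is selected by scanning `K` over a range
(`select_model_order()`), training the best of several seeded restarts at
each order, and examining the goodness-of-fit

$$ \chi^2/\mathrm{dof} = \frac{\sum_{s,i} (h_{si}-m_{si})^2 /
   \max(m_{si}, \epsilon)}{SI - K(I-1) - KS} , $$

whose numerator is the Pearson statistic over all spectra and bins and
whose denominator subtracts the shared PMF parameters and the
per-spectrum weights.  For pure Poisson counts recorded at gain $g$
(intensity units per ion event) this statistic converges to
$\approx g$.  The selected order is the first at which the curve has
reached a minimum or flattened: the relative improvement to the next
order falls below `plateau_tol` (default 0.05).  We deliberately use the
*successive-improvement* form rather than "within tolerance of the best
value in the range": χ²/dof keeps creeping downward by roughly
$(I+S)/(SI)$ per extra order through noise absorption, so a best-value
anchor drifts with the scanned range, while the flattening criterion is
stable and matches the intended "minimum or plateau" reading.

# MAX SEP

Likelihood only pins down the fitted hyperplane; the components spanning
it are linearly degenerate.  `max_sep()` reduces the degeneracy by
repeatedly subtracting from each component the maximum amount of every
other that keeps all probabilities non-negative
($\alpha = \min_{i:\,P(i|k)>0} P(i\mid j)/P(i\mid k)$), renormalising
after each subtraction.  Each output is a non-negative combination of the
inputs and vice versa, so refitting weights after separation reproduces
the corpus likelihood (asserted to $10^{-6}$ relative); the zero-bin count
never decreases, moving the set towards the factor-analysis
"simple structure" criteria reported by `simplicity_report()`.  Sweeps
run in descending order of total fitted weight (dominant structure
first); a subtraction that would leave less than 5% of a component's mass
is vetoed so near-duplicates are not annihilated.  Separation is applied
once, after training converges and before calibration, with weights then
refitted — interleaving with EM is possible in principle but the post-hoc
placement keeps training monotone and was adopted as the default.

# Mapping components to classes and calibration

For a binary mixture (class A mass fraction $p$), components are first
screened by the correlation of their fractional weight with the known
proportions: $|r| < 0.2$ (configurable) marks a component as
contamination/ambiguity and rejects it.  The remaining components are
labelled A or B (or rejected) by exhaustive search over labellings,
minimising the calibrated residual; because an A↔B swap is absorbed by a
negative affine slope, only labellings with positive slope are accepted,
which orients the labels.  Beyond 729 labellings the search falls back to
the sign of the correlation.

Calibration (`calibrate()`) then estimates one positive efficiency weight
$w_k$ per retained component (log-parameterised, first fixed at 1,
BFGS from 10 seeded starts) together with a closed-form affine map, so
that

$$ \hat p = \mathrm{slope}\cdot
   \frac{\sum_{k\in A} w_k Q_k}{\sum_{k \in A \cup B} w_k Q_k}
   + \mathrm{intercept} $$

matches ground truth in least squares.  The efficiencies absorb the
different detection efficiencies with which each class's molecules
contribute to the recorded signal; on the synthetic design with class B
generated at half the detection efficiency of class A, the recovered
ratio $w_B/w_A$ is 2.  `precision` is the standard deviation of the
calibrated residuals, in proportion units.  Predictions are clipped to
$[0,1]$ at prediction time only; calibration and pull statistics use the
unclipped values to avoid boundary bias.

# Error theory

The covariance of the fitted weights is the inverse observed Fisher
information of the Poisson likelihood at the solution,
$J_{kl} = \sum_i h_i P(i|k) P(i|l) / m_i^2$, inflated by the corpus
χ²/dof when that exceeds 1 (residual unmodelled structure) and never
deflated below the Poisson floor.  A singular information matrix falls
back to a flagged Moore–Penrose pseudo-inverse.  The per-spectrum
proportion error follows by first-order propagation through the weighted
ratio and affine map.  Tests check the information matrix against a
finite-difference Hessian (1%), the single-component closed form
$\mathrm{Var}(Q)=N$, and the $\sqrt{c}$ scaling of errors under count
scaling.

Two empirical validations close the loop:

* **Pull distributions** — $(\hat p - p)/\hat\sigma$ over a corpus with
  known truth should have mean 0 and standard deviation 1 (sample, n−1
  convention) when estimates are unbiased and errors correctly predicted.
* **Bland–Altman power law** — residuals $(h_i - m_i)$ against expected
  intensity, pooled over spectra and bins, binned into 20 equal-count
  quantile bands; regressing log band variance on log band centre fits
  $\mathrm{Var}(x) = a\,x^b$.  $b = 1$ is the Poisson signature (residual
  spread growing as the square root of the signal) with $a$ the gain;
  $b = 0$ with $a = \sigma^2$ is the iid-Gaussian alternative.  The scale
  $a$ is reported with the caveat that its log-intercept extrapolates
  well below the band centres and so carries a much larger relative
  uncertainty than $b$.

# The synthetic generator

No public spectra accompany the study design this package targets, so
`make_class_pmfs()` / `generate_corpus()` emulate it: two class PMFs
sharing 30% of their peak positions with independent intensities, a
fixed 8-peak contamination PMF taking 5% of events, class-B detection
efficiency 0.5 relative to A, 11 proportions from 0 to 1 in 0.1 steps
with 8 replicate depositions each (88 spectra), per-spectrum totals
uniform in 2,000–20,000 events, and counts recorded as gain × Poisson
draws.  Defaults of 60 bins with 35 peaks per class were chosen so that —
as after gap-removal preprocessing of real spectra — essentially every
retained bin carries signal in at least one class; per-spectrum totals
put per-peak counts in the range typical of integrated MALDI lipid peaks
while keeping full analyses in seconds.  `add_profile_artifacts()`
renders histograms back to profile spectra with Gaussian peak shapes, a
smooth baseline, zero-mean Gaussian background noise and a global m/z
jitter, exercising the preprocessing stage end to end.

The generator reproduces the *statistical* structure the method assumes —
linear additivity, independent Poisson bins, gain scaling, constant
contamination — but not suppression effects, isotope envelopes, adduct
series, correlated peak-shape changes, or imperfect alignment residue.
Passing tests therefore demonstrate the estimator's correctness and
calibration under its stated assumptions, not performance on any
particular instrument's data.

# Preprocessing

Raw profile spectra pass through: cross-correlation alignment over
integer axis steps with parabolic sub-step refinement
(`align_spectrum()`); baseline subtraction by an iteratively refined
running median in which peak regions (2 robust σ above the current
estimate, dilated) are bridged by interpolation before re-estimation
(`baseline_correct()` — background noise stays zero-mean, negative
residuals are retained); significant-peak binning at 5× the robust noise
of the corpus-mean spectrum with a 3-sample minimum run width and
half-open `[low, high)` bins (`detect_peak_bins()`); per-bin integration
divided by the gain (`integrate_peaks()`); and total-signal filtering of
low-signal and saturated spectra (`filter_spectra()`).  The milk-lipid
analysis window of 650–850 Da is the shipped example configuration.  The
exact alignment/baseline operators used on the original instrument data
are not restated in the source study; the implementations here are
standard, testable stand-ins and the retained-peak counts of the original
analyses are not expected to be reproduced.

# Problem sizes and runtime

All shipped analyses run on one CPU in seconds: the default corpus is
88 spectra × 60 bins; order scans cover K = 1–5 with 3–10 restarts;
ensembles default to 50 restarts (`train_restarts()`), matching the
multiple-model spread assessment the method prescribes, though the test
suite uses 10 to stay fast.  The acceptance script regenerates the gain-5
corpus, fits at the generating order K = 3, and reports the Bland–Altman
exponent from 20 quantile bands.

# Known limitations

* Binary mixtures only; no multi-class or absolute quantitation.
* The additive Gaussian background is handled in preprocessing, not
  inside the likelihood; heavy unremoved baseline will inflate χ²/dof
  and widen (correctly) the scaled error bars.
* In-sample calibration precision is optimistic; `rank_and_calibrate()`
  offers leave-one-out scoring for the peak-ratio benchmark, and the same
  caveat applies to the LP-ICA precision.
* The A/B orientation of labels requires ground truth spanning a range of
  proportions; calibration is unidentifiable from a single proportion.
* `χ²/dof`-scaled covariances treat all unmodelled structure as
  noise-like; strongly systematic misfit (wrong K) biases predictions in
  ways the pull width only partially reflects.
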