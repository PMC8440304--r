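# stenoscreen

In-silico screening for arterial stenosis from pulse-wave measurements.

Peripheral artery disease — a stenosis (narrowing) of a large artery,
most often from atherosclerosis — is usually diagnosed by imaging, which
is too expensive for large-scale screening.  Because a narrowed vessel
changes the pressure and flow-rate waveforms passing through it, cheap
peripheral pressure/flow measurements may carry a detectable biomarker of
disease.  `stenoscreen` implements a proof-of-concept pipeline testing
that idea on the aorto-iliac bifurcation (abdominal aorta splitting into
the two common iliacs):

1. **Physics** — a one-dimensional pulse-wave propagation model per
   vessel,

   ```
   A_t + (AU)_x = 0
   U_t + U U_x + P_x / rho = f / (rho A),   f = -2 (zeta + 2) mu pi U
   P   = P_ext + P_d + beta (sqrt(A) - sqrt(A_d)) / A_d,
   beta = (4/3) E h sqrt(pi)
   ```

   solved to a periodic state with a Fourier-series inlet flow and
   three-element Windkessel (R1–C–R2) outflow models at the iliac
   outlets.  Stenoses are imposed as a cosine narrowing of the diastolic
   area profile with severity `S ∈ [0.5, 0.9]` and normalised extent
   `[b, e]`.
2. **Virtual patient database (VPD)** — 25 network parameters (geometry,
   wall stiffness, Windkessel triplets, 11 inlet Fourier coefficients)
   sampled independently, Normal with SD 20% of the mean; an expected
   50% of patients receive one stenosis (equally likely in each vessel);
   simulated patients with non-physiological inlet pressures are removed
   by hard filters (max < 225 mmHg, min > 25 mmHg, pulse < 120 mmHg).
3. **Machine learning** — waveforms at the inlet and the two outlets
   (P1, Q1, P2, Q2, P3, Q3) are reduced to 11 Fourier coefficients each,
   Z-scored on training data, and fed to cost-weighted logistic
   regression (the weighted cross-entropy
   `L = -(1/m) Σ [w τ log h + (1-τ) log(1-h)]`, with `w` solving
   `r = w m1/m2`), SVM, Gaussian naive Bayes and random forest —
   as entire-network or individual-vessel binary classifiers, and as
   one-vs-all / one-vs-one / custom-probabilistic (CPC) multiclass
   ensembles.  The CPC defaults every patient to "no disease" unless a
   vessel's predicted disease probability reaches a decision boundary B.
4. **Evaluation** — sensitivity/specificity and the F score
   `F = (δ²+1) P R / (δ² P + R)`, events-per-variable cohort sizing,
   five-fold (random 2/3–1/3 split) validation, searches over all 63
   measurement combinations, like-for-like symmetry audits, learning
   curves, severity analysis and ROC/AUC.

## Worked example

Build a small solver-backed cohort and score an entire-network RBF-SVM
classifier with five-fold validation:

```r
library(stenoscreen)
set.seed(7)
vpd <- build_vpd(targets = c(healthy = 60, aorta = 20,
                             iliac_1 = 20, iliac_2 = 20))
vpd
#> <vpd> 120 patients (healthy=60, aorta=20, iliac_1=20, iliac_2=20); acceptance rate 0.87

feats <- features_from_vpd(vpd)
res <- five_fold(feats, vpd_labels(vpd),
                 rule = list(type = "enbc"), method = "svm_rbf")
round(res$mean, 3)
#>           f sensitivity specificity     train_f
#>       0.581       0.581       0.597       0.910
```

120 patients were accepted (87% of simulated candidates passed the
physiological pressure filters).  The five-fold mean sensitivity is the
fraction of diseased patients detected (0.581), the specificity the
fraction of healthy patients recognised as healthy (0.597), and `f` the
healthy-class F score; `Se + Sp > 1` means the classifier beats naive
guessing even on this very small cohort.  The full-size study cohort
follows the events-per-variable rule:

```r
sz <- epv_requirements()   # 12 events/variable, 66 dims, 2/3 training
c(sz$diseased_per_vessel, sz$healthy, sz$healthy_epv)
#> 1188 3564   36
```

End-to-end orchestration (`generate_vpd_files()`, `run_experiment()`)
reads a YAML configuration and writes CSV/JSON outputs stamped with a
seed and configuration hash; see the methods vignette
(`vignettes/stenoscreen-methods.Rmd`) for the model assumptions, the
parameter tables and the design decisions.

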