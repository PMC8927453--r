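# burnmech

Tissue biomechanics asks a deceptively simple question when an animal model
stands in for human tissue: are the two materials mechanically the same?
`burnmech` implements a complete, reproducible pipeline for answering it from
uniaxial tensile tests, built around the comparison of full-thickness burned
human and porcine skin. It takes raw force–displacement records, extracts
five mechanical properties per specimen, and quantifies the difference
between two tissue populations with univariate hypothesis tests, effect
sizes, power analysis and cross-validated classification.

The package ships a seeded synthetic tensile-test generator with the same
statistical structure (two tissues × three loading rates, J-shaped curves
with a rupture point, right-skewed property distributions, multiplicative
load-cell noise), so every stage is testable end to end without access to
specimen data.

## The model and the five properties

Each specimen's record is converted to nominal measures using the
undeformed geometry: stress σ_N = F/A₀ (MPa) and strain ε_N = ΔL/L₀. From
the curve we take:

* **ultimate tensile stress** — the peak nominal stress (rupture point);
* **ultimate tensile strain** — the strain at that peak;
* **toughness** — the area under the stress–strain curve up to the peak
  (MJ/m³, energy absorbed per unit volume);
* **μ and γ** — the two coefficients of the Veronda–Westmann hyperelastic
  law fitted to the pre-peak curve.

The Veronda–Westmann strain energy, an exponential-in-Ī₁ law that
reproduces the J-shaped toe of soft tissue, is

Ψ(Ī₁, Ī₂) = (μ/γ)(e^{γ(Ī₁−3)} − 1) − μ(Ī₂ − 3),

and under incompressible uniaxial tension (λ = 1 + ε_N,
Ī₁ = λ² + 2/λ) the nominal stress is

σ_NU = 2μ(1 − λ⁻³)(λ e^{γ(Ī₁−3)} − 1).

`vw_fit()` estimates (μ, γ) by nonlinear least squares: μ enters the stress
linearly, so it is profiled out in closed form on a γ log-grid and the best
candidate is polished with a Levenberg–Marquardt iteration on
(log μ, log γ). The fit is deterministic and recovers noiseless parameters
to better than 10⁻⁶ relative error.

Downstream, `compare_properties()` runs a normality-guided decision tree
(Shapiro–Wilk → F-test → pooled/Welch t-test, or Kolmogorov–Smirnov on
median-centered samples → Wilcoxon/Welch) for every property × rate at
α = 0.01, `required_sample_sizes()` does exact noncentral-t power analysis,
and `loocv_classify()` classifies tissue type with leave-one-out
cross-validated ridge-stabilized logistic regression, reporting accuracy,
sensitivity, specificity, F1, ROC-AUC, MCC, FMI and ARI plus per-feature
contribution shares.

## Worked example

```r
library(burnmech)

report <- run_pipeline(pipeline_config(seed = 1))
print(report)
#> Study report: 404 specimens (17 removed as outliers), alpha = 0.01
#> Univariate: 15/15 comparisons reject; pooled Cohen's d = 1.58
#> Required group sizes at d = 1.58: 15 / 36 (gpower convention)
#> Classification (LOOCV logistic regression):
#> # A tibble: 4 x 13
#>   task_label    tp    fp    fn    tn accuracy sensitivity specificity    f1
#>   <chr>      <int> <int> <int> <int>    <dbl>       <dbl>       <dbl> <dbl>
#> 1 0.3           89     0     0    35    1           1           1     1
#> 2 2             86     1     2    37    0.976       0.977       0.974 0.983
#> 3 8             95     2     4    36    0.956       0.960       0.947 0.969
#> 4 combined     270     4     6   107    0.974       0.978       0.964 0.982
```

The default configuration simulates 404 specimens (95/92/102 of one tissue
and 38/39/38 of the other across 0.3, 2.0 and 8.0 mm/s). Seventeen
specimens fall outside the 3×IQR extreme-outlier fences and are removed.
All 15 univariate comparisons reject equality at α = 0.01, the mean Cohen's
d across them is 1.58, and LOOCV logistic regression separates the tissues
with ≥ 95% accuracy per rate and combined — the qualitative picture the
pipeline is designed to quantify.

Single-specimen workflow:

```r
rec <- generate_curve(mu = 0.05, gamma = 8, rupture_strain = 0.5,
                      L0 = 7.6, A0 = 6.2, noise_sd_rel = 0.02, seed = 42)
fit <- vw_fit(to_stress_strain(rec, L0 = 7.6, A0 = 6.2))
print(fit)
#> Veronda-Westmann fit
#>   mu     = 0.04835 MPa
#>   gamma  = 8.0669
#>   R^2    = 0.999591 over 200 points
```

With 2% force noise the true (0.05, 8) is recovered within a few percent
and R² stays above 0.99. `tidy()`, `glance()` and `augment()` methods are
provided for fits, test results and classification reports;
`autoplot()`, `plot_stress_strain()` and `plot_property_boxes()` give
ggplot2 graphics.

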