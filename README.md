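# sobologit

Scalar-on-image logistic regression with combined L1 and Sobolev
regularization.

## What problem this solves

In medical imaging, handwritten-character recognition and similar
settings, the covariate of a binary classifier is an entire image and
the regression coefficient is itself an image: one log-odds weight per
pixel.  Plain maximum likelihood fails in this high-dimensional regime,
and generic sparse penalties (lasso, elastic net) ignore what makes
image coefficients special — most pixels are irrelevant, and the
relevant ones form spatially smooth regions with edges.

`sobologit` fits the no-intercept logistic model
log P(Y=+1|X)/P(Y=−1|X) = ⟨X, B⟩ for labels Y ∈ {−1, +1} by minimizing

    Q(β) = (1/n) Σᵢ log(1 + exp(−Yᵢ βᵀXᵢ))  +  λ₁ βᵀDᵀDβ  +  λ₂ ‖β‖₁

where β = vec(B) and D is the sparse signed-difference matrix of
4-adjacent pixels, so βᵀDᵀDβ is the squared discrete Sobolev norm
‖∇B‖₂² and DᵀD is the grid-graph Laplacian.  The L1 term selects
pixels; the Sobolev term makes neighbouring pixels share effects,
preserving shape information.  The optimizer is cyclic coordinate
descent with soft-thresholded Newton-style updates (compiled inner
loop), with a KKT subgradient certificate at exit.

The package provides, as both R functions and a thin command-line
wrapper (`inst/cli/sobologit.R` with subcommands `simulate`, `fit`,
`tune`, `cv`, `predict`, `evaluate`, `study`):

* `build_difference_operator()`, `sobolev_norm()` — the penalty operator;
* `fit_sobologit()`, `kkt_residual()` — the solver;
* `lambda_max()`, `default_grid()`, `select_by_validation()`,
  `cross_validate()` — the tuning-parameter machinery (λ₀ threshold,
  (α, λ) grids, validation-set and M-fold CV selection);
* `make_example_dataset()`, `sample_ar_design()`, `sample_haar_design()`
  — synthetic-data generators for AR-correlated Gaussian and
  Haar-wavelet image designs with binary-shape or smooth truth images;
* `run_simulation_study()`, `prediction_error()`, `estimation_error()`
  — the replicated study harness comparing the Sobolev+L1 fit
  (`lg_sob`) against pure-L1 logistic regression (`lg_l1`);
* `read_usps_digits()` — an optional loader for the classic
  label-plus-256-pixels handwritten-digit text format (no download is
  performed).

## Worked example

Simulate a 16×16 study condition (AR-correlated Gaussian images, a
binary disk as the true coefficient image, logistic labels), tune on a
validation set, and score on a test set:

```r
library(sobologit)

cfg <- simulation_config(shape = c(16, 16), n_train = 300,
                         n_validation = 300, n_test = 300,
                         design = "ar", coefficient_kind = "binary_shape",
                         seed = 42)
sim <- make_example_dataset(cfg)

sel <- select_by_validation(sim$train, sim$validation,
                            reduced_grid(sim$train),
                            solver_config(tol_objective = 1e-9,
                                          tol_kkt = 1e-4))
sel
#> <tuning_result> (validation) best alpha = 0.2, best lambda = 0.0495535, PE = 0.1
sel$fit
#> <sobologit_fit> 16 x 16 coefficient image
#>   lambda1 = 0.0396428, lambda2 = 0.0099107
#>   sweeps = 12, objective = 0.3501108, active set = 157 / 256
#>   converged = TRUE (KKT residual 1.6e-06)

prediction_error(sel$fit$beta_hat, sim$test)
#> [1] 0.08666667
estimation_error(sel$fit$B_hat, sim$B0)
#> [1] 34.75823
```

The selected mixing proportion α = 0.2 puts 80% of the penalty on the
Sobolev term — the validation set recognizes that the true coefficient
image is spatially coherent.  The tuned model misclassifies 8.7% of
test images; `estimation_error` is the squared Frobenius distance
between the estimated and true coefficient images.  `sel$fit$B_hat` is
the 16×16 estimated image, ready for `image()` or export via
`write_coefficient_image()`.

To see why the Sobolev term earns its keep, run the replicated study
(the same protocol repeated over independent datasets, with `lg_l1` the
same solver restricted to α = 1, i.e. plain lasso-logistic):

```r
run_simulation_study(cfg, n_replicates = 10, seed = 61)
#> <study_report> 10 replicates, 16 x 16 images (ar design, binary_shape truth), n_train = 300
#>  method    mean_pe  mean_ee
#>  lg_sob 0.09533333 36.05838
#>   lg_l1 0.15200000 33.14865
```

The smoothness-aware fit cuts the pure-L1 prediction error by more than
a third on this spatially structured truth.

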