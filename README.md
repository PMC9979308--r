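# dictmri

Accelerated MRI acquires only a fraction of k-space (the 2-D Fourier domain
of the image) and reconstructs the missing information from a prior.
`dictmri` implements and compares the three classical tiers of that prior —
increasingly adaptive "dictionaries" — together with the image
preprocessing operators and the diagnostic-concordance statistics used when
such images feed a staging decision (e.g. pre-surgical tumor T staging
read from MR versus the histopathological ground truth). It is aimed at
methods researchers and students who want a compact, fully synthetic,
CPU-scale testbed for compressed-sensing MRI ideas: every experiment in
the package runs from generated phantoms, with no external image data.

## The three reconstruction routes

Given undersampled, noisy measurements `y = M F x + n` (`F` the centered
unitary Fourier transform, `M` a boolean sampling mask):

1. **Analytic dictionary (total variation).** Solve

   `min_x ||M F x - y||_2^2 + lambda * sum_i sqrt(|D_x x|_i^2 + |D_y x|_i^2 + phi^2)`

   by gradient descent with a backtracking line search (monotone objective),
   starting from the zero-filled inverse. The sparsifier is the fixed
   discrete gradient; `phi > 0` smooths the TV seminorm so it is
   differentiable.

2. **Synthetic dictionary (K-SVD + OMP).** Model every (mean-removed) image
   patch as a T-sparse combination of learned unit-norm atoms,

   `min_{D,X} ||Y - D X||_F^2  s.t.  ||x_i||_0 <= T`,

   alternating orthogonal-matching-pursuit sparse coding with rank-1 atom
   refits. Reconstruction iterates patch coding, overlap-averaged
   reassembly and a data-consistency projection that restores the measured
   k-space entries exactly.

3. **Deep dictionary (convolutional network).** A small conv-ReLU-conv
   stack `h` trained on (zero-filled, clean) image pairs with the cost

   `H = (1/n) sum_i 0.5 ||h(x_i) - y_i||^2 + (lambda/2) sum W^2`

   by gradient descent `W <- W - alpha dH/dW` (an adaptive-moment option
   exists for benchmark-scale training), applied at test time to the
   zero-filled input, followed by the same data-consistency projection.

Supporting modules: Shepp-Logan-like phantom generation with correlated
tissue texture, sampling-mask synthesis (uniform, variable-density, radial;
conjugate-symmetric, exact sample counts), dual-tree complex wavelet
denoising, white/black morphological top-hats, spatial/frequency
enhancement, PSNR/SSIM scoring, a method-by-rate experiment runner, and
staging contingency-table analysis (per-stage sensitivity/specificity,
coincidence rate, Pearson chi-square, Cohen's kappa).

## Worked example

```r
library(dictmri)

truth <- make_phantom(phantom_spec(64, 64, texture_amp = 0.03, seed = 1))
mask  <- make_mask(mask_spec("variable_density", 0.4, seed = 2), dim(truth))
acq   <- simulate_acquisition(truth, mask, noise_sigma = 0.005, seed = 3)

zf <- zero_filled(acq)
tv <- reconstruct_tv(acq, tv_solve_spec(lambda_tv = 1e-2, max_iters = 120))

round(c(zero_filled = psnr(truth, zf), tv = psnr(truth, tv$image)), 2)
#> zero_filled          tv
#>       19.91       24.04
round(c(zero_filled = ssim(truth, zf), tv = ssim(truth, tv$image)), 4)
#> zero_filled          tv
#>      0.6254      0.8253
```

The TV solve recovers about 4.1 dB over the zero-filled baseline here; the
SSIM gain (0.63 to 0.83) reflects the removal of the incoherent aliasing
that variable-density undersampling spreads across the image. The
dictionary routes are exercised the same way via `reconstruct_dict()` and
`train_deep()`/`reconstruct_deep()`, and `run_experiment()` assembles the
full method-by-sampling-rate PSNR/SSIM table.

Staging concordance from a shipped imaging-vs-pathology table:

```r
tb <- read_staging_table(system.file("extdata", "table2_mr_staging.csv",
                                     package = "dictmri"))
evaluate_cohort(tb)
#> n = 146 patients, 3 stages (T1-2, T3, T4)
#> overall coincidence rate (trace/total): 35.62%
#> Cohen's kappa: 0.0313
#> Pearson chi-square: 8.9114 (df = 4, p = 0.06335)
#>  stage sensitivity_pct specificity_pct n_pathology n_imaging
#>   T1-2           46.34           65.71          41        55
#>     T3           31.03           56.82          58        56
#>     T4           31.91           79.80          47        35
```

## Command line

A thin `dictmri` executable (installed under `exec/`) exposes the same
functionality: `dictmri phantom`, `mask`, `acquire`, `cohort`, `denoise`,
`tophat`, `enhance`, `recon-tv`, `recon-dict`, `recon-deep`, `eval`,
`staging-eval`, `experiment`; every subcommand takes `--seed` and `--out`,
and file-producing runs emit a JSON manifest of resolved parameters.

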