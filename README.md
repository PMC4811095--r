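# dltgv

Compressed-sensing MRI reconstruction in R, combining an **adaptively learned
patch dictionary** (K-SVD + orthogonal matching pursuit) with a
**second-order total generalized variation (TGV²)** penalty, solved by an
alternating direction method of multipliers (ADMM) whose coupled
image/vector-field subproblem has a closed-form per-frequency solution.

## The problem

MRI acquires data in k-space (the 2D Fourier domain of the image). Scans can
be accelerated by sampling only a subset of k-space, at the price of aliasing
artifacts in the naive zero-filled reconstruction. Undersampled
reconstruction estimates the image `u ∈ ℂ^{n×n}` from measurements

    b = K u + ξ,     K = P F,

where `F` is the unitary 2D DFT, `P` selects the sampled locations and `ξ` is
complex white Gaussian noise. The package solves

    min_{u, p, A, Γ}  (β/2)‖Ku − b‖₂²  +  (λ₀/2)‖AΓ − Ru‖₂²
                      + α₁‖Du − p‖₁  +  α₀‖ε(p)‖₁

* `R` extracts all overlapping 6×6 patches (with periodic wrap, so
  `RᵀR = 36·I`); `A ∈ ℂ^{36×144}` is a dictionary learned by K-SVD and
  `Γ` the sparse patch codes found by OMP — the adaptive prior that recovers
  texture and fine detail;
* `α₁‖Du − p‖₁ + α₀‖ε(p)‖₁` is the second-order TGV penalty (`D` forward
  differences, `ε` the symmetrized gradient of the auxiliary field `p`) —
  favours piecewise-affine images without the staircasing of plain TV;
* the two `ℓ₁` terms are split with auxiliaries `y = Du − p`, `z = ε(p)` and
  handled by isotropic shrinkage; the remaining quadratic in `(u, p₁, p₂)` is
  circulant in every block except `K*K` (diagonal in the DFT basis), so it is
  solved exactly as an independent 3×3 Hermitian system per frequency via
  Cramer's rule.

Sampling-mask generators (pseudo-radial, variable-density random, Cartesian
phase-encode, Archimedean spiral), a Shepp–Logan/complex-phase phantom
module, and PSNR / HFEN quality metrics make the package self-contained: no
external data are needed to exercise it.

## Worked example

```r
library(dltgv)

ref  <- shepp_logan(128)                       # [0, 255] head phantom
mask <- make_mask("radial", 128, 4, seed = 1)  # pseudo-radial, 4-fold
print(mask)
#> k-space sampling mask: 128x128, scheme=radial, kept=4092 (factor 4.004)

b <- forward_measure(ref, mask)                # noiseless k-space samples
res <- reconstruct(b, solver_params(), reference = ref)
print(res)
#> reconstruction: 128x128 image, 15 outer iterations, objective 1.4643e+07
#>   final PSNR vs reference: 26.70 dB

psnr(ref, adjoint_measure(b))                  # zero-filled baseline
#> [1] 19.21
hfen(ref, res$u)
#> [1] 0.0961
```

The reconstruction recovers 7.5 dB over the zero-filled baseline at 4-fold
undersampling; HFEN (the relative Laplacian-of-Gaussian error norm) near 0.1
indicates that edges and fine features are largely restored. Setting
`alpha0 = alpha1 = 0` gives a dictionary-only reconstruction, `lambda0 = 0` a
pure TGV² reconstruction — both useful baselines.

A command-line wrapper is installed with the package:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "dltgv.R", package = "dltgv"))')" \
    reconstruct --n 128 --scheme radial --factor 4 --out run1
```

with subcommands `makemask`, `simulate`, `reconstruct`, `sweep`; every run
archives its JSON configuration next to its outputs.

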