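# smstempo

Temporally regularized SENSE reconstruction and statistical-efficiency
analysis for simultaneous multi-slice (SMS) fMRI.

## The problem

SMS-EPI accelerates fMRI by exciting and jointly encoding MB slices per
shot; the price is g-factor noise amplification wherever the coil array
cannot cleanly separate the folded voxels. Conventional reconstructions
treat every time-point independently. This package implements a
reconstruction that couples time-points through an L2 temporal smoothness
penalty and — because the whole pipeline stays linear — quantifies exactly
what that buys and costs, voxel by voxel. It is aimed at fMRI
reconstruction methodologists: people choosing sampling schemes and
regularization weights, and wanting the statistical consequences in closed
form instead of rules of thumb.

## The model

With `A` the (block-diagonal-in-time) SENSE encoding operator of a
time-varying CAIPI sampling scheme and `∇` the temporal finite difference,
the reconstruction is

    x̂ = argmin_x ‖Ax − k‖² + λ‖∇x‖²  =  (A′A + λ∇′∇)⁻¹ A′k
       = S_λ A⁺k,      S_λ = (A′A + λ∇′∇)⁻¹(A′A)

`S_λ` is an *encoding-dependent* temporal smoother: it adapts to the local
conditioning, smoothing badly aliased voxels more. From it the package
computes analytically, per voxel:

* bias `(S_λ − I)x` (residual aliasing / slice leakage of a signal `x`);
* g-factor `g(m,t)² = diag(S_λ(A′A)⁻¹S_λ′)·diag(A′A)` (g = 1 for a voxel
  with no fold-over partners at λ = 0);
* effective temporal DOF `tr_m(S_λ S_λ′)` (= Nt at λ = 0);
* relative GLM efficiency — exact, for a given task regressor, and the
  asymptotic form `(g0/g_λ)² · DOF_λ/Nt`;
* tSNR efficiency `mean/sd · sqrt(DOF/Nt)`.

The headline result the package reproduces: efficiency gains exist exactly
where `g0 > 1`, and encoding-independent post-hoc smoothing with matched
DOF can never gain. Everything runs on synthetic data (coil models,
cylindrical phantoms, 1/f BOLD-like signals, task regressors, complex
Gaussian noise), so no acquisition is needed.

## Worked example

```r
library(smstempo)
## MB = 8 CAIPI encoding with 16 synthetic coils on a 24 x 24 x 8 grid
scheme <- SamplingScheme(nKy = 24, nKz = 8, nT = 64, ry = 1,
                         dkzDky = 3, dkzDt = 2)
mask   <- buildCaipiMask(scheme)
sens   <- synthSensitivities(16, c(24, 24, 8), seed = 1)
scheme
#> SamplingScheme: 24 x 8 (ky x kz), 64 time-points
#>   ry = 1, dkz/dky = 3/1, dkz/dt = 2, dky/dt = 0
#>   24 samples per shot (undersampling factor 8)

## analytic quality maps at lambda = 1e-2 with a 5-period block design
rep <- efficiencyMaps(sens, mask, lambda = 1e-2,
                      design = makeRegressor("block", 64))
rep
#> EfficiencyReport (lambda = 0.01, nT = 64, 3008 support voxels)
#>   g0:      median 1.193  max 1.749
#>   g:       median 0.950  max 1.074
#>   DOF/nT:  median 0.726
#>   e (asym): median 1.140  max 1.970
#>   e (exact): median 1.095  max 1.679

## noise-free leakage check: 1/f signal confined to slice 5
sim2 <- runSim2(sens, mask, lambdas = c(0, 1e-2), nRepeats = 5, seed = 1)
for (r in sim2$results)
  cat(sprintf("lambda = %g: 95th-pct NRMSE, unexcited slices = %.4f\n",
              r$lambda, r$p95Unexcited))
#> lambda = 0: 95th-pct NRMSE, unexcited slices = 0.0000
#> lambda = 0.01: 95th-pct NRMSE, unexcited slices = 0.0029
```

Reading the numbers: at λ = 1e-2 the worst-conditioned voxels (g0 up to
1.75 here) see their noise fall below the fully sampled reference
(g = 0.95 median) while retaining 73% of their temporal DOF — a net GLM
efficiency gain of up to 1.68 under the block design. The cost is bias:
with a realistic low-frequency signal confined to one slice, the
95th-percentile leakage into the other slices is 0.3% of the slice's RMS
signal (exactly zero at λ = 0, which is unbiased).

Reconstruction itself: `forwardOp()` / `adjointOp()` apply the encoding,
`solveCG()` is the general iterative solver (tolerance 1e-4, 200
iterations), and `solveDirect()` the exact per-alias-group factorization
the analytics are built on. `runSim1()` is the Monte-Carlo noise study
validating the analytic g/DOF/efficiency expressions empirically.

A thin command-line wrapper is installed at `inst/cli/smstempo.R`
(verbs: `mask`, `fixtures`, `recon`, `metrics`, `sim1`, `sim2`), e.g.

```sh
Rscript "$(Rscript -e 'cat(system.file("cli","smstempo.R",package="smstempo"))')" \
  sim2 --n-ky 48 --n-kz 8 --nt 64 --dkz-dky 3 --dkz-dt 2 -o sim2.rds
```

## Vignette

`vignettes/temporal-regularization.Rmd` documents the model and its
assumptions, the alias-group decomposition and block-tridiagonal solver
that make the exact computations tractable, the boundary-condition and
normalization conventions, what the synthetic data do and do not emulate,
and known limitations.
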