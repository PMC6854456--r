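---
title: "Spatially adaptive temporal regularization for SMS fMRI: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatially adaptive temporal regularization for SMS fMRI: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The reconstruction model

Simultaneous multi-slice (SMS) EPI excites MB slices per shot and encodes
them jointly; unaliasing is a parallel-imaging inverse problem that is
conveniently treated as 3D Cartesian undersampling of a (ky, kz) lattice,
where the kz axis indexes the simultaneous slices. `smstempo` solves the
temporally regularized SENSE problem

$$ \hat{x} = \arg\min_x \|Ax - k\|_2^2 + \lambda \|\nabla x\|_2^2
          = (A'A + \lambda \nabla'\nabla)^{-1} A'k $$

where $A$ is block diagonal over time (coil sensitivity weighting followed
by the under-sampled unitary Fourier transform of each shot), $k$ is the
multi-coil k-space time-series, and $\nabla$ is the order-1 finite
difference along time, applied voxel-by-voxel. The penalty trades temporal
resolution for noise: it is an L2 smoother, so the whole reconstruction
stays linear and can be analyzed in closed form.

The central analytic object is the equivalent smoothing operator

$$ S_\lambda = (A'A + \lambda \nabla'\nabla)^{-1} (A'A), $$

which maps the conventional pseudoinverse reconstruction to the regularized
one. $S_\lambda$ depends on $A'A$, i.e. on the coil geometry and the
sampling pattern, so the smoothing is *spatially adaptive*: strongly
aliased voxels are smoothed more than well-conditioned ones at the same
$\lambda$. Everything the package computes — bias, g-factor, effective
degrees of freedom (DOF), GLM and tSNR efficiency — derives from
$S_\lambda$:

* **bias** $(S_\lambda - I)x$: signal misallocation (residual aliasing and
  inter-slice leakage) of a noise-free signal $x$;
* **g-factor** $g(m,t)^2 = \mathrm{diag}(S_\lambda (A'A)^{-1}
  S_\lambda')_{m,t}\,\mathrm{diag}(A'A)_{m,t}$: noise amplification
  relative to a fully sampled, unsmoothed reconstruction, anchored so a
  voxel with no fold-over partners has $g = 1$ at $\lambda = 0$;
* **approximate DOF** $\mathrm{tr}_m(S_\lambda S_\lambda')$: the per-voxel
  sum of squared operator row norms, equal to $N_t$ exactly at
  $\lambda = 0$;
* **GLM efficiency** (relative to $\lambda = 0$): the squared g-factor
  ratio, times the effective-DOF ratio, times the design-variance ratio
  computed from the smoothed design $\tilde D = S_\lambda D$. Its
  asymptotic, design-free form is $(g_0/g_\lambda)^2\,
  \mathrm{tr}_m(S_\lambda S_\lambda')/N_t$ — the g-factor gain per retained
  DOF. We note that a superficially different reading of the asymptotic
  expression (with $N_t/\mathrm{tr}_m$ in place of $\mathrm{tr}_m/N_t$)
  is inconsistent with both the stated iff-characterization of a net
  benefit and the fact that post-hoc smoothing cannot gain; the package
  implements the consistent form.
* **tSNR efficiency** $\mathrm{mean}(|x|)/\mathrm{sd}(x)\cdot
  (\mathrm{DOF}/N_t)^{1/2}$: conventional tSNR discounted for lost
  temporal DOF. The square-root exponent follows the precision scaling of
  a mean estimate with its DOF; a linear exponent is available behind the
  `exponent` argument for sensitivity analyses.

The key scientific point these quantities express: regularization helps
*only* where $g_0 > 1$. Encoding-independent post-hoc smoothing
$S_\kappa = (I + \kappa\nabla'\nabla)^{-1}$ filters noise but reduces DOF
in exact proportion, so its efficiency never exceeds 1; the
encoding-*dependent* $S_\lambda$ reduces the variance of poorly
conditioned voxels faster than their DOF, producing a net statistical
benefit there.

## Sampling schemes

A CAIPI scheme is parameterized by three ratios: `dkzDky` (the within-shot
kz blip per unit ky, which sets the inter-slice FOV shift), `dkzDt` (the
between-shot kz shift of the whole pattern) and `dkyDt` (the between-shot
ky shift, meaningful only with in-plane acceleration `ry > 1`). Indices
are 0-based with DC at index 0 and all shifts are modular, so the
shot-to-shot relation is an exact integer statement that the tests assert
literally. One shot's samples must form a lattice (a cyclic subgroup of
the (ky, kz) torus); the induced image-domain fold-over offsets are the
lattice's dual, and the voxels connected by those offsets form
time-invariant *alias groups* — at most `MB * ry` voxels each — which are
the unit of every direct computation. Non-constant (pseudorandom) shift
schedules are accepted by the mask builder but break time-invariance, so
they route to the iterative solver.

## Solvers and numerical choices

Two solver paths cross-validate each other:

* `solveCG()`: plain conjugate gradients on the normal equations with the
  matrix-free FFT operator, relative tolerance `1e-4`, at most 200
  iterations (the defaults used for all reconstructions here). No
  preconditioner is applied by default.
* `solveDirect()` / `smoothingOperator()`: exact per-alias-group solves.
  In time-major ordering the group system $A'A + \lambda\nabla'\nabla$ is
  Hermitian block tridiagonal ($A'A$ is block diagonal over time with
  $G \times G$ blocks conjugated by the shift phase schedule; $\nabla'\nabla$
  is tridiagonal), so it is factorized by a block-Thomas LDL recursion in
  $O(N_t G^3)$ rather than $O((G N_t)^3)$. This is what makes full-volume
  analytic maps and Monte-Carlo studies feasible on one CPU. The dense
  whole-problem inverse is retained in the test suite as a brute-force
  oracle; the two agree to ~1e-15.

Boundary convention: $\nabla$ uses non-circulant forward differences by
default — fMRI series are not periodic, and a circulant wrap would couple
the first and last frames. A consequence worth knowing: at $\lambda > 0$
the noise variance (hence $g(m,t)$) deviates slightly at the series ends,
so per-time g-factors are exactly stationary only at $\lambda = 0$ or
under the circulant variant (`circulant = TRUE`), which is provided for
analyses that require strict stationarity (the circulant system is not
block tridiagonal and is factorized densely, so it is reserved for
operator construction rather than volume solves).

Degenerate inputs: alias groups whose coil-overlap matrix is singular
(e.g. fewer effective coils than fold-over partners at $\lambda = 0$)
raise an explicit error on the direct path; temporal regularization cannot
repair them, because a time-constant difference of identical-sensitivity
partners is in the null space of both terms. The CG path on such
(consistent but singular) systems converges to a non-unique solution — the
correct diagnosis there is non-identifiability, which the tests assert as
failure to recover an encoded truth.

Tie-breaks and conventions: unitary FFT scaling throughout, so published
$\lambda$ values in the 1e-3..1e-1 range land in a comparable operating
regime with the synthetic suite's amplitude convention (phantom baseline
magnitude 1); coil noise is assumed whitened (identity covariance);
the readout direction is fully sampled, kept in the image domain, and
never mixes voxels.

## The synthetic suite: what it emulates, and what it does not

`synthSensitivities()` builds smooth complex coil profiles (Gaussian-lobed
magnitudes from rings of coil centres around the support, slowly varying
phase, sum-of-squares normalized to 1 inside a cylindrical support). They
stand in for measured, coil-compressed sensitivities and reproduce their
qualitative behaviour — spatially varying conditioning with central g-factor
hot spots (g0 up to ~2.4 on the default 48x48x8, 16-coil, MB = 8
configuration) — but not the fine structure of any physical array. For the
same reason the leakage simulation's absolute NRMSE is comparable to
measured-coil values only in order of magnitude, and the package treats
published leakage levels as upper bounds rather than equalities.

`oneOverFSignal()` draws real series with power ∝ 1/f over non-zero
frequencies (random phases, Hermitian symmetrized, DC excluded and
modelled as a separate baseline); the fitted log-log spectral slope is
−1.0. `makeRegressor()` provides the three probe designs (5-period block;
fast event-related as seeded Bernoulli events convolved with a
double-gamma HRF; white noise), standardized to zero mean and unit norm.

Two study drivers orchestrate the analyses:

* `runSim1()` — noise-only Monte Carlo: complex Gaussian k-space noise is
  propagated through the reconstruction group by group (with its exact
  per-group covariance), giving empirical g-factors, DOF (white
  image-domain noise pushed through $S_\lambda$) and efficiency next to
  the analytic values, plus mean noise periodograms against DOF-matched
  post-hoc smoothing. The reduced-scale default (48x48x8 volume, 64
  time-points, 200 realizations) reproduces the analytic maps to within
  ~2% (g) and ~4% (DOF) worst-case per voxel; the full-scale conditions
  (256 time-points, 1000 realizations) are a parameter change.
* `runSim2()` — signal-only leakage: a noise-free 1/f signal confined to
  one slice (slice 5 of 8 by default) is encoded and reconstructed; any
  signal in the other slices is leakage. Since the paper's signal
  normalization is not published, the suite uses baseline 1 + 5% 1/f
  fluctuation and normalizes NRMSE to the excited slice's average RMS
  (the same normalization used for single-band in-vivo leakage
  assessments, baseline-dominated in both cases). At $\lambda = 0$ the
  NRMSE is zero to solver precision; at $\lambda = 10^{-2}$ the
  95th-percentile unexcited-slice NRMSE is ~0.004, and it is insensitive
  (<20% variation) to the between-shot shift because the fold-over
  pattern itself does not change with the shift.

What passing these simulations does *not* show about real data: the noise
model is white and thermal (no physiological noise, no autocorrelation —
efficiency statements are therefore about the thermally dominated regime);
sensitivities are exact (no mis-calibration, which in practice produces
sharp tSNR-efficiency boundaries); there is no motion, off-resonance or
EPI distortion; and the magnitude transform's noise-floor bias is ignored,
which is acceptable at tSNR > 2.

## Parameters that matter

| parameter | meaning | default | why |
|---|---|---|---|
| `lambda` | temporal regularization weight (unitless; data scaled by unitary FFT, phantom baseline 1) | — (study parameter) | 1e-3..1e-2 gives meaningful efficiency gains with leakage well below reference bounds; peak efficiency near 1e-1 at the cost of visible smoothing |
| `tol`, `maxiter` | CG stopping rule | 1e-4, 200 | reconstruction solver settings used throughout |
| `dkzDky` | within-shot CAIPI blip | 3 (studies) | standard FOV-shift conditioning of MB = 8 |
| `dkzDt` | between-shot kz shift | 2 (studies) | time-varying sampling: lower g at equal DOF; leakage unaffected |
| `fluctSd` | 1/f fluctuation SD relative to baseline | 0.05 | typical resting BOLD amplitude |
| `nReal` | Monte-Carlo realizations | 200 (reduced), 1000 (full) | 200 already bounds per-voxel MC error under 5% |
| `excitedSlice` | Sim2 signal slice | 5 | middle slice of the MB = 8 stack |
| `exponent` | tSNR-efficiency DOF exponent | 0.5 | precision scaling of a mean with its DOF |

Problem sizes: the package's reference configurations are 24x24x8 (exact
identities, efficiency maps) and 48x48x8 (Monte Carlo, leakage), both with
Nt = 64, chosen so every analysis in the test suite and the acceptance
script completes in minutes on a single CPU while preserving the study
structure (MB = 8, 16 coils, dkz/dky = 3, dkz/dt = 2). The full-scale
96x96x8x256 conditions are reachable by changing the size arguments only.

## Known limitations

* Exact GLM efficiency supports a single effect regressor (p = 1);
  nuisance regressors must be projected out of the effect column first.
  The multi-contrast generalization of the efficiency ratio is not
  defined here.
* The efficiency machinery assumes white thermal noise after whitening;
  no pre-whitened GLM or physiological noise model is included.
* For a g0 = 1 voxel the exact efficiency can exceed 1 by O(1e-4) at
  small lambda — a finite-Nt second-order term in the DOF ratio, not a
  real gain; tests bound it at 1e-3.
* The asymptotic efficiency tracks the exact one to a few percent only in
  the mild-smoothing regime (DOF/Nt ≳ 0.85 for the block design); at
  DOF/Nt ≈ 0.6 they differ by tens of percent, as expected from its
  derivation.
* Cartesian lattices only; the general formulation admits non-Cartesian
  trajectories but this implementation does not.
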