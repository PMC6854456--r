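#' @include AllClasses.R AllGenerics.R smoothing.R
NULL

#' Analytic g-factor per voxel and time-point
#'
#' Noise amplification of the regularized estimator relative to a fully
#' sampled, unsmoothed reconstruction with the same coils:
#' `g(m, t)^2 = diag(S (A'A)^{-1} S')_(m,t) * diag(A'A)_(m,t)`. The
#' normalization anchors `g = 1` for a voxel that does not alias onto any
#' other voxel at `lambda = 0`. For constant-shift schemes `g(m, t)` is
#' constant across time.
#'
#' @param S a [SmoothingOperator].
#' @return numeric matrix (G x nT) of per-time g-factors.
#' @seealso [gFactorRMS()] for the per-voxel RMS average, [g0Factor()] for
#'   the unregularized reference.
#' @export
gFactor <- function(S) {
  stopifnot(is(S, "SmoothingOperator"))
  v <- matrix(S@varDiag, S@groupSize, S@nT)
  sqrt(pmax(v * S@ataDiag, 0))
}

#' Per-voxel RMS g-factor
#'
#' Root-mean-square of the per-time g-factor across time.
#'
#' @param S a [SmoothingOperator].
#' @return numeric vector of length G.
#' @export
gFactorRMS <- function(S) {
  g <- gFactor(S)
  sqrt(rowMeans(g^2))
}

#' Unregularized g-factor of the group members
#'
#' `g0(m) = sqrt((A'A)_mm * ((A'A)^{-1})_mm)` (time-independent), equal to 1
#' exactly for singleton groups.
#'
#' @param S a [SmoothingOperator].
#' @return numeric vector of length G.
#' @export
g0Factor <- function(S) S@g0

#' Approximate effective degrees of freedom
#'
#' The design-independent DOF measure `trm(S S')`: for voxel `m`, the sum
#' over time of the squared full-row norms of the smoothing operator
#' (including cross-voxel coupling). Equals `nT` exactly at `lambda = 0`
#' and decreases monotonically with regularization.
#'
#' @param S a [SmoothingOperator].
#' @param m optional member index; default all members.
#' @return numeric vector (length G, or 1 if `m` given).
#' @export
approxDof <- function(S, m = NULL) {
  stopifnot(is(S, "SmoothingOperator"))
  rn <- rowSums(Mod(S@S)^2)
  dof <- rowSums(matrix(rn, S@groupSize, S@nT))
  if (is.null(m)) dof else dof[m]
}

## Nt x (G*nT) row slab of S for voxel m, and the voxel's Nt x Nt
## self-coupling Gram matrix W = S_m. S_m.'
voxelRowGram <- function(S, m) {
  idx <- (0:(S@nT - 1L)) * S@groupSize + m
  Rm <- S@S[idx, , drop = FALSE]
  Rm %*% Conj(t(Rm))
}

checkDesign <- function(D, nT) {
  D <- as.matrix(D)
  if (nrow(D) != nT)
    stop("design matrix has ", nrow(D), " rows but the series has ", nT,
         " time-points")
  if (qr(D)$rank < ncol(D))
    stop("design matrix is rank deficient")
  D
}

#' Exact effective degrees of freedom under a design
#'
#' Residual effective DOF of an ordinary least-squares fit of the smoothed
#' design to the smoothed data:
#' `DOF = trm((I - P) S S')` with `P` the projector onto the smoothed
#' design `SD` (the voxel's temporal block of `S` applied to `D`). At
#' `lambda = 0` this is `nT - p` for any full-rank design with `p` columns.
#'
#' @param S a [SmoothingOperator].
#' @param D design matrix (nT x p).
#' @param m member index (default all).
#' @return numeric vector of effective DOF.
#' @export
effectiveDof <- function(S, D, m = NULL) {
  stopifnot(is(S, "SmoothingOperator"))
  D <- checkDesign(D, S@nT)
  mm <- if (is.null(m)) seq_len(S@groupSize) else m
  vapply(mm, function(i) {
    W <- voxelRowGram(S, i)
    Dt <- temporalBlock(S, i) %*% D
    DtH <- Conj(t(Dt))
    gram <- DtH %*% Dt
    if (qr(Dt)$rank < ncol(Dt)) {
      bad <- which.min(colSums(Mod(Dt)))
      stop("smoothed design is rank deficient (regressor ",
           if (is.null(colnames(D))) bad else colnames(D)[bad],
           " vanishes under smoothing)")
    }
    C1 <- DtH %*% W %*% Dt
    Re(sum(diag(W))) - Re(sum(diag(solve(gram, C1))))
  }, 0)
}

#' Exact relative GLM efficiency
#'
#' Voxel-wise efficiency of the effect estimate from the regularized
#' reconstruction relative to the unregularized one:
#' the squared g-factor ratio, times the effective-DOF ratio, times the
#' ratio of the design-induced estimator variances
#' `(D'D)^{-1}` versus `(SD)'(SD))^{-1} (SD)' S S' (SD) ((SD)'(SD))^{-1}`.
#' Equals 1 identically at `lambda = 0`; exceeds 1 only where the
#' unregularized g-factor exceeds 1.
#'
#' Only single-effect designs (`p = 1`) are supported; nuisance regressors
#' should be projected out of the effect column beforehand.
#'
#' @param S a [SmoothingOperator].
#' @param D design matrix (nT x 1).
#' @param m member index (default all).
#' @return numeric vector of relative efficiencies.
#' @export
glmEfficiencyExact <- function(S, D, m = NULL) {
  stopifnot(is(S, "SmoothingOperator"))
  D <- checkDesign(D, S@nT)
  if (ncol(D) != 1L)
    stop("only single-effect designs (p = 1) are supported; project ",
         "nuisance regressors out of the effect column first")
  mm <- if (is.null(m)) seq_len(S@groupSize) else m
  gbar <- gFactorRMS(S)
  g0 <- S@g0
  if (length(g0) == 1L) g0 <- rep(g0, S@groupSize)
  dd <- as.numeric(crossprod(D))
  vapply(mm, function(i) {
    W <- voxelRowGram(S, i)
    Dt <- temporalBlock(S, i) %*% D
    nd <- Re(Conj(t(Dt)) %*% Dt)[1, 1]
    if (nd <= .Machine$double.eps * dd)
      stop("smoothed design is rank deficient (regressor 1 vanishes under smoothing)")
    sandwich <- Re(Conj(t(Dt)) %*% W %*% Dt)[1, 1] / nd^2
    dofEff <- {
      C1 <- Re(Conj(t(Dt)) %*% W %*% Dt)[1, 1]
      Re(sum(diag(W))) - C1 / nd
    }
    dof0 <- S@nT - 1
    (g0[i] / gbar[i])^2 * (dofEff / dof0) * ((1 / dd) / sandwich)
  }, 0)
}

#' Asymptotic relative GLM efficiency
#'
#' The design-independent large-`nT`, small-`lambda` limit: the squared
#' g-factor ratio normalized by the respective DOF,
#' `e = (g0 / g)^2 * (trm(S S') / nT)`. Efficiency exceeds 1 exactly when
#' regularization reduces the squared g-factor faster than the effective
#' DOF, i.e. when `g^2 / DOF < g0^2 / nT`.
#'
#' @param S a [SmoothingOperator].
#' @param m member index (default all).
#' @return numeric vector of relative efficiencies.
#' @export
glmEfficiencyAsymptotic <- function(S, m = NULL) {
  stopifnot(is(S, "SmoothingOperator"))
  mm <- if (is.null(m)) seq_len(S@groupSize) else m
  gbar <- gFactorRMS(S)
  g0 <- S@g0
  if (length(g0) == 1L) g0 <- rep(g0, S@groupSize)
  dof <- approxDof(S)
  ((g0 / gbar)^2 * dof / S@nT)[mm]
}

#' tSNR efficiency map
#'
#' Conventional temporal SNR (mean over standard deviation of the
#' magnitude time-course) adjusted for the effective temporal degrees of
#' freedom: `tSNReff = mean(|x|) / sd(x) * (DOF / nT)^exponent`. With
#' `DOF / nT = 1` this is the conventional tSNR; with fewer effective DOF
#' the efficiency decreases to reflect the reduced independent information
#' per unit time. The default square-root exponent follows the precision
#' scaling of a mean estimate with its DOF; `exponent = 1` is available
#' behind the flag.
#'
#' @param ts numeric (magnitude) array `(Nx, Ny, Nz, Nt)`.
#' @param dofMap numeric array `(Nx, Ny, Nz)` of effective DOF (e.g. from
#'   [efficiencyMaps()]), or a scalar.
#' @param exponent exponent on `DOF / nT` (0.5 or 1).
#' @return numeric array `(Nx, Ny, Nz)`; voxels with zero temporal standard
#'   deviation are returned as NA (masked out).
#' @export
tsnrEfficiency <- function(ts, dofMap, exponent = 0.5) {
  stopifnot(is.array(ts), length(dim(ts)) == 4L, dim(ts)[4] >= 2L)
  if (is.complex(ts)) stop("magnitude (or real) time-series required")
  nT <- dim(ts)[4]
  d3 <- dim(ts)[1:3]
  m <- matrix(ts, prod(d3), nT)
  mu <- rowMeans(abs(m))
  sd <- sqrt(rowSums((m - rowMeans(m))^2) / (nT - 1))
  out <- mu / sd * (as.vector(dofMap) / nT)^exponent
  out[sd == 0] <- NA_real_
  array(out, d3)
}

#' Expected reconstruction bias of a noise-free signal
#'
#' The signal misallocation `(S - I) x` produced by the smoothing
#' operator: the expected difference between the regularized
#' reconstruction and the truth, which quantifies residual aliasing and
#' inter-slice leakage. Identically zero at `lambda = 0`.
#'
#' @param S a [SmoothingOperator].
#' @param xTrue complex matrix (G x nT) of noise-free member time-courses.
#' @return complex matrix (G x nT) of expected bias.
#' @export
biasMap <- function(S, xTrue) {
  stopifnot(is(S, "SmoothingOperator"))
  xTrue <- as.matrix(xTrue)
  stopifnot(nrow(xTrue) == S@groupSize, ncol(xTrue) == S@nT)
  v <- as.vector(xTrue)                    # time-major: (t-1)*G + m
  matrix(S@S %*% v - v, S@groupSize, S@nT)
}

#' Normalized root-mean-square error across time
#'
#' Per-voxel RMS of the reconstruction error over time, divided by a
#' reference signal level (typically the average RMS signal of the excited
#' slice, see [refRms()]).
#'
#' @param xHat,xTrue arrays `(Nx, Ny, Nz, Nt)` (complex or numeric).
#' @param ref positive scalar reference RMS.
#' @return numeric array `(Nx, Ny, Nz)`.
#' @export
nrmse <- function(xHat, xTrue, ref) {
  stopifnot(identical(dim(xHat), dim(xTrue)))
  if (!is.numeric(ref) || length(ref) != 1L || ref <= 0)
    stop("reference RMS must be a positive scalar")
  d <- dim(xHat)
  e <- matrix(xHat - xTrue, prod(d[1:3]), d[4])
  array(sqrt(rowMeans(Mod(e)^2)) / ref, d[1:3])
}

#' Average RMS signal level over a reference region
#'
#' @param x array `(Nx, Ny, Nz, Nt)`.
#' @param region logical array `(Nx, Ny, Nz)` selecting the reference
#'   voxels (e.g. the excited slice within the support).
#' @return scalar mean-across-region of the per-voxel temporal RMS.
#' @export
refRms <- function(x, region) {
  d <- dim(x)
  m <- matrix(x, prod(d[1:3]), d[4])
  mean(sqrt(rowMeans(Mod(m[as.vector(region), , drop = FALSE])^2)))
}

#' Voxel-wise efficiency maps for an encoding
#'
#' Computes, alias group by alias group, the analytic quality metrics of a
#' regularized reconstruction on the full image grid: unregularized and
#' regularized RMS g-factors, approximate effective DOF, and the exact
#' (design-dependent) and asymptotic relative GLM efficiencies.
#'
#' @param sens a [CoilSensitivities].
#' @param mask a [SamplingMask].
#' @param lambda temporal regularization weight.
#' @param design optional nT x 1 design matrix for the exact efficiency.
#' @param groups optional precomputed [aliasGroups()] result.
#' @return an [EfficiencyReport]; out-of-support voxels are NA.
#' @export
efficiencyMaps <- function(sens, mask, lambda, design = NULL, groups = NULL) {
  if (is.null(groups)) groups <- aliasGroups(mask, sens)
  d <- dim(sens@values)[1:3]
  nT <- mask@scheme@nT
  blank <- array(NA_real_, d)
  g0m <- gm <- dofm <- em <- eam <- blank
  if (!is.null(design)) design <- checkDesign(design, nT)
  for (g in groups) {
    S <- smoothingOperator(g, lambda)
    ii <- cbind(g@x, g@members[, 1] + 1L, g@members[, 2] + 1L)
    g0m[ii] <- g0Factor(S)
    gm[ii] <- gFactorRMS(S)
    dofm[ii] <- approxDof(S)
    eam[ii] <- glmEfficiencyAsymptotic(S)
    if (!is.null(design)) em[ii] <- glmEfficiencyExact(S, design)
  }
  new("EfficiencyReport", g0 = g0m, gLam = gm, dof = dofm, eLam = em,
      eAsym = eam, lambda = lambda, nT = as.integer(nT), design = design)
}

setMethod("show", "EfficiencyReport", function(object) {
  ok <- !is.na(object@g0)
  cat(sprintf("EfficiencyReport (lambda = %g, nT = %d, %d support voxels)\n",
              object@lambda, object@nT, sum(ok)))
  if (any(ok)) {
    cat(sprintf("  g0:      median %.3f  max %.3f\n",
                stats::median(object@g0[ok]), max(object@g0[ok])))
    cat(sprintf("  g:       median %.3f  max %.3f\n",
                stats::median(object@gLam[ok]), max(object@gLam[ok])))
    cat(sprintf("  DOF/nT:  median %.3f\n",
                stats::median(object@dof[ok]) / object@nT))
    if (!all(is.na(object@eAsym)))
      cat(sprintf("  e (asym): median %.3f  max %.3f\n",
                  stats::median(object@eAsym[ok]), max(object@eAsym[ok])))
    if (!all(is.na(object@eLam[ok])))
      cat(sprintf("  e (exact): median %.3f  max %.3f\n",
                  stats::median(object@eLam[ok]), max(object@eLam[ok])))
  }
})
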