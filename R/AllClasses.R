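#' @import methods
NULL

setClassUnion("matrixOrNULL", c("matrix", "NULL"))

#' CAIPI sampling scheme
#'
#' Parameterization of a time-varying Cartesian CAIPI sampling pattern for an
#' SMS (or 3D) acquisition. A scheme is defined on an `nKy` x `nKz` phase
#' encode / partition lattice with `nT` shots (volume time-points). Within a
#' shot, every `ry`-th ky line is acquired and the kz blip schedule advances
#' kz by `dkzDky` per unit ky (a rational number, stored as numerator and
#' denominator). Between shots the whole pattern is circularly shifted by
#' `dkyDt` in ky and `dkzDt` in kz.
#'
#' All indices are 0-based with DC at index 0 and shifts are applied modulo
#' `(nKy, nKz)`, so the shot-to-shot shift relation is an exact integer
#' statement on the lattice.
#'
#' @slot nKy integer, number of ky phase-encode lines (also image Ny).
#' @slot nKz integer, number of kz partitions = simultaneous slices MB
#'   (also image Nz).
#' @slot nT integer, number of time points.
#' @slot ry integer, in-plane acceleration (>= 1).
#' @slot dkzDkyNum,dkzDkyDen integers, kz increment per unit ky as a rational
#'   `dkzDkyNum / dkzDkyDen`.
#' @slot dkzDt integer, kz shift of the whole pattern per shot.
#' @slot dkyDt integer, ky shift of the pattern per shot (only meaningful
#'   with `ry > 1`).
#' @exportClass SamplingScheme
setClass("SamplingScheme",
         representation(nKy = "integer", nKz = "integer", nT = "integer",
                        ry = "integer", dkzDkyNum = "integer",
                        dkzDkyDen = "integer", dkzDt = "integer",
                        dkyDt = "integer"))

setValidity("SamplingScheme", function(object) {
  msg <- character()
  if (object@nKy < 1L || object@nKz < 1L || object@nT < 1L)
    msg <- c(msg, "nKy, nKz and nT must be positive")
  if (object@ry < 1L)
    msg <- c(msg, "in-plane acceleration ry must be >= 1")
  if (object@nKy %% object@ry != 0L)
    msg <- c(msg, sprintf(
      "invalid scheme: nKy (%d) must be divisible by ry (%d) for an integer number of samples per shot",
      object@nKy, object@ry))
  if (object@dkzDkyDen < 1L)
    msg <- c(msg, "dkzDky denominator must be positive")
  blip <- object@ry * object@dkzDkyNum
  if (blip %% object@dkzDkyDen != 0L)
    msg <- c(msg, sprintf(
      "invalid scheme: dkzDky = %d/%d does not give an integer kz blip per acquired line (ry = %d)",
      object@dkzDkyNum, object@dkzDkyDen, object@ry))
  if (length(msg) == 0L) {
    ## one-shot samples must form a lattice (cyclic subgroup) so that the
    ## alias pattern is a clean coset structure
    b <- blip %/% object@dkzDkyDen
    nS <- object@nKy %/% object@ry
    if ((nS * b) %% object@nKz != 0L)
      msg <- c(msg, sprintf(
        "invalid scheme: kz blip %d does not close the sampling lattice over %d shots-per-volume lines (nKz = %d)",
        b, nS, object@nKz))
  }
  if (length(msg)) msg else TRUE
})

#' Boolean k-space sampling mask
#'
#' Occupancy of the `(ky, kz, t)` lattice generated from a
#' [SamplingScheme]. For constant-shift schemes the mask at time `t` equals
#' the mask at time 0 circularly shifted by `(t * dkyDt, t * dkzDt)`.
#'
#' @slot occupancy logical array of dimension `(nKy, nKz, nT)`.
#' @slot scheme the generating [SamplingScheme].
#' @exportClass SamplingMask
setClass("SamplingMask",
         representation(occupancy = "array", scheme = "SamplingScheme"))

setValidity("SamplingMask", function(object) {
  d <- dim(object@occupancy)
  s <- object@scheme
  if (length(d) != 3L) return("occupancy must be a 3D (ky, kz, t) array")
  if (!is.logical(object@occupancy)) return("occupancy must be logical")
  if (!all(d == c(s@nKy, s@nKz, s@nT)))
    return("occupancy dimensions disagree with scheme")
  perShot <- colSums(matrix(object@occupancy, d[1] * d[2], d[3]))
  if (length(unique(perShot)) != 1L)
    return("per-shot sample count is not constant across time")
  TRUE
})

#' Coil sensitivity maps
#'
#' Complex coil sensitivity profiles on the image grid, assumed noise
#' whitened (unit-variance independent complex Gaussian noise per channel).
#' Sensitivities are identically zero outside the support mask.
#'
#' @slot values complex array `(Nx, Ny, Nz, nCoil)`.
#' @slot support logical array `(Nx, Ny, Nz)`.
#' @exportClass CoilSensitivities
setClass("CoilSensitivities",
         representation(values = "array", support = "array"))

setValidity("CoilSensitivities", function(object) {
  dv <- dim(object@values); ds <- dim(object@support)
  if (length(dv) != 4L) return("values must be a 4D (x, y, z, coil) array")
  if (!is.complex(object@values)) return("values must be complex")
  if (length(ds) != 3L || !all(ds == dv[1:3]))
    return("support must be a 3D array matching the spatial grid")
  if (any(object@values[!as.vector(object@support)] != 0))
    return("sensitivities must be zero outside the support mask")
  TRUE
})

#' SENSE encoding operator
#'
#' The forward model `A`, block diagonal across time: at time `t` it applies
#' point-wise coil sensitivity weighting followed by the under-sampled
#' unitary Fourier transform on the `(y, z)` plane. The readout direction x
#' is fully sampled and kept in the image domain (hybrid space), so every
#' x-position decouples.
#'
#' @slot sens a [CoilSensitivities] object.
#' @slot mask a [SamplingMask] object.
#' @exportClass EncodingOperator
setClass("EncodingOperator",
         representation(sens = "CoilSensitivities", mask = "SamplingMask"))

setValidity("EncodingOperator", function(object) {
  dv <- dim(object@sens@values)
  s <- object@mask@scheme
  if (dv[2] != s@nKy || dv[3] != s@nKz)
    return("sensitivity (y, z) grid must match the (nKy, nKz) lattice")
  TRUE
})

#' Alias group
#'
#' The time-invariant set of voxels at one readout position that fold onto
#' each other under the sampling lattice. All direct computations (exact
#' solves, smoothing operators, g-factors) are performed independently per
#' alias group. `members` holds 0-based `(y, z)` indices; `theta` holds the
#' per-member temporal phase increment induced by the shot-to-shot k-space
#' shift, so the member phase schedule is `exp(1i * theta * t)`.
#'
#' @slot x integer, 1-based readout index of this group.
#' @slot members integer matrix (G x 2) of 0-based (y, z) indices.
#' @slot V complex matrix (G x nCoil) of member sensitivities.
#' @slot theta numeric length-G phase increments per shot.
#' @slot s numeric, sampling density (samples per shot / lattice size).
#' @slot nT integer, number of time points.
#' @exportClass AliasGroup
setClass("AliasGroup",
         representation(x = "integer", members = "matrix", V = "matrix",
                        theta = "numeric", s = "numeric", nT = "integer"))

#' Equivalent temporal smoothing operator
#'
#' Dense representation, for one alias group, of the operator
#' `S = (A'A + lambda D'D)^{-1} (A'A)` that maps the unregularized
#' (pseudoinverse) reconstruction to the regularized one. Stored in
#' time-major ordering: row/column `(t - 1) * G + m` addresses voxel `m` at
#' time `t`. Alongside the matrix itself the constructor caches the
#' quantities needed by the noise statistics: the per-(voxel, time) variance
#' diagonal `diag(S (A'A)^{-1} S')`, the diagonal of `A'A`, and the
#' unregularized g-factor of each member.
#'
#' The same class represents the encoding-independent post-hoc smoother
#' `(I + kappa D'D)^{-1}` (`kind = "posthoc"`, group size 1), in which case
#' the cached variance diagonal is `diag(S S')` and the reference g-factor
#' is 1, so that all downstream statistics flow through one code path.
#'
#' @slot S complex (or numeric, post-hoc) matrix of size `(G * nT)^2`.
#' @slot nT integer.
#' @slot groupSize integer G.
#' @slot lambda numeric regularization weight (or kappa for post-hoc).
#' @slot members 0-based member index matrix, or NULL for post-hoc.
#' @slot varDiag numeric length `G * nT`, estimator variance diagonal.
#' @slot ataDiag numeric length G, diagonal of `A'A` per member.
#' @slot g0 numeric length G, unregularized g-factor per member.
#' @slot kind character, `"encoding"` or `"posthoc"`.
#' @exportClass SmoothingOperator
setClass("SmoothingOperator",
         representation(S = "matrix", nT = "integer", groupSize = "integer",
                        lambda = "numeric", members = "matrixOrNULL",
                        varDiag = "numeric", ataDiag = "numeric",
                        g0 = "numeric", kind = "character"))

#' Reconstruction result
#'
#' A reconstructed complex image time-series together with a convergence
#' record.
#'
#' @slot image complex array `(Nx, Ny, Nz, Nt)`.
#' @slot lambda numeric regularization weight used.
#' @slot solver character, `"cg"` or `"direct"`.
#' @slot iterations integer, CG iterations used (0 for direct).
#' @slot residual numeric, final relative normal-equation residual.
#' @slot converged logical.
#' @exportClass ReconResult
setClass("ReconResult",
         representation(image = "array", lambda = "numeric",
                        solver = "character", iterations = "integer",
                        residual = "numeric", converged = "logical"))

#' Voxel-wise efficiency report
#'
#' Maps of the analytic reconstruction quality metrics on the image grid:
#' unregularized and regularized g-factors (RMS across time), normalized
#' effective degrees of freedom, and exact / asymptotic GLM efficiency.
#' Voxels outside the coil support are NA.
#'
#' @slot g0,gLam,dof,eLam,eAsym numeric arrays `(Nx, Ny, Nz)`.
#' @slot lambda numeric.
#' @slot nT integer.
#' @slot design the design matrix used for the exact efficiency, or NULL.
#' @exportClass EfficiencyReport
setClass("EfficiencyReport",
         representation(g0 = "array", gLam = "array", dof = "array",
                        eLam = "array", eAsym = "array", lambda = "numeric",
                        nT = "integer", design = "matrixOrNULL"))
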