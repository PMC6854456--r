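#' @include AllClasses.R AllGenerics.R groups.R solver.R
NULL

#' Equivalent smoothing operator of an alias group
#'
#' Materializes the dense operator `S = (A'A + lambda D'D)^{-1} (A'A)`
#' restricted to one alias group, in time-major ordering. Applying `S`
#' after a conventional pseudoinverse reconstruction is exactly equivalent
#' to the one-shot regularized solve; `S` is spatially adaptive in that it
#' depends on the group's `A'A` (coil overlap, sampling density, phase
#' schedule).
#'
#' The constructor also caches the variance diagonal
#' `diag(S (A'A)^{-1} S')`, the `A'A` diagonal, and the unregularized
#' g-factor of each member, from which all noise statistics
#' ([gFactor()], [approxDof()], [glmEfficiencyExact()], ...) follow without
#' further factorizations.
#'
#' @param group an [AliasGroup].
#' @param lambda temporal regularization weight (>= 0). At `lambda = 0`,
#'   `S` is the identity (for an invertible group).
#' @param circulant logical: use the circulant temporal difference
#'   operator instead of the default open-boundary one. With the open
#'   boundary (fMRI series are not periodic) the regularized noise
#'   variance differs slightly at the first/last frames; the circulant
#'   variant restores exact temporal stationarity when the sampling
#'   pattern's shift period divides `nT`, at the cost of coupling the
#'   series ends. The circulant system is not block tridiagonal and is
#'   factorized densely.
#' @return a [SmoothingOperator].
#' @export
smoothingOperator <- function(group, lambda, circulant = FALSE) {
  stopifnot(is(group, "AliasGroup"), lambda >= 0)
  G <- nrow(group@members)
  nT <- group@nT
  n <- G * nT
  H <- groupH(group)
  Hinv <- tryCatch(solve(H), error = function(e)
    stop("singular coil-overlap matrix: the alias group cannot be ",
         "unaliased by this coil set", call. = FALSE))
  Phi <- groupPhases(group)
  ## dense A'A (block diagonal over time) in time-major ordering
  Bd <- matrix(0i, n, n)
  for (t in seq_len(nT)) {
    idx <- (t - 1L) * G + seq_len(G)
    Bd[idx, idx] <- group@s * (outer(Phi[, t], Conj(Phi[, t])) * H)
  }
  if (circulant) {
    M <- Bd + lambda * kronecker(tdiffPenalty(nT, circulant = TRUE),
                                 diag(1 + 0i, G))
    X <- tryCatch(solve(M, Bd), error = function(e)
      stop("singular alias-group system (lambda = ", lambda, ")",
           call. = FALSE))
  } else {
    fac <- groupFactor(group, lambda)
    X <- groupSolve(fac, Bd)               # S = M^{-1} (A'A)
  }
  ## variance diagonal: diag(S (A'A)^{-1} S') = rowSums((X B^{-1}) conj(X))
  Y <- X
  for (t in seq_len(nT)) {
    idx <- (t - 1L) * G + seq_len(G)
    Binv <- (outer(Phi[, t], Conj(Phi[, t])) * Hinv) / group@s
    Y[, idx] <- X[, idx, drop = FALSE] %*% Binv
  }
  varDiag <- Re(rowSums(Y * Conj(X)))
  g0 <- sqrt(pmax(Re(diag(H)) * Re(diag(Hinv)), 0))
  new("SmoothingOperator", S = X, nT = nT, groupSize = G,
      lambda = lambda, members = group@members, varDiag = varDiag,
      ataDiag = group@s * Re(diag(H)), g0 = g0, kind = "encoding")
}

#' Encoding-independent post-hoc temporal smoother
#'
#' The conventional comparator: the kernel smoother
#' `S = (I + kappa D'D)^{-1}`, identical for every voxel. Its rows sum to 1
#' (constants are preserved). Returned as a [SmoothingOperator] with group
#' size 1, unit `A'A` diagonal and unit reference g-factor, so the same
#' statistics code applies: its g-factor is `sqrt(diag(S S'))` relative to
#' the unsmoothed series, and its effective DOF is encoding-independent.
#'
#' @param kappa smoothing weight (>= 0); `kappa = 0` gives the identity.
#' @param nT number of time points.
#' @param circulant boundary convention for the difference operator.
#' @return a [SmoothingOperator] of kind `"posthoc"`.
#' @export
posthocSmoother <- function(kappa, nT, circulant = FALSE) {
  stopifnot(kappa >= 0, nT >= 1)
  S <- solve(diag(nT) + kappa * tdiffPenalty(nT, circulant))
  new("SmoothingOperator", S = S, nT = as.integer(nT), groupSize = 1L,
      lambda = kappa, members = NULL, varDiag = rowSums(S^2),
      ataDiag = 1, g0 = 1, kind = "posthoc")
}

#' Match a post-hoc smoother to a target effective DOF
#'
#' Finds, by bisection, the kernel weight `kappa` whose post-hoc smoother
#' has a given approximate effective DOF `trm(S S')`. The DOF of
#' `(I + kappa D'D)^{-1}` decreases monotonically from `nT` (at
#' `kappa = 0`) towards 1 (the constant mode survives), so any target in
#' that range is attainable.
#'
#' @param targetDof target value of `trm(S S')`, in `[1, nT]`.
#' @param nT number of time points.
#' @param tol absolute DOF tolerance (default `1e-3 * nT`).
#' @param circulant boundary convention.
#' @return list with elements `kappa` and `dof` (achieved value).
#' @export
matchKappa <- function(targetDof, nT, tol = 1e-3 * nT, circulant = FALSE) {
  if (targetDof > nT || targetDof < 1)
    stop("target DOF ", targetDof, " outside the attainable range [1, ", nT, "]")
  L <- tdiffPenalty(nT, circulant)
  dofOf <- function(k) sum(solve(diag(nT) + k * L)^2)
  if (abs(targetDof - nT) <= tol) return(list(kappa = 0, dof = nT))
  hi <- 1
  while (dofOf(hi) > targetDof) {
    hi <- hi * 4
    if (hi > 1e12) stop("target DOF ", targetDof, " not attainable")
  }
  lo <- 0
  repeat {
    mid <- (lo + hi) / 2
    d <- dofOf(mid)
    if (abs(d - targetDof) <= tol) return(list(kappa = mid, dof = d))
    if (d > targetDof) lo <- mid else hi <- mid
    if (hi - lo < 1e-14 * max(1, hi))
      return(list(kappa = mid, dof = d))
  }
}

#' @rdname accessors
#' @export
setMethod("smoothingMatrix", "SmoothingOperator", function(object) object@S)

#' @rdname temporalBlock
#' @export
setMethod("temporalBlock", "SmoothingOperator", function(object, m = 1L) {
  stopifnot(m >= 1L, m <= object@groupSize)
  idx <- (0:(object@nT - 1L)) * object@groupSize + m
  object@S[idx, idx, drop = FALSE]
})

#' @rdname accessors
#' @export
setMethod("groupMembers", "SmoothingOperator", function(object) object@members)

setMethod("show", "SmoothingOperator", function(object) {
  if (object@kind == "posthoc")
    cat(sprintf("SmoothingOperator (post-hoc, kappa = %g, nT = %d)\n",
                object@lambda, object@nT))
  else
    cat(sprintf("SmoothingOperator (encoding-dependent, lambda = %g, G = %d, nT = %d)\n",
                object@lambda, object@groupSize, object@nT))
})
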