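#' @include AllClasses.R AllGenerics.R groups.R
NULL

## ---- temporal finite differences ----------------------------------------

#' Temporal finite-difference penalty matrix
#'
#' The Gram matrix `D'D` of the order-1 forward finite-difference operator
#' acting along time. The default (open) boundary uses the (nT-1) x nT
#' non-circulant difference matrix, so `D'D` is tridiagonal, symmetric
#' positive semidefinite, and annihilates constants; the circulant variant
#' wraps the last frame onto the first.
#'
#' @param nT number of time points.
#' @param circulant logical, wrap the boundary (default FALSE: fMRI series
#'   are not periodic).
#' @return an nT x nT matrix.
#' @export
tdiffPenalty <- function(nT, circulant = FALSE) {
  if (nT == 1L) return(matrix(0, 1, 1))
  L <- diag(2, nT)
  L[cbind(1:(nT - 1), 2:nT)] <- -1
  L[cbind(2:nT, 1:(nT - 1))] <- -1
  if (circulant) {
    L[1, nT] <- L[1, nT] - 1
    L[nT, 1] <- L[nT, 1] - 1
  } else {
    L[1, 1] <- 1
    L[nT, nT] <- 1
  }
  L
}

## D'D applied along dim 4 of a 4D array (open boundary unless circulant)
tLtL <- function(img, circulant = FALSE) {
  nT <- dim(img)[4]
  if (nT == 1L) return(array(0i, dim(img)))
  d <- img[, , , 2:nT, drop = FALSE] - img[, , , 1:(nT - 1), drop = FALSE]
  out <- array(0i, dim(img))
  out[, , , 1:(nT - 1)] <- -d
  out[, , , 2:nT] <- out[, , , 2:nT, drop = FALSE] + d
  if (circulant) {
    dw <- img[, , , 1, drop = FALSE] - img[, , , nT, drop = FALSE]
    out[, , , nT] <- out[, , , nT, drop = FALSE] - dw
    out[, , , 1] <- out[, , , 1, drop = FALSE] + dw
  }
  out
}

## ---- block-tridiagonal group system -------------------------------------

## The per-group normal system M = blockdiag_t(s phi_t H phi_t') +
## lambda (I_G (x) D'D) is, in time-major ordering, Hermitian block
## tridiagonal with G x G diagonal blocks and scalar off-diagonal blocks
## -lambda I. It is factorized by block LDL (Thomas) recursion in
## O(nT * G^3) and solved in O(nT * G^2) per right-hand side, instead of
## O((G nT)^3) for a dense factorization.
groupFactor <- function(group, lambda) {
  G <- nrow(group@members)
  nT <- group@nT
  H <- groupH(group)
  Phi <- groupPhases(group)
  cdiag <- if (nT == 1L) 0 else c(1, rep(2, max(nT - 2L, 0L)), 1)
  Dinv <- array(0i, c(G, G, nT))
  Ig <- diag(1 + 0i, G)
  prev <- NULL
  for (t in seq_len(nT)) {
    Bt <- group@s * (outer(Phi[, t], Conj(Phi[, t])) * H) +
      lambda * cdiag[t] * Ig
    if (!is.null(prev)) Bt <- Bt - lambda^2 * prev
    Di <- tryCatch(solve(Bt), error = function(e)
      stop("singular alias-group system (lambda = ", lambda,
           "): the coil set cannot unalias this group; increase lambda ",
           "or the number of coils", call. = FALSE))
    Dinv[, , t] <- Di
    prev <- Di
  }
  list(Dinv = Dinv, lambda = lambda, G = G, nT = nT)
}

## solve M z = r for a (G*nT) x m time-major right-hand side matrix
groupSolve <- function(fac, rhs) {
  G <- fac$G; nT <- fac$nT; lam <- fac$lambda
  rhs <- as.matrix(rhs)
  m <- ncol(rhs)
  r <- array(rhs, c(G, nT, m))
  w <- r
  if (nT > 1L && lam != 0) {
    for (t in 2:nT)
      w[, t, ] <- r[, t, ] + lam * (fac$Dinv[, , t - 1] %*% w[, t - 1, ])
  }
  z <- w
  z[, nT, ] <- fac$Dinv[, , nT] %*% w[, nT, ]
  if (nT > 1L) {
    if (lam != 0) {
      for (t in (nT - 1L):1L)
        z[, t, ] <- fac$Dinv[, , t] %*% (w[, t, ] + lam * z[, t + 1, ])
    } else {
      for (t in (nT - 1L):1L)
        z[, t, ] <- fac$Dinv[, , t] %*% w[, t, ]
    }
  }
  dim(z) <- c(G * nT, m)
  z
}

## apply the group's A'A (block diagonal over time) to a time-major
## (G*nT) x m matrix
groupAtA <- function(group, y) {
  G <- nrow(group@members); nT <- group@nT
  y <- as.matrix(y)
  m <- ncol(y)
  H <- groupH(group)
  Phi <- groupPhases(group)
  yy <- array(y, c(G, nT, m))
  out <- yy
  for (t in seq_len(nT))
    out[, t, ] <- group@s * (Phi[, t] * (H %*% (Conj(Phi[, t]) * yy[, t, ])))
  dim(out) <- c(G * nT, m)
  out
}

## linear (column-major) voxel indices of the group's members in a 4D/5D
## image array, as a (G, nT [, R]) index array
groupImageIndex <- function(group, dims) {
  G <- nrow(group@members)
  nvol <- prod(dims[1:3])
  vlin <- group@x + dims[1] * (group@members[, 1] +
                               dims[2] * group@members[, 2])
  idx <- outer(vlin, (0:(dims[4] - 1L)) * nvol, "+")
  if (length(dims) == 5L)
    idx <- outer(idx, (0:(dims[5] - 1L)) * nvol * dims[4], "+")
  ## flatten: a (G x ndim) matrix would otherwise be taken as coordinates
  as.vector(idx)
}

#' Apply the equivalent smoothing operator to an image time-series
#'
#' Computes `S x = (A'A + lambda D'D)^{-1} (A'A) x` exactly, alias group by
#' alias group. This equals the noise-free regularized reconstruction of
#' the encoded signal `x` (by linearity), and is the work-horse of the
#' leakage simulations. Voxels outside the coil support are passed through
#' as zero.
#'
#' @param groups list of [AliasGroup] (from [aliasGroups()]).
#' @param img complex array `(Nx, Ny, Nz, Nt)` or `(Nx, Ny, Nz, Nt, R)` for
#'   `R` stacked realizations (solved together against one factorization).
#' @param lambda temporal regularization weight (>= 0).
#' @return array like `img`.
#' @export
applySmoothing <- function(groups, img, lambda) {
  storage.mode(img) <- "complex"
  d <- dim(img)
  stopifnot(length(d) %in% c(4L, 5L))
  out <- array(0i, d)
  for (g in groups) {
    idx <- groupImageIndex(g, d)
    G <- nrow(g@members)
    R <- if (length(d) == 5L) d[5] else 1L
    xg <- matrix(img[idx], G * g@nT, R)
    fac <- groupFactor(g, lambda)
    z <- groupSolve(fac, groupAtA(g, xg))
    out[idx] <- z
  }
  out
}

#' Exact direct reconstruction by alias-group partitioning
#'
#' Solves `(A'A + lambda D'D) x = A'k` exactly via independent Hermitian
#' block-tridiagonal factorizations, one per alias group. Requires a
#' constant-shift sampling scheme; it is the oracle against which the CG
#' solver is verified.
#'
#' @param encoding an [EncodingOperator].
#' @param ksp complex k-space array `(Nx, nKy, nKz, nCoil, nT)`.
#' @param lambda temporal regularization weight (>= 0).
#' @param groups optionally, precomputed [aliasGroups()] output.
#' @param sizeCap maximum `G * nT` for a direct factorization; larger
#'   groups indicate the CG path should be used.
#' @return a [ReconResult].
#' @export
solveDirect <- function(encoding, ksp, lambda, groups = NULL,
                        sizeCap = 8192L) {
  stopifnot(is(encoding, "EncodingOperator"), lambda >= 0)
  if (is.null(groups))
    groups <- aliasGroups(encoding@mask, encoding@sens)
  gs <- vapply(groups, function(g) nrow(g@members) * g@nT, 0)
  if (any(gs > sizeCap))
    stop("alias-group system size ", max(gs), " exceeds the direct-solve ",
         "cap (", sizeCap, "); use solveCG()")
  atk <- adjointOp(encoding, ksp)
  d <- dim(atk)
  out <- array(0i, d)
  for (g in groups) {
    idx <- groupImageIndex(g, d)
    fac <- groupFactor(g, lambda)
    out[idx] <- groupSolve(fac, matrix(atk[idx], ncol = 1L))
  }
  new("ReconResult", image = out, lambda = lambda, solver = "direct",
      iterations = 0L, residual = 0, converged = TRUE)
}

#' @rdname accessors
#' @export
setMethod("reconImage", "ReconResult", function(object) object@image)

setMethod("show", "ReconResult", function(object) {
  d <- dim(object@image)
  cat(sprintf("ReconResult (%s, lambda = %g): %d x %d x %d x %d\n",
              object@solver, object@lambda, d[1], d[2], d[3], d[4]))
  if (object@solver == "cg")
    cat(sprintf("  %d iterations, relative residual %.3g (%s)\n",
                object@iterations, object@residual,
                if (object@converged) "converged" else "NOT converged"))
})
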