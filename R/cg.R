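#' @include AllClasses.R AllGenerics.R encoding.R solver.R
NULL

#' Reconstruction configuration
#'
#' Bundles the regularization weight with the conjugate-gradient stopping
#' rule. The defaults (relative tolerance `1e-4`, at most 200 iterations)
#' are the solver settings used throughout the analyses in this package.
#'
#' @param lambda temporal regularization weight (>= 0).
#' @param tol relative normal-equation residual tolerance.
#' @param maxiter iteration cap.
#' @param circulant logical, use a circulant temporal difference operator
#'   (default FALSE: open boundary, fMRI series are not periodic).
#' @return a list with class `"reconConfig"`.
#' @export
reconConfig <- function(lambda = 0, tol = 1e-4, maxiter = 200L,
                        circulant = FALSE) {
  stopifnot(lambda >= 0, tol > 0, maxiter >= 1)
  structure(list(lambda = lambda, tol = tol, maxiter = as.integer(maxiter),
                 circulant = circulant),
            class = "reconConfig")
}

#' Conjugate-gradient reconstruction
#'
#' Solves the temporally regularized normal equations
#' `(A'A + lambda D'D) x = A'k` by plain (unpreconditioned) conjugate
#' gradients with the composite operator applied matrix-free through FFTs.
#' Works for any sampling mask, including time-coupled (non-constant-shift)
#' schedules that the direct per-group solver cannot partition.
#'
#' @param encoding an [EncodingOperator].
#' @param ksp complex k-space array `(Nx, nKy, nKz, nCoil, nT)`.
#' @param config a [reconConfig()] (or a bare numeric lambda, in which case
#'   default tolerances are used).
#' @return a [ReconResult] carrying the convergence record. With
#'   `lambda = 0` and a singular normal operator the solver returns the
#'   iteration-capped partial result with `converged = FALSE` and a
#'   warning.
#' @export
solveCG <- function(encoding, ksp, config = reconConfig()) {
  stopifnot(is(encoding, "EncodingOperator"))
  if (is.numeric(config)) config <- reconConfig(lambda = config)
  lam <- config$lambda
  b <- adjointOp(encoding, ksp)
  cdot <- function(a, v) Re(sum(Conj(a) * v))
  applyM <- function(v) {
    out <- normalOp(encoding, v)
    if (lam > 0) out <- out + lam * tLtL(v, config$circulant)
    out
  }
  x <- array(0i, dim(b))
  r <- b
  p <- r
  rs <- cdot(r, r)
  bnorm <- sqrt(rs)
  if (bnorm == 0)
    return(new("ReconResult", image = x, lambda = lam, solver = "cg",
               iterations = 0L, residual = 0, converged = TRUE))
  it <- 0L
  relres <- 1
  while (it < config$maxiter) {
    Ap <- applyM(p)
    pAp <- cdot(p, Ap)
    if (!is.finite(pAp) || pAp <= 0) break   # singular / indefinite system
    alpha <- rs / pAp
    x <- x + alpha * p
    r <- r - alpha * Ap
    rsNew <- cdot(r, r)
    it <- it + 1L
    relres <- sqrt(rsNew) / bnorm
    if (relres <= config$tol) {
      rs <- rsNew
      break
    }
    p <- r + (rsNew / rs) * p
    rs <- rsNew
  }
  conv <- relres <= config$tol
  if (!conv)
    warning(sprintf(
      "CG did not reach tolerance %.1g in %d iterations (relative residual %.3g); partial result returned",
      config$tol, it, relres))
  new("ReconResult", image = x, lambda = lam, solver = "cg",
      iterations = it, residual = relres, converged = conv)
}
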