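#' @include AllClasses.R AllGenerics.R sampling.R
NULL

## ---- unitary FFT helpers -------------------------------------------------

## 1D unitary DFT along one dimension of an n-D array (C-level mvfft).
fftAlong <- function(a, dim, inverse = FALSE) {
  d <- dim(a)
  n <- d[dim]
  perm <- c(dim, seq_along(d)[-dim])
  m <- matrix(aperm(a, perm), nrow = n)
  m <- stats::mvfft(m, inverse = inverse) / sqrt(n)
  aperm(array(m, d[perm]), order(perm))
}

## unitary 2D DFT on the (y, z) plane: dims 2 and 3 of (x, y, z, ...) arrays
fftYZ <- function(a, inverse = FALSE) {
  fftAlong(fftAlong(a, 2L, inverse), 3L, inverse)
}

## ---- constructors --------------------------------------------------------

#' Construct coil sensitivity maps
#'
#' @param values complex array `(Nx, Ny, Nz, nCoil)`; entries outside
#'   `support` are zeroed.
#' @param support logical array `(Nx, Ny, Nz)`; defaults to the voxels where
#'   any coil is non-zero.
#' @return a [CoilSensitivities].
#' @export
CoilSensitivities <- function(values, support = NULL) {
  storage.mode(values) <- "complex"
  if (is.null(support))
    support <- apply(abs(values) > 0, 1:3, any)
  values[array(!support, dim(values))] <- 0 + 0i
  new("CoilSensitivities", values = values, support = support)
}

#' @rdname accessors
#' @export
setMethod("sensValues", "CoilSensitivities", function(object) object@values)

#' @rdname accessors
#' @export
setMethod("supportMask", "CoilSensitivities", function(object) object@support)

setMethod("show", "CoilSensitivities", function(object) {
  d <- dim(object@values)
  cat(sprintf("CoilSensitivities: %d coils on a %d x %d x %d grid (%d support voxels)\n",
              d[4], d[1], d[2], d[3], sum(object@support)))
})

#' Build the SENSE encoding operator
#'
#' Combines coil sensitivities with a time-varying sampling mask into the
#' block-diagonal-in-time forward model `A`: point-wise sensitivity
#' weighting followed by the under-sampled unitary Fourier transform on the
#' (y, z) plane. The readout direction is fully sampled and is kept in the
#' image domain throughout (hybrid space), so it never mixes voxels.
#'
#' @param sens a [CoilSensitivities].
#' @param mask a [SamplingMask].
#' @return an [EncodingOperator].
#' @export
makeEncoding <- function(sens, mask) {
  stopifnot(is(sens, "CoilSensitivities"), is(mask, "SamplingMask"))
  op <- new("EncodingOperator", sens = sens, mask = mask)
  validObject(op)
  op
}

setMethod("show", "EncodingOperator", function(object) {
  cat("EncodingOperator (SENSE, hybrid readout space)\n")
  show(object@sens)
  show(object@mask@scheme)
})

## ---- forward / adjoint ---------------------------------------------------

#' @rdname forwardOp
#' @export
setMethod("forwardOp", "EncodingOperator", function(object, img) {
  S <- object@sens@values
  d <- dim(S)                       # Nx Ny Nz C
  occ <- object@mask@occupancy
  scheme <- object@mask@scheme
  nT <- scheme@nT
  if (!is.array(img) || length(dim(img)) != 4L ||
      !all(dim(img)[1:3] == d[1:3]) || dim(img)[4] != nT)
    stop("image dimensions do not match the encoding operator")
  storage.mode(img) <- "complex"
  out <- array(0i, c(d[1], d[2], d[3], d[4], nT))
  for (t in seq_len(nT)) {
    w <- array(as.vector(img[, , , t]) * as.vector(S), d)  # recycle over coils
    k <- fftYZ(w)
    km <- matrix(k, d[1], d[2] * d[3] * d[4])
    km[, rep(!as.vector(occ[, , t]), d[4])] <- 0i
    out[, , , , t] <- km
  }
  out
})

#' @rdname adjointOp
#' @export
setMethod("adjointOp", "EncodingOperator", function(object, ksp) {
  S <- object@sens@values
  d <- dim(S)
  occ <- object@mask@occupancy
  nT <- object@mask@scheme@nT
  if (!is.array(ksp) || length(dim(ksp)) != 5L ||
      !all(dim(ksp) == c(d, nT)))
    stop("k-space dimensions do not match the encoding operator")
  out <- array(0i, c(d[1], d[2], d[3], nT))
  for (t in seq_len(nT)) {
    km <- matrix(ksp[, , , , t], d[1], d[2] * d[3] * d[4])
    km[, rep(!as.vector(occ[, , t]), d[4])] <- 0i
    w <- fftYZ(array(km, d), inverse = TRUE)
    out[, , , t] <- rowSums(array(as.vector(w) * Conj(as.vector(S)), c(prod(d[1:3]), d[4])))
  }
  out
})

## A'A applied to a full image time-series (used by the CG solver)
normalOp <- function(object, img) {
  S <- object@sens@values
  d <- dim(S)
  occ <- object@mask@occupancy
  nT <- object@mask@scheme@nT
  out <- array(0i, dim(img))
  for (t in seq_len(nT)) {
    w <- array(as.vector(img[, , , t]) * as.vector(S), d)
    k <- fftYZ(w)
    km <- matrix(k, d[1], d[2] * d[3] * d[4])
    km[, rep(!as.vector(occ[, , t]), d[4])] <- 0i
    w <- fftYZ(array(km, d), inverse = TRUE)
    out[, , , t] <- rowSums(array(as.vector(w) * Conj(as.vector(S)), c(prod(d[1:3]), d[4])))
  }
  out
}
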