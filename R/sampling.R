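#' @include AllClasses.R AllGenerics.R
NULL

#' Construct a CAIPI sampling scheme
#'
#' @param nKy number of phase-encode lines (image Ny).
#' @param nKz number of kz partitions, equal to the multiband factor MB
#'   (image Nz).
#' @param nT number of time points (shots per slice group).
#' @param ry in-plane acceleration factor (every `ry`-th ky line acquired).
#' @param dkzDky kz increment per unit ky within a shot; a numeric scalar or
#'   a string `"p/q"` for rational values (e.g. `"3/2"` for an MB8R2-style
#'   blip pattern). `ry * dkzDky` must be an integer, the kz blip per
#'   acquired line.
#' @param dkzDt kz shift of the whole pattern from shot to shot.
#' @param dkyDt ky shift of the pattern from shot to shot (requires
#'   `ry > 1` to be meaningful).
#'
#' @details
#' Conventional CAIPI sampling corresponds to `dkzDt = 0` (identical pattern
#' every shot). Non-zero `dkzDt` / `dkyDt` shift the pattern in k-space from
#' shot to shot; with constant shifts, the mask at time `t` is an exact
#' circular shift of the mask at time 0, the alias pattern is
#' time-invariant, and g-factors are constant across time.
#'
#' The one-shot samples must form a lattice (a cyclic subgroup of the
#' `(ky, kz)` torus); schemes whose blip schedule does not close into a
#' lattice are rejected, as are schemes with a non-integer number of samples
#' per shot.
#'
#' @return a [SamplingScheme].
#' @examples
#' SamplingScheme(nKy = 16, nKz = 8, nT = 32, ry = 2, dkzDky = "3/2",
#'                dkzDt = 3, dkyDt = 1)
#' @export
SamplingScheme <- function(nKy, nKz, nT, ry = 1L, dkzDky = 1L,
                           dkzDt = 0L, dkyDt = 0L) {
  r <- parseRational(dkzDky)
  new("SamplingScheme", nKy = as.integer(nKy), nKz = as.integer(nKz),
      nT = as.integer(nT), ry = as.integer(ry),
      dkzDkyNum = r[1], dkzDkyDen = r[2],
      dkzDt = as.integer(dkzDt), dkyDt = as.integer(dkyDt))
}

parseRational <- function(x) {
  if (is.character(x)) {
    parts <- strsplit(x, "/", fixed = TRUE)[[1]]
    if (length(parts) == 1L) parts <- c(parts, "1")
    p <- suppressWarnings(as.integer(parts))
    if (length(p) != 2L || anyNA(p)) stop("cannot parse rational '", x, "'")
    return(p)
  }
  x <- as.numeric(x)
  for (den in 1:64) {
    if (abs(x * den - round(x * den)) < 1e-9)
      return(c(as.integer(round(x * den)), as.integer(den)))
  }
  stop("cannot express dkzDky = ", x, " as a small rational")
}

## kz blip per acquired ky line (integer by validity)
kzBlip <- function(scheme) {
  (scheme@ry * scheme@dkzDkyNum) %/% scheme@dkzDkyDen
}

## number of samples per shot
samplesPerShot <- function(scheme) scheme@nKy %/% scheme@ry

#' One-shot sample coordinates
#'
#' 0-based `(ky, kz)` coordinates of the samples acquired in shot `t`.
#'
#' @param scheme a [SamplingScheme].
#' @param t 0-based shot index.
#' @return integer matrix with columns `ky`, `kz`.
#' @export
shotSamples <- function(scheme, t = 0L) {
  nS <- samplesPerShot(scheme)
  b <- kzBlip(scheme)
  m <- 0:(nS - 1L)
  cbind(ky = (m * scheme@ry + t * scheme@dkyDt) %% scheme@nKy,
        kz = (m * b + t * scheme@dkzDt) %% scheme@nKz)
}

#' Build the time-varying CAIPI sampling mask
#'
#' Generates the boolean occupancy lattice over `(ky, kz, t)` for a scheme.
#' Every shot acquires `nKy / ry` samples; for constant-shift schemes the
#' pattern at time `t` is the time-0 pattern circularly shifted by
#' `(t * dkyDt, t * dkzDt)`.
#'
#' @param scheme a [SamplingScheme].
#' @param shifts optional `nT x 2` integer matrix of explicit per-shot
#'   `(ky, kz)` pattern offsets, overriding the constant `dkyDt` / `dkzDt`
#'   schedule (e.g. a pseudorandom schedule). Masks built this way do not
#'   have time-invariant alias groups: the per-group direct machinery
#'   refuses them and the CG solver must be used.
#' @return a [SamplingMask].
#' @export
buildCaipiMask <- function(scheme, shifts = NULL) {
  stopifnot(is(scheme, "SamplingScheme"))
  validObject(scheme)
  occ <- array(FALSE, c(scheme@nKy, scheme@nKz, scheme@nT))
  s0 <- shotSamples(scheme, 0L)
  if (anyDuplicated(s0))
    stop("invalid scheme: one-shot samples are not distinct lattice points")
  if (is.null(shifts)) {
    shifts <- cbind(0:(scheme@nT - 1L) * scheme@dkyDt,
                    0:(scheme@nT - 1L) * scheme@dkzDt)
  } else {
    shifts <- as.matrix(shifts)
    if (nrow(shifts) != scheme@nT || ncol(shifts) != 2L)
      stop("shifts must be an nT x 2 integer matrix")
  }
  for (t in 0:(scheme@nT - 1L)) {
    st <- cbind((s0[, 1] + shifts[t + 1L, 1]) %% scheme@nKy,
                (s0[, 2] + shifts[t + 1L, 2]) %% scheme@nKz,
                t)
    occ[st + 1L] <- TRUE
  }
  new("SamplingMask", occupancy = occ, scheme = scheme)
}

#' @rdname accessors
#' @param object an object with the named component.
#' @export
setMethod("occupancy", "SamplingMask", function(object) object@occupancy)

#' @rdname accessors
#' @export
setMethod("schemeOf", "SamplingMask", function(object) object@scheme)

#' @rdname accessors
#' @export
setMethod("schemeOf", "EncodingOperator", function(object) object@mask@scheme)

setMethod("show", "SamplingScheme", function(object) {
  cat(sprintf("SamplingScheme: %d x %d (ky x kz), %d time-points\n",
              object@nKy, object@nKz, object@nT))
  cat(sprintf("  ry = %d, dkz/dky = %d/%d, dkz/dt = %d, dky/dt = %d\n",
              object@ry, object@dkzDkyNum, object@dkzDkyDen,
              object@dkzDt, object@dkyDt))
  cat(sprintf("  %d samples per shot (undersampling factor %g)\n",
              samplesPerShot(object),
              object@nKy * object@nKz / samplesPerShot(object)))
})

setMethod("show", "SamplingMask", function(object) {
  cat("SamplingMask over (ky, kz, t):\n")
  show(object@scheme)
})
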