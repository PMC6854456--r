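#' @include AllClasses.R AllGenerics.R sampling.R encoding.R
NULL

#' Alias offsets of a sampling lattice
#'
#' The set of image-domain `(dy, dz)` displacements onto which a voxel
#' folds under one shot's sampling lattice, i.e. the support of the point
#' spread function of the one-shot `(ky, kz)` sample set. For a lattice
#' generated by `(ry, b)` (with `b` the kz blip per acquired line) these are
#' exactly the displacements `d` with `ry*dy/nKy + b*dz/nKz` integer, and
#' there are `ry * nKz` of them.
#'
#' @param scheme a [SamplingScheme].
#' @return integer matrix with 0-based columns `dy`, `dz`.
#' @export
aliasOffsets <- function(scheme) {
  b <- kzBlip(scheme)
  g <- expand.grid(dy = 0:(scheme@nKy - 1L), dz = 0:(scheme@nKz - 1L))
  keep <- (scheme@ry * g$dy * scheme@nKz + b * g$dz * scheme@nKy) %%
    (scheme@nKy * scheme@nKz) == 0L
  as.matrix(g[keep, , drop = FALSE])
}

## coset label for every (y, z) voxel; 0-based input grid, returns an
## nKy x nKz integer matrix of coset ids (1..nCoset)
cosetLabels <- function(scheme) {
  off <- aliasOffsets(scheme)
  ny <- scheme@nKy; nz <- scheme@nKz
  lab <- matrix(0L, ny, nz)
  nxt <- 0L
  for (z in 0:(nz - 1L)) for (y in 0:(ny - 1L)) {
    if (lab[y + 1L, z + 1L] == 0L) {
      nxt <- nxt + 1L
      yy <- (y + off[, 1]) %% ny
      zz <- (z + off[, 2]) %% nz
      lab[cbind(yy + 1L, zz + 1L)] <- nxt
    }
  }
  lab
}

## check that the occupancy honours the constant-shift relation of its scheme
isConstantShift <- function(mask) {
  occ <- mask@occupancy
  s <- mask@scheme
  m0 <- matrix(occ[, , 1], s@nKy, s@nKz)
  for (t in seq_len(s@nT - 1L)) {
    iy <- ((0:(s@nKy - 1L) - t * s@dkyDt) %% s@nKy) + 1L
    iz <- ((0:(s@nKz - 1L) - t * s@dkzDt) %% s@nKz) + 1L
    if (!identical(as.vector(occ[, , t + 1L]),
                   as.vector(m0[iy, iz, drop = FALSE]))) return(FALSE)
  }
  TRUE
}

#' Decompose an encoding into alias groups
#'
#' Partitions the in-support voxels into alias groups: the sets of `(y, z)`
#' voxels at each readout position that fold onto each other under the
#' one-shot sampling lattice. For constant-shift schemes the membership is
#' time-invariant and the between-shot k-space shift only multiplies each
#' member by a unit phasor per time-point, which is what makes exact,
#' independent per-group computation possible.
#'
#' @param mask a [SamplingMask] whose occupancy satisfies the constant-shift
#'   relation of its scheme (masks built with per-shot shift overrides do
#'   not, and require the dense/iterative solver instead).
#' @param sens a [CoilSensitivities] on a grid matching the mask lattice.
#' @return a list of [AliasGroup] objects covering all in-support voxels.
#' @export
aliasGroups <- function(mask, sens) {
  stopifnot(is(mask, "SamplingMask"), is(sens, "CoilSensitivities"))
  scheme <- mask@scheme
  d <- dim(sens@values)
  if (d[2] != scheme@nKy || d[3] != scheme@nKz)
    stop("sensitivity grid does not match the sampling lattice")
  if (!isConstantShift(mask))
    stop("time-coupled sampling: the mask does not follow a constant shift ",
         "schedule, so alias groups are not time-invariant; use the ",
         "iterative (CG) solver on the full problem instead")
  lab <- cosetLabels(scheme)
  ncos <- max(lab)
  nS <- samplesPerShot(scheme)
  sdens <- nS / (scheme@nKy * scheme@nKz)
  ## member (y, z) lists per coset, 0-based
  memb <- vector("list", ncos)
  for (id in seq_len(ncos)) {
    w <- which(lab == id)
    memb[[id]] <- cbind(y = (w - 1L) %% scheme@nKy,
                        z = (w - 1L) %/% scheme@nKy)
  }
  groups <- vector("list", d[1] * ncos)
  ng <- 0L
  for (x in seq_len(d[1])) {
    supx <- matrix(sens@support[x, , ], d[2], d[3])
    for (id in seq_len(ncos)) {
      mm <- memb[[id]]
      keep <- supx[mm + 1L]
      if (!any(keep)) next
      mm <- mm[keep, , drop = FALSE]
      V <- matrix(sens@values[cbind(rep(x, nrow(mm) * d[4]),
                                    rep(mm[, 1] + 1L, d[4]),
                                    rep(mm[, 2] + 1L, d[4]),
                                    rep(seq_len(d[4]), each = nrow(mm)))],
                  nrow(mm), d[4])
      theta <- 2 * pi * (scheme@dkyDt * mm[, 1] / scheme@nKy +
                         scheme@dkzDt * mm[, 2] / scheme@nKz)
      ng <- ng + 1L
      groups[[ng]] <- new("AliasGroup", x = x, members = mm, V = V,
                          theta = theta, s = sdens, nT = scheme@nT)
    }
  }
  groups[seq_len(ng)]
}

#' @rdname accessors
#' @export
setMethod("groupMembers", "AliasGroup", function(object) object@members)

setMethod("show", "AliasGroup", function(object) {
  cat(sprintf("AliasGroup: %d voxels at x = %d, %d coils, %d time-points\n",
              nrow(object@members), object@x, ncol(object@V), object@nT))
})

## G x G Hermitian coil-overlap matrix H_ij = sum_c conj(S_c(i)) S_c(j)
groupH <- function(group) Conj(group@V) %*% t(group@V)

## G x nT phase schedule phi_i(t) = exp(1i * theta_i * t), t = 0..nT-1
groupPhases <- function(group, tIdx = NULL) {
  if (is.null(tIdx)) tIdx <- 0:(group@nT - 1L)
  exp(1i * outer(group@theta, tIdx))
}

#' @rdname ataBlocks
#' @export
setMethod("ataBlocks", "AliasGroup", function(object, t = NULL) {
  if (is.null(t)) t <- 0:(object@nT - 1L)
  H <- groupH(object)
  Phi <- groupPhases(object, t)
  lapply(seq_along(t), function(j)
    object@s * (outer(Phi[, j], Conj(Phi[, j])) * H))
})
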