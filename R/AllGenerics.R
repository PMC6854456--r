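#' @include AllClasses.R
NULL

#' Apply the forward encoding operator
#'
#' Maps a complex image time-series to multi-coil hybrid k-space data
#' (readout x kept in the image domain, unitary Fourier transform on the
#' (y, z) plane, restricted to the sampled locations of each shot).
#'
#' @param object an [EncodingOperator].
#' @param img complex array `(Nx, Ny, Nz, Nt)`.
#' @return complex array `(Nx, nKy, nKz, nCoil, nT)`, zero off-mask.
#' @export
setGeneric("forwardOp", function(object, img) standardGeneric("forwardOp"))

#' Apply the adjoint of the encoding operator
#'
#' @param object an [EncodingOperator].
#' @param ksp complex array `(Nx, nKy, nKz, nCoil, nT)`.
#' @return complex array `(Nx, Ny, Nz, Nt)`.
#' @export
setGeneric("adjointOp", function(object, ksp) standardGeneric("adjointOp"))

#' Per-time normal-operator blocks of an alias group
#'
#' Returns the G x G Hermitian blocks of `A'A` restricted to the group, one
#' per time-point (or for selected time-points).
#'
#' @param object an [AliasGroup].
#' @param t 0-based time indices (default all).
#' @return a list of G x G complex Hermitian matrices.
#' @export
setGeneric("ataBlocks", function(object, t = NULL) standardGeneric("ataBlocks"))

#' @rdname accessors
#' @export
setGeneric("occupancy", function(object) standardGeneric("occupancy"))

#' @rdname accessors
#' @export
setGeneric("schemeOf", function(object) standardGeneric("schemeOf"))

#' @rdname accessors
#' @export
setGeneric("sensValues", function(object) standardGeneric("sensValues"))

#' @rdname accessors
#' @export
setGeneric("supportMask", function(object) standardGeneric("supportMask"))

#' @rdname accessors
#' @export
setGeneric("groupMembers", function(object) standardGeneric("groupMembers"))

#' @rdname accessors
#' @export
setGeneric("smoothingMatrix", function(object) standardGeneric("smoothingMatrix"))

#' Temporal block of a smoothing operator
#'
#' The Nt x Nt sub-matrix of the smoothing operator coupling voxel `m` to
#' itself across time. This is the block used to form the smoothed design
#' matrix `SD` in the GLM efficiency computations.
#'
#' @param object a [SmoothingOperator].
#' @param m member index (1-based, within the group).
#' @return an Nt x Nt matrix.
#' @export
setGeneric("temporalBlock", function(object, m = 1L) standardGeneric("temporalBlock"))

#' @rdname accessors
#' @export
setGeneric("reconImage", function(object) standardGeneric("reconImage"))
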