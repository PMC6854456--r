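#' @include AllClasses.R AllGenerics.R sampling.R encoding.R synth.R
NULL

## serialized container layout (single-file RDS): a named list with a
## format tag, the k-space array, mask occupancy, sensitivities + support,
## and the scheme parameters as a flat attribute list
containerFormat <- "smstempo-dataset-v1"

schemeToList <- function(s) {
  list(nKy = s@nKy, nKz = s@nKz, nT = s@nT, ry = s@ry,
       dkzDky = sprintf("%d/%d", s@dkzDkyNum, s@dkzDkyDen),
       dkzDt = s@dkzDt, dkyDt = s@dkyDt)
}

schemeFromList <- function(l) {
  need <- c("nKy", "nKz", "nT", "ry", "dkzDky", "dkzDt", "dkyDt")
  miss <- setdiff(need, names(l))
  if (length(miss))
    stop("dataset schema error: missing scheme attribute(s) /scheme/",
         paste(miss, collapse = ", /scheme/"))
  SamplingScheme(l$nKy, l$nKz, l$nT, l$ry, l$dkzDky, l$dkzDt, l$dkyDt)
}

#' Write a dataset container
#'
#' Serializes k-space data, the sampling mask, coil sensitivities and the
#' scheme parameters into a single portable file (RDS serialization of a
#' tagged named list). The layout mirrors the in-memory objects:
#' `kspace` (complex, Nx x nKy x nKz x nCoil x nT), `mask` (logical,
#' nKy x nKz x nT), `sens` and `support`, and `scheme` (named parameter
#' list with `dkzDky` as a `"p/q"` string).
#'
#' @param path output file path.
#' @param ksp complex k-space array (may be NULL for mask/sensitivity-only
#'   containers).
#' @param sens a [CoilSensitivities].
#' @param mask a [SamplingMask].
#' @return the path, invisibly.
#' @export
writeDataset <- function(path, ksp, sens, mask) {
  stopifnot(is(sens, "CoilSensitivities"), is(mask, "SamplingMask"))
  if (!is.null(ksp)) {
    d <- dim(ksp)
    s <- mask@scheme
    if (length(d) != 5L || d[2] != s@nKy || d[3] != s@nKz ||
        d[4] != dim(sens@values)[4] || d[5] != s@nT)
      stop("k-space dimensions disagree with mask/sensitivities")
  }
  obj <- list(format = containerFormat, kspace = ksp,
              mask = mask@occupancy, sens = sens@values,
              support = sens@support, scheme = schemeToList(mask@scheme))
  saveRDS(obj, path)
  invisible(path)
}

#' Read a dataset container
#'
#' Validates and loads a container written by [writeDataset()]. Shape
#' consistency between the k-space data, mask and scheme is verified; a
#' mask that does not reproduce from its scheme parameters is reported as
#' a consistency error.
#'
#' @param path file path.
#' @return list with elements `kspace` (or NULL), `sens`
#'   ([CoilSensitivities]), `mask` ([SamplingMask]) and `scheme`.
#' @export
readDataset <- function(path) {
  obj <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read dataset container '", path, "': ", conditionMessage(e),
         call. = FALSE))
  if (!is.list(obj) || !identical(obj$format, containerFormat))
    stop("dataset schema error: '", path, "' is not a ", containerFormat,
         " container")
  for (el in c("mask", "sens", "support", "scheme"))
    if (is.null(obj[[el]]))
      stop("dataset schema error: missing element /", el)
  scheme <- schemeFromList(obj$scheme)
  if (!all(dim(obj$mask) == c(scheme@nKy, scheme@nKz, scheme@nT)))
    stop("dataset consistency error: mask dimensions disagree with /scheme")
  built <- buildCaipiMask(scheme)
  if (!identical(obj$mask, built@occupancy))
    stop("dataset consistency error: mask occupancy does not match the ",
         "scheme parameters")
  sens <- CoilSensitivities(obj$sens, obj$support)
  if (!is.null(obj$kspace)) {
    d <- dim(obj$kspace)
    if (length(d) != 5L || d[2] != scheme@nKy || d[3] != scheme@nKz ||
        d[4] != dim(sens@values)[4] || d[5] != scheme@nT)
      stop("dataset consistency error: k-space dimensions disagree")
  }
  list(kspace = obj$kspace, sens = sens, mask = built, scheme = scheme)
}

#' Export a reconstructed time-series as NIfTI
#'
#' Writes a 4D NIfTI-1 file with the time axis fourth and the voxel size
#' recorded in the header. The default 2 mm isotropic voxel matches a
#' typical whole-brain SMS-fMRI protocol.
#'
#' @param img numeric (magnitude/real) array `(Nx, Ny, Nz, Nt)`, or a
#'   complex array with `magnitude = TRUE`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param voxelSize numeric length-3 voxel edge lengths in mm.
#' @param tr repetition time in seconds stored in the time pixdim.
#' @param magnitude take the magnitude of complex input (an error is
#'   raised for complex input without this flag).
#' @return the path, invisibly.
#' @export
exportNifti <- function(img, path, voxelSize = c(2, 2, 2), tr = 1,
                        magnitude = FALSE) {
  stopifnot(is.array(img), length(dim(img)) == 4L, length(voxelSize) == 3L)
  if (is.complex(img)) {
    if (!magnitude)
      stop("complex image: NIfTI-1 export requires magnitude = TRUE")
    img <- Mod(img)
  }
  nii <- RNifti::asNifti(img)
  RNifti::pixdim(nii) <- c(voxelSize, tr)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Generate the canonical small fixture dataset
#'
#' A deterministic, fully synthetic dataset (MB = 4, 8 coils, 16 x 16 x 4
#' grid, 8 time points, CAIPI shift pattern) small enough for tests and
#' examples: phantom signal is encoded noise-free and complex Gaussian
#' noise added at the stated level.
#'
#' @param path output container path.
#' @param seed integer seed.
#' @param sigma k-space noise standard deviation.
#' @return the path, invisibly.
#' @export
makeFixtureDataset <- function(path, seed = 1L, sigma = 0.02) {
  scheme <- SamplingScheme(nKy = 16, nKz = 4, nT = 8, ry = 1,
                           dkzDky = 1, dkzDt = 1)
  mask <- buildCaipiMask(scheme)
  sens <- synthSensitivities(8, c(16, 16, 4), seed = seed)
  enc <- makeEncoding(sens, mask)
  base <- array(0i, c(16, 16, 4, 8))
  base[] <- rep(as.complex(sens@support), 8)
  ksp <- forwardOp(enc, base)
  ksp <- addNoise(ksp, mask, sigma, seed = seed + 1L)
  writeDataset(path, ksp, sens, mask)
}
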