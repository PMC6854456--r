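#' @include AllClasses.R AllGenerics.R encoding.R
NULL

## run expr with a fixed RNG seed, restoring the caller's RNG state
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

#' Cylindrical phantom support
#'
#' A disc in the (x, y) plane extended along z (the slice direction),
#' emulating the cylindrical phantom geometry used for simulation studies.
#'
#' @param dims integer vector `(Nx, Ny, Nz)`.
#' @param radiusFrac disc radius as a fraction of `min(Nx, Ny)`.
#' @return logical array `(Nx, Ny, Nz)`.
#' @export
cylinderSupport <- function(dims, radiusFrac = 0.45) {
  cx <- (dims[1] + 1) / 2
  cy <- (dims[2] + 1) / 2
  r2 <- (radiusFrac * min(dims[1], dims[2]))^2
  disc <- outer((seq_len(dims[1]) - cx)^2, (seq_len(dims[2]) - cy)^2, "+") <= r2
  array(disc, dims)
}

#' Synthetic coil sensitivity maps
#'
#' Smooth complex-valued coil profiles standing in for measured (and
#' compressed) array-coil sensitivities: coil centres are arranged in rings
#' around the support perimeter at several z levels, each with a
#' Gaussian-lobed magnitude and a slowly varying linear phase; positions
#' and phase gradients receive small seeded jitter so different seeds give
#' different (but statistically alike) coil sets. The maps are normalized
#' so the sum-of-squares sensitivity is 1 at every support voxel and are
#' identically zero outside the support.
#'
#' @param nCoils number of channels; at least the total fold-over factor
#'   (MB times in-plane acceleration) is needed for typical alias groups to
#'   be invertible.
#' @param dims image grid `(Nx, Ny, Nz)`.
#' @param seed integer seed; the maps are deterministic given
#'   `(seed, nCoils, dims)`.
#' @param support logical array; defaults to [cylinderSupport()].
#' @param nRings number of z-rings of coil centres (default spreads the
#'   coils over two rings, head-coil style).
#' @return a [CoilSensitivities].
#' @export
synthSensitivities <- function(nCoils, dims, seed = 1L, support = NULL,
                               nRings = NULL) {
  stopifnot(length(dims) == 3L, nCoils >= 1)
  if (nCoils < 2)
    warning("fewer than 2 coils: aliased voxels cannot be unaliased ",
            "(singular normal operator at lambda = 0)")
  if (is.null(support)) support <- cylinderSupport(dims)
  if (is.null(nRings)) nRings <- max(1L, min(4L, round(nCoils / 8)))
  perRing <- ceiling(nCoils / nRings)
  withSeed(seed, {
    vals <- array(0i, c(dims, nCoils))
    R <- 0.62 * min(dims[1], dims[2])
    cx <- (dims[1] + 1) / 2; cy <- (dims[2] + 1) / 2
    sigXY <- 0.45 * min(dims[1], dims[2])
    sigZ <- max(1.0, 0.85 * dims[3] / nRings)
    xg <- seq_len(dims[1]); yg <- seq_len(dims[2]); zg <- seq_len(dims[3])
    for (k in seq_len(nCoils)) {
      ring <- ((k - 1L) %/% perRing)
      ang <- 2 * pi * ((k - 1L) %% perRing) / perRing +
        pi * ring / perRing + stats::rnorm(1, 0, 0.05)
      zc <- (ring + 0.5) * dims[3] / nRings + stats::rnorm(1, 0, 0.15)
      px <- cx + R * cos(ang)
      py <- cy + R * sin(ang)
      mag <- exp(-(outer((xg - px)^2, (yg - py)^2, "+")) / (2 * sigXY^2))
      magz <- exp(-(zg - zc)^2 / (2 * sigZ^2))
      ## linear phase: plane wave pointing from the coil towards the centre
      kx <- (cx - px) / dims[1] * (1 + stats::rnorm(1, 0, 0.1))
      ky <- (cy - py) / dims[2] * (1 + stats::rnorm(1, 0, 0.1))
      kz <- stats::rnorm(1, 0, 0.3) / max(dims[3], 2)
      ph0 <- stats::runif(1, 0, 2 * pi)
      phxy <- outer(kx * xg, ky * yg, "+")
      for (z in zg)
        vals[, , z, k] <- (mag * magz[z]) *
          exp(1i * (2 * pi * (phxy + kz * z) + ph0))
    }
    sos <- sqrt(apply(Mod(vals)^2, 1:3, sum))
    sos[sos == 0] <- 1
    vals <- vals / array(sos, dim(vals))
    vals[array(!support, dim(vals))] <- 0i
    CoilSensitivities(vals, support)
  })
}

#' 1/f BOLD-like signal model
#'
#' Real-valued time-courses whose power spectrum decays as `1/f` over the
#' non-zero frequencies (random spectral phases, Hermitian-symmetrized),
#' the standard low-frequency model for resting BOLD fluctuations. The DC
#' component is excluded from the power law (baselines are modelled
#' separately); each series is standardized to zero mean and unit standard
#' deviation.
#'
#' @param n number of independent series.
#' @param nT series length.
#' @param seed integer seed (bitwise-reproducible output).
#' @return numeric matrix `n x nT`.
#' @export
oneOverFSignal <- function(n, nT, seed = 1L) {
  stopifnot(n >= 1, nT >= 4)
  withSeed(seed, {
    m <- (nT - 1L) %/% 2L
    co <- matrix(0i, n, nT)
    f <- (1:m) / nT
    amp <- matrix(stats::rnorm(n * m), n) + 1i * matrix(stats::rnorm(n * m), n)
    co[, 2:(m + 1L)] <- amp * rep(1 / sqrt(f), each = n)
    co[, nT + 1L - (1:m)] <- Conj(co[, 2:(m + 1L)])
    if (nT %% 2L == 0L)
      co[, nT / 2L + 1L] <- stats::rnorm(n) / sqrt((nT / 2) / nT)
    x <- Re(t(apply(co, 1, function(r) stats::fft(r, inverse = TRUE)))) / nT
    x <- x - rowMeans(x)
    x / sqrt(rowSums(x^2) / (nT - 1))
  })
}

#' GLM task regressors
#'
#' The three test regressors used to probe design-dependence of the
#' efficiency metrics: a 5-period block design, a fast event-related
#' design (randomized short events convolved with a canonical double-gamma
#' haemodynamic response), and a white-noise regressor. All are
#' standardized to zero mean and unit Euclidean norm.
#'
#' @param kind `"block"`, `"event"` or `"noise"`.
#' @param nT number of time points (>= 10).
#' @param seed integer seed (used by the stochastic kinds).
#' @return an `nT x 1` design matrix.
#' @export
makeRegressor <- function(kind = c("block", "event", "noise"), nT,
                          seed = 1L) {
  kind <- match.arg(kind)
  stopifnot(nT >= 10)
  x <- switch(kind,
    block = as.numeric((floor(10 * (0:(nT - 1)) / nT)) %% 2L),
    event = withSeed(seed, {
      ev <- as.numeric(stats::runif(nT) < 0.12)
      h <- stats::dgamma(0:24, shape = 6) - stats::dgamma(0:24, shape = 16) / 6
      stats::convolve(ev, rev(h), type = "open")[seq_len(nT)]
    }),
    noise = withSeed(seed, stats::rnorm(nT)))
  x <- x - mean(x)
  nrm <- sqrt(sum(x^2))
  if (nrm == 0) stop("degenerate regressor")
  matrix(x / nrm, nT, 1, dimnames = list(NULL, kind))
}

#' Add complex Gaussian measurement noise to k-space data
#'
#' i.i.d. circular complex Gaussian noise with total variance `sigma^2`
#' (split evenly between real and imaginary parts) is added at every
#' sampled location of every coil. Unsampled locations stay zero.
#'
#' @param ksp complex array `(Nx, nKy, nKz, nCoil, nT)`.
#' @param mask the [SamplingMask] describing the sampled locations.
#' @param sigma noise standard deviation (>= 0).
#' @param seed integer seed.
#' @return array like `ksp`.
#' @export
addNoise <- function(ksp, mask, sigma, seed = 1L) {
  stopifnot(sigma >= 0)
  if (sigma == 0) return(ksp)
  d <- dim(ksp)
  occ <- mask@occupancy
  withSeed(seed, {
    for (t in seq_len(d[5])) {
      w <- which(rep(as.vector(occ[, , t]), d[4]))
      nn <- length(w) * d[1]
      slab <- matrix(ksp[, , , , t], d[1], prod(d[2:4]))
      slab[, w] <- slab[, w] +
        (sigma / sqrt(2)) * (stats::rnorm(nn) + 1i * stats::rnorm(nn))
      ksp[, , , , t] <- slab
    }
    ksp
  })
}
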