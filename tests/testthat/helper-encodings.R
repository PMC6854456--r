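## shared builders for small synthetic encodings

smallEncoding <- function(nKy = 16, nKz = 4, nT = 8, ry = 1, dkzDky = 1,
                          dkzDt = 1, dkyDt = 0, nx = 4, nCoils = 6,
                          seed = 1, support = NULL) {
  scheme <- SamplingScheme(nKy, nKz, nT, ry, dkzDky, dkzDt, dkyDt)
  mask <- buildCaipiMask(scheme)
  if (is.null(support)) support <- array(TRUE, c(nx, nKy, nKz))
  sens <- synthSensitivities(nCoils, c(nx, nKy, nKz), seed = seed,
                             support = support)
  enc <- makeEncoding(sens, mask)
  list(scheme = scheme, mask = mask, sens = sens, enc = enc,
       groups = aliasGroups(mask, sens))
}

## an encoding in which every in-support voxel is a singleton alias group:
## support restricted to one slice, so all kz fold-over partners fall
## outside the coil support
singletonEncoding <- function(nKy = 16, nKz = 8, nT = 16, nx = 4,
                              nCoils = 16, slice = 5, seed = 1) {
  sup <- array(FALSE, c(nx, nKy, nKz))
  sup[, , slice] <- TRUE
  smallEncoding(nKy = nKy, nKz = nKz, nT = nT, ry = 1, dkzDky = 3,
                dkzDt = 2, nx = nx, nCoils = nCoils, seed = seed,
                support = sup)
}

randImage <- function(dims, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  array(complex(real = rnorm(prod(dims)), imaginary = rnorm(prod(dims))),
        dims)
}

randKspace <- function(enc, seed = NULL) {
  d <- c(dim(sensValues(enc@sens)), enc@mask@scheme@nT)
  k <- randImage(d, seed)
  ## zero the unsampled locations so the data are mask-consistent
  occ <- occupancy(enc@mask)
  for (t in seq_len(d[5])) {
    km <- matrix(k[, , , , t], d[1], prod(d[2:4]))
    km[, rep(!as.vector(occ[, , t]), d[4])] <- 0i
    k[, , , , t] <- km
  }
  k
}

## dense whole-problem solve of (A'A + lambda D'D) x = A'k, assembled
## column by column from the matrix-free operators; brute-force oracle for
## the structured solvers (small problems only)
denseNormalSolve <- function(enc, ksp, lambda) {
  d <- dim(sensValues(enc@sens))
  nT <- enc@mask@scheme@nT
  nv <- d[2] * d[3]
  atk <- adjointOp(enc, ksp)
  out <- array(0i, c(d[1:3], nT))
  for (xi in seq_len(d[1])) {
    n <- nv * nT
    M <- matrix(0i, n, n)
    for (j in seq_len(n)) {
      e <- array(0i, c(d[1:3], nT))
      vox <- (j - 1) %% nv
      tt <- (j - 1) %/% nv
      e[xi + d[1] * vox + d[1] * nv * tt] <- 1
      Me <- smstempo:::normalOp(enc, e) + lambda * smstempo:::tLtL(e)
      M[, j] <- matrix(Me, d[1], n)[xi, ]
    }
    b <- matrix(atk, d[1], n)[xi, ]
    out[xi, , , ] <- array(solve(M, b), c(d[2], d[3], nT))
  }
  out
}

relErr <- function(a, b) {
  max(Mod(a - b)) / max(Mod(b))
}
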