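#' @include AllClasses.R AllGenerics.R stats.R synth.R
NULL

## draw the group-projected adjoint of pure k-space noise: a (G*nT) x m
## time-major matrix with the exact covariance A'A of the group (unit
## complex noise variance per sampled k-space location and coil)
drawNoiseRhs <- function(group, m) {
  G <- nrow(group@members)
  nT <- group@nT
  nc <- ncol(group@V)
  zeta <- (matrix(stats::rnorm(nc * nT * m), nc) +
           1i * matrix(stats::rnorm(nc * nT * m), nc)) / sqrt(2)
  w <- Conj(group@V) %*% zeta               # G x (nT*m), Cov = H per column
  Phi <- groupPhases(group)                 # G x nT
  w <- array(w, c(G, nT, m)) * as.vector(Phi)  # recycles over realizations
  dim(w) <- c(G * nT, m)
  sqrt(group@s) * w
}

#' Monte-Carlo noise simulation
#'
#' Propagates pure complex Gaussian k-space noise through the regularized
#' reconstruction, alias group by alias group, and compares the empirical
#' noise statistics with the analytic expressions: per-voxel RMS g-factor,
#' approximate effective DOF (via white image-domain noise pushed through
#' the smoothing operator), and the asymptotic relative efficiency formed
#' from both. For a few representative voxels (spanning the g0 range) it
#' also records mean noise periodograms of the regularized reconstruction,
#' of the unregularized reconstruction, and of DOF-matched post-hoc
#' smoothing applied to the unregularized reconstruction, together with
#' their total noise powers.
#'
#' @param sens a [CoilSensitivities].
#' @param mask a [SamplingMask] (constant-shift scheme).
#' @param lambda temporal regularization weight.
#' @param nReal number of noise realizations (the full-scale study uses
#'   1000; 200 is a practical reduced-scale default).
#' @param seed integer seed.
#' @param design optional nT x 1 design matrix: adds exact-efficiency maps.
#' @param groups optional precomputed [aliasGroups()].
#' @param spectra logical, record per-voxel noise spectra.
#' @return a list with components `analytic` and `empirical` (each holding
#'   `gLam`, `dof`, `eAsym` maps, plus `g0` and exact efficiency under
#'   `analytic`), `spectra` (per representative voxel), and the run
#'   parameters.
#' @export
runSim1 <- function(sens, mask, lambda, nReal = 200L, seed = 1L,
                    design = NULL, groups = NULL, spectra = TRUE) {
  if (is.null(groups)) groups <- aliasGroups(mask, sens)
  d <- dim(sens@values)[1:3]
  nT <- mask@scheme@nT
  blank <- array(NA_real_, d)
  an <- list(g0 = blank, gLam = blank, dof = blank, eAsym = blank,
             eLam = blank)
  em <- list(gLam = blank, dof = blank, eAsym = blank)
  ## pick spectra voxels from the cheap unregularized g-factor map
  specSel <- NULL
  if (spectra) {
    g0all <- lapply(groups, function(g) {
      H <- groupH(g)
      sqrt(pmax(Re(diag(H)) * Re(diag(solve(H))), 0))
    })
    flat <- unlist(g0all)
    gidx <- rep(seq_along(groups), vapply(g0all, length, 0L))
    midx <- unlist(lapply(g0all, seq_along))
    pick <- unique(c(which.max(flat),
                     which.min(abs(flat - stats::median(flat))),
                     which.min(flat)))
    specSel <- data.frame(group = gidx[pick], member = midx[pick],
                          g0 = flat[pick])
  }
  specOut <- list()
  withSeed(seed, {
    for (gi in seq_along(groups)) {
      g <- groups[[gi]]
      G <- nrow(g@members)
      ii <- cbind(g@x, g@members[, 1] + 1L, g@members[, 2] + 1L)
      S <- smoothingOperator(g, lambda)
      an$g0[ii] <- g0Factor(S)
      an$gLam[ii] <- gFactorRMS(S)
      an$dof[ii] <- approxDof(S)
      an$eAsym[ii] <- glmEfficiencyAsymptotic(S)
      if (!is.null(design)) an$eLam[ii] <- glmEfficiencyExact(S, design)
      fac <- groupFactor(g, lambda)
      ## empirical g: k-space noise -> A'n -> solve
      rhs <- drawNoiseRhs(g, nReal)
      xh <- groupSolve(fac, rhs)
      vh <- rowMeans(Mod(xh)^2)                       # var per (m, t)
      gEmp2 <- matrix(vh, G, nT) * S@ataDiag
      em$gLam[ii] <- sqrt(rowMeans(gEmp2))
      ## empirical DOF: white image-time noise through S = M^{-1} A'A
      wht <- (matrix(stats::rnorm(G * nT * nReal), G * nT) +
              1i * matrix(stats::rnorm(G * nT * nReal), G * nT)) / sqrt(2)
      yh <- groupSolve(fac, groupAtA(g, wht))
      em$dof[ii] <- rowSums(matrix(rowMeans(Mod(yh)^2), G, nT))
      em$eAsym[ii] <- (g0Factor(S) / em$gLam[ii])^2 * em$dof[ii] / nT
      ## spectra for selected voxels in this group
      if (!is.null(specSel) && gi %in% specSel$group) {
        fac0 <- groupFactor(g, 0)
        x0 <- groupSolve(fac0, rhs)
        for (r in which(specSel$group == gi)) {
          m <- specSel$member[r]
          idx <- (0:(nT - 1L)) * G + m
          ts <- xh[idx, , drop = FALSE]               # nT x nReal
          ts0 <- x0[idx, , drop = FALSE]
          kap <- matchKappa(approxDof(S, m), nT)
          Sk <- posthocSmoother(kap$kappa, nT)
          tsp <- Sk@S %*% ts0
          pgram <- function(z) rowMeans(Mod(stats::mvfft(z))^2) / nT
          specOut[[length(specOut) + 1L]] <- list(
            voxel = c(x = g@x, y = g@members[m, 1], z = g@members[m, 2]),
            g0 = specSel$g0[r], kappa = kap$kappa, dofTarget = kap$dof,
            freq = (0:(nT - 1L)) / nT,
            specReg = pgram(ts), specUnreg = pgram(ts0),
            specPosthoc = pgram(tsp),
            powerReg = sum(colSums(Mod(ts)^2)) / nReal,
            powerPosthoc = sum(colSums(Mod(tsp)^2)) / nReal)
        }
      }
    }
  })
  list(analytic = an, empirical = em, spectra = specOut,
       lambda = lambda, nReal = nReal, nT = nT, seed = seed)
}

#' Noise-free slice-leakage simulation
#'
#' Reconstructs a noise-free dataset in which only one slice carries
#' signal, so that any signal appearing in the other slices must be
#' leakage. Each in-support voxel of the excited slice carries a baseline
#' plus a 1/f BOLD-like fluctuation; the simulation is repeated with fresh
#' random signals, and the per-voxel NRMSE across time (normalized to the
#' average RMS signal of the excited slice) is summarized by its 95th
#' percentile over the whole support and over the unexcited slices.
#'
#' @param sens a [CoilSensitivities].
#' @param mask a [SamplingMask].
#' @param lambdas regularization weights to evaluate.
#' @param nRepeats number of random-signal repeats.
#' @param seed integer seed.
#' @param excitedSlice 1-based z index of the slice carrying signal.
#' @param fluctSd standard deviation of the 1/f fluctuation relative to
#'   the baseline signal (default 0.05, a typical resting BOLD fluctuation
#'   amplitude).
#' @param groups optional precomputed [aliasGroups()].
#' @return list with per-lambda summaries: mean (across repeats) 95th
#'   percentile NRMSE over the support (`p95Volume`) and over unexcited
#'   slices (`p95Unexcited`), per-repeat values, and the across-repeat
#'   mean NRMSE map.
#' @export
runSim2 <- function(sens, mask, lambdas = c(0, 1e-3, 5e-3, 1e-2),
                    nRepeats = 10L, seed = 1L, excitedSlice = 5L,
                    fluctSd = 0.05, groups = NULL) {
  if (is.null(groups)) groups <- aliasGroups(mask, sens)
  d <- dim(sens@values)[1:3]
  nT <- mask@scheme@nT
  stopifnot(excitedSlice >= 1L, excitedSlice <= d[3])
  sup <- sens@support
  excited <- array(FALSE, d)
  excited[, , excitedSlice] <- sup[, , excitedSlice]
  unexcited <- sup & !excited
  nv <- sum(excited)
  if (nv == 0L) stop("no support voxels in the excited slice")
  sig <- oneOverFSignal(nv * nRepeats, nT, seed = seed)
  truth <- array(0i, c(d, nT, nRepeats))
  w <- which(excited)
  for (r in seq_len(nRepeats)) {
    rows <- (r - 1L) * nv + seq_len(nv)
    slab <- 1 + fluctSd * sig[rows, , drop = FALSE]   # baseline + fluctuation
    for (t in seq_len(nT))
      truth[w + (t - 1L) * prod(d) + (r - 1L) * prod(d) * nT] <- slab[, t]
  }
  ref <- refRms(truth[, , , , 1, drop = FALSE], excited)
  out <- list()
  for (lam in lambdas) {
    xh <- applySmoothing(groups, truth, lam)
    p95v <- p95u <- numeric(nRepeats)
    mapAcc <- array(0, d)
    for (r in seq_len(nRepeats)) {
      er <- nrmse(array(xh[, , , , r], c(d, nT)),
                  array(truth[, , , , r], c(d, nT)), ref)
      p95v[r] <- stats::quantile(er[sup], 0.95, names = FALSE)
      p95u[r] <- stats::quantile(er[unexcited], 0.95, names = FALSE)
      mapAcc <- mapAcc + er / nRepeats
    }
    out[[length(out) + 1L]] <- list(
      lambda = lam,
      p95Volume = mean(p95v), p95VolumeByRepeat = p95v,
      p95Unexcited = mean(p95u), p95UnexcitedByRepeat = p95u,
      nrmseMap = mapAcc)
  }
  list(results = out, lambdas = lambdas, nRepeats = nRepeats,
       excitedSlice = excitedSlice, fluctSd = fluctSd, refRms = ref,
       seed = seed, nT = nT)
}
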