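test_that("a voxel that does not alias has g = 1 exactly at lambda = 0", {
  e <- singletonEncoding()
  expect_true(all(vapply(e$groups, function(g) nrow(groupMembers(g)), 0L) == 1L))
  S0 <- smoothingOperator(e$groups[[7]], 0)
  expect_equal(unname(gFactor(S0)[1, ]), rep(1, e$scheme@nT),
               tolerance = 1e-12)
  expect_equal(g0Factor(S0), 1, tolerance = 1e-12)
})

test_that("per-time g-factors are constant across time for constant-shift schemes", {
  e <- smallEncoding(nKy = 16, nKz = 4, nT = 16, dkzDky = 1, dkzDt = 1,
                     nx = 2, nCoils = 8, seed = 2)
  g <- e$groups[[which.max(vapply(e$groups, function(g) nrow(groupMembers(g)), 0L))]]
  spread <- function(S) {
    gf <- gFactor(S)
    max(apply(gf, 1, function(r) diff(range(r)) / mean(r)))
  }
  ## unregularized: exact stationarity
  expect_lt(spread(smoothingOperator(g, 0)), 1e-12)
  ## regularized, stationary (circulant) boundary with the shift period
  ## dividing nT: exact stationarity again
  expect_lt(spread(smoothingOperator(g, 1e-2, circulant = TRUE)), 1e-8)
})

test_that("Monte-Carlo variance ratios reproduce the analytic g-factor", {
  e <- smallEncoding(nKy = 16, nKz = 4, nT = 16, dkzDky = 1, dkzDt = 1,
                     nx = 2, nCoils = 8, seed = 5)
  r <- runSim1(e$sens, e$mask, 1e-2, nReal = 1000, seed = 3, spectra = FALSE)
  ok <- !is.na(r$analytic$gLam)
  relg <- abs(r$empirical$gLam[ok] - r$analytic$gLam[ok]) / r$analytic$gLam[ok]
  expect_lt(max(relg), 0.03)
})

test_that("approximate DOF is nT at lambda = 0 and decreases monotonically", {
  ## 256 time-points, as in the full-scale noise study
  sens <- CoilSensitivities(array(1 + 0i, c(1, 8, 1, 1)),
                            array(TRUE, c(1, 8, 1)))
  groups <- aliasGroups(buildCaipiMask(SamplingScheme(8, 1, 256, 1, 0, 0)),
                        sens)
  expect_equal(approxDof(smoothingOperator(groups[[1]], 0)), 256,
               tolerance = 1e-10)
  e <- smallEncoding(nKy = 12, nKz = 4, nT = 12, dkzDky = 1, dkzDt = 1,
                     nx = 2, nCoils = 8, seed = 6)
  g <- e$groups[[3]]
  dofs <- vapply(10^seq(-5, 2), function(l)
    mean(approxDof(smoothingOperator(g, l))), 0)
  expect_true(all(diff(dofs) <= 1e-9))
  ## g-factor is monotone non-increasing in lambda as well
  gs <- vapply(10^seq(-5, 2), function(l)
    mean(gFactorRMS(smoothingOperator(g, l))), 0)
  expect_true(all(diff(gs) <= 1e-9))
})

test_that("post-hoc DOF is encoding independent and equals the kernel row norms", {
  Sk <- posthocSmoother(0.3, 24)
  expect_equal(approxDof(Sk), sum(solve(diag(24) + 0.3 * tdiffPenalty(24))^2),
               tolerance = 1e-12)
})

test_that("design-exact DOF is nT - p at lambda = 0 and never exceeds the approximate DOF", {
  e <- smallEncoding(nKy = 12, nKz = 4, nT = 16, dkzDky = 1, dkzDt = 1,
                     nx = 2, nCoils = 8, seed = 7)
  g <- e$groups[[4]]
  S0 <- smoothingOperator(g, 0)
  D <- makeRegressor("block", 16)
  expect_equal(effectiveDof(S0, D), rep(15, nrow(groupMembers(g))),
               tolerance = 1e-9)
  Sl <- smoothingOperator(g, 3e-2)
  set.seed(8)
  for (i in 1:5) {
    Dr <- matrix(rnorm(16), 16, 1)
    expect_true(all(effectiveDof(Sl, Dr) <= approxDof(Sl) + 1e-9))
  }
})

test_that("the three task regressors give distinct DOF curves that agree at lambda = 0", {
  e <- smallEncoding(nKy = 12, nKz = 4, nT = 32, dkzDky = 1, dkzDt = 1,
                     nx = 2, nCoils = 8, seed = 9)
  g <- e$groups[[2]]
  designs <- list(makeRegressor("block", 32),
                  makeRegressor("event", 32, seed = 1),
                  makeRegressor("noise", 32, seed = 1))
  d0 <- vapply(designs, function(D)
    effectiveDof(smoothingOperator(g, 0), D, m = 1), 0)
  expect_equal(d0, rep(31, 3), tolerance = 1e-9)
  dl <- vapply(designs, function(D)
    effectiveDof(smoothingOperator(g, 5e-2), D, m = 1), 0)
  expect_gt(min(dist(dl)), 1e-6)
})

test_that("exact GLM efficiency is 1 at lambda = 0 and bounded for non-aliased voxels", {
  eS <- singletonEncoding(nT = 64)
  g <- eS$groups[[10]]
  D <- makeRegressor("block", 64)
  expect_equal(glmEfficiencyExact(smoothingOperator(g, 0), D), 1,
               tolerance = 1e-10)
  ## no efficiency gain where g0 = 1 (up to a small finite-nT term)
  emax <- max(vapply(10^seq(-5, -1, by = 0.5), function(l)
    glmEfficiencyExact(smoothingOperator(g, l), D), 0))
  expect_lt(emax, 1 + 1e-3)
})

test_that("post-hoc smoothing can only reduce the exact efficiency", {
  D <- makeRegressor("block", 64)
  for (kap in c(1e-2, 1e-1, 1)) {
    ek <- glmEfficiencyExact(posthocSmoother(kap, 64), D)
    expect_lte(ek, 1 + 1e-10)
  }
})

test_that("asymptotic efficiency matches its algebraic characterization and the exact form", {
  e <- smallEncoding(nKy = 16, nKz = 4, nT = 128, dkzDky = 1, dkzDt = 1,
                     nx = 1, nCoils = 6, seed = 10)
  g <- e$groups[[which.max(vapply(e$groups, function(g) nrow(groupMembers(g)), 0L))]]
  S0 <- smoothingOperator(g, 0)
  expect_equal(glmEfficiencyAsymptotic(S0),
               rep(1, nrow(groupMembers(g))), tolerance = 1e-10)
  D <- makeRegressor("block", 128)
  ## agreement holds in the mild-smoothing regime the approximation targets
  for (l in c(1e-4, 1e-3)) {
    S <- smoothingOperator(g, l)
    ea <- glmEfficiencyAsymptotic(S)
    ee <- glmEfficiencyExact(S, D)
    expect_lt(max(abs(ea - ee) / ee), 0.05)
    ## e > 1 exactly when g^2/DOF improves on g0^2/nT
    lhs <- ea > 1
    rhs <- gFactorRMS(S)^2 / approxDof(S) < g0Factor(S)^2 / S@nT
    expect_identical(lhs, rhs)
  }
})

test_that("tSNR efficiency reduces to conventional tSNR at full DOF and penalizes lost DOF", {
  set.seed(11)
  nT <- 256
  sigma <- 0.5
  ts <- array(10, c(3, 3, 2, nT)) + array(rnorm(9 * 2 * nT, sd = sigma),
                                          c(3, 3, 2, nT))
  full <- tsnrEfficiency(ts, array(nT, c(3, 3, 2)))
  expect_equal(mean(full), 10 / sigma, tolerance = 0.1 * 10 / sigma)
  half <- tsnrEfficiency(ts, array(nT / 2, c(3, 3, 2)))
  expect_true(all(half < full))
  expect_equal(half, full * sqrt(0.5), tolerance = 1e-12)
  ## linear-exponent flag
  lin <- tsnrEfficiency(ts, array(nT / 2, c(3, 3, 2)), exponent = 1)
  expect_equal(lin, full * 0.5, tolerance = 1e-12)
  ## degenerate voxels are masked out
  flat <- array(1, c(2, 2, 1, 8))
  expect_true(all(is.na(tsnrEfficiency(flat, array(8, c(2, 2, 1))))))
})

test_that("expected bias vanishes at lambda = 0, matches the reconstruction error and grows with lambda", {
  e <- smallEncoding(nKy = 12, nKz = 4, nT = 32, dkzDky = 1, dkzDt = 1,
                     nx = 2, nCoils = 8, seed = 12)
  g <- e$groups[[6]]
  G <- nrow(groupMembers(g))
  xt <- matrix(oneOverFSignal(G, 32, seed = 13), G, 32)
  expect_lt(max(Mod(biasMap(smoothingOperator(g, 0), xt))), 1e-10)
  ## bias = noise-free reconstruction minus truth (linearity of the solve)
  lam <- 1e-2
  b1 <- biasMap(smoothingOperator(g, lam), xt)
  fac <- smstempo:::groupFactor(g, lam)
  xr <- smstempo:::groupSolve(fac, smstempo:::groupAtA(g, as.vector(xt)))
  b2 <- matrix(xr, G, 32) - xt
  expect_lt(max(Mod(b1 - b2)), 1e-8)
  norms <- vapply(c(1e-4, 1e-3, 1e-2, 1e-1), function(l)
    sum(Mod(biasMap(smoothingOperator(g, l), xt))^2), 0)
  expect_true(all(diff(norms) > 0))
})

test_that("NRMSE matches its definition and a brute-force computation", {
  x <- randImage(c(3, 4, 2, 5), seed = 14)
  expect_true(all(nrmse(x, x, ref = 1) == 0))
  ## unit-amplitude error at one voxel with reference RMS 2 gives 0.5
  y <- x
  y[2, 3, 1, ] <- y[2, 3, 1, ] + 1
  err <- nrmse(y, x, ref = 2)
  expect_equal(err[2, 3, 1], 0.5, tolerance = 1e-12)
  ## brute-force two-loop oracle
  bf <- array(0, c(3, 4, 2))
  for (i in 1:3) for (j in 1:4) for (k in 1:2)
    bf[i, j, k] <- sqrt(mean(Mod(y[i, j, k, ] - x[i, j, k, ])^2)) / 2
  expect_lt(max(abs(err - bf)), 1e-12)
  expect_error(nrmse(y, x, ref = 0), "positive")
})

test_that("rank-deficient smoothed designs are reported with the offending regressor", {
  e <- smallEncoding(nKy = 12, nKz = 4, nT = 16, nx = 1, nCoils = 8,
                     seed = 15)
  S <- smoothingOperator(e$groups[[1]], 1e-2)
  Dbad <- matrix(0, 16, 1, dimnames = list(NULL, "flat"))
  expect_error(effectiveDof(S, Dbad), "rank deficient")
  expect_error(glmEfficiencyExact(S, cbind(makeRegressor("block", 16),
                                           makeRegressor("noise", 16))),
               "single-effect")
})
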