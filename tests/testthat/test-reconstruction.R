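test_that("fully sampled single-coil data at lambda = 0 invert in one CG iteration", {
  sens <- CoilSensitivities(array(1 + 0i, c(2, 8, 1, 1)),
                            array(TRUE, c(2, 8, 1)))
  scheme <- SamplingScheme(8, 1, 4, 1, 0, 0)
  enc <- makeEncoding(sens, buildCaipiMask(scheme))
  x0 <- randImage(c(2, 8, 1, 4), seed = 1)
  k <- forwardOp(enc, x0)
  r <- solveCG(enc, k, reconConfig(0))
  expect_equal(r@iterations, 1L)
  expect_true(r@converged)
  expect_lt(relErr(reconImage(r), x0), 1e-12)
})

test_that("CG matches the per-group direct solve within tolerance-consistent bounds", {
  e <- smallEncoding(nKy = 12, nKz = 4, nT = 6, dkzDky = 1, dkzDt = 1,
                     nx = 3, nCoils = 6, seed = 3)
  k <- randKspace(e$enc, seed = 4)
  for (lam in c(1e-3, 1e-1)) {
    rd <- solveDirect(e$enc, k, lam)
    rc <- solveCG(e$enc, k, reconConfig(lam, tol = 1e-8, maxiter = 500))
    expect_true(rc@converged)
    expect_lt(relErr(reconImage(rc), reconImage(rd)), 1e-3)
  }
})

test_that("direct solve matches the dense whole-problem inversion", {
  e <- smallEncoding(nKy = 8, nKz = 2, nT = 8, dkzDky = 1, dkzDt = 1,
                     nx = 2, nCoils = 4, seed = 6)
  k <- randKspace(e$enc, seed = 7)
  for (lam in c(0, 5e-2)) {
    xd <- reconImage(solveDirect(e$enc, k, lam))
    xo <- denseNormalSolve(e$enc, k, lam)
    expect_lt(relErr(xd, xo), 1e-10)
  }
})

test_that("direct solve is linear and invariant to group ordering", {
  e <- smallEncoding(nKy = 8, nKz = 4, nT = 5, dkzDky = 1, dkzDt = 2,
                     nx = 2, nCoils = 6, seed = 8)
  k1 <- randKspace(e$enc, seed = 9)
  k2 <- randKspace(e$enc, seed = 10)
  lam <- 1e-2
  x1 <- reconImage(solveDirect(e$enc, k1, lam, groups = e$groups))
  x2 <- reconImage(solveDirect(e$enc, k2, lam, groups = e$groups))
  x12 <- reconImage(solveDirect(e$enc, k1 + k2, lam, groups = e$groups))
  expect_lt(relErr(x12, x1 + x2), 1e-11)
  xr <- reconImage(solveDirect(e$enc, k1, lam, groups = rev(e$groups)))
  expect_identical(xr, x1)
})

test_that("size cap on direct solves routes to the CG path", {
  e <- smallEncoding(nKy = 8, nKz = 4, nT = 5, nx = 2, nCoils = 6)
  k <- randKspace(e$enc)
  expect_error(solveDirect(e$enc, k, 0, sizeCap = 4L), "solveCG")
})

test_that("unresolvable aliasing is flagged or non-identifiable at lambda = 0", {
  ## one flat coil cannot separate fold-over partners at lambda = 0: the
  ## direct factorization refuses, and the CG solution (of the consistent
  ## but singular normal equations) cannot recover an encoded truth
  sens <- CoilSensitivities(array(1 + 0i, c(2, 8, 2, 1)),
                            array(TRUE, c(2, 8, 2)))
  scheme <- SamplingScheme(8, 2, 4, 1, 1, 0)
  enc <- makeEncoding(sens, buildCaipiMask(scheme))
  expect_error(solveDirect(enc, randKspace(enc, seed = 11), 0), "singular")
  x0 <- randImage(c(2, 8, 2, 4), seed = 12)
  r <- solveCG(enc, forwardOp(enc, x0), reconConfig(0, maxiter = 100))
  expect_gt(relErr(reconImage(r), x0), 0.1)
  ## temporal regularization cannot cure this: the time-constant
  ## difference of the two identical-sensitivity partners is in the null
  ## space of both the encoding and the temporal penalty
  expect_error(solveDirect(enc, forwardOp(enc, x0), 1e-2), "singular")
})

test_that("smoothing operator is the identity at lambda = 0 and in the lambda -> 0 limit", {
  e <- smallEncoding(nKy = 16, nKz = 4, nT = 8, dkzDky = 1, dkzDt = 1,
                     nx = 2, nCoils = 6, seed = 2)
  g <- e$groups[[which.max(vapply(e$groups, function(g) nrow(groupMembers(g)), 0L))]]
  n <- nrow(groupMembers(g)) * g@nT
  S0 <- smoothingOperator(g, 0)
  expect_lt(max(Mod(smoothingMatrix(S0) - diag(n))), 1e-12)
  Seps <- smoothingOperator(g, 1e-12)
  expect_lt(max(Mod(smoothingMatrix(Seps) - diag(n))), 1e-8)
})

test_that("applying S after the pseudoinverse equals the one-shot regularized solve", {
  e <- smallEncoding(nKy = 12, nKz = 4, nT = 8, dkzDky = 1, dkzDt = 1,
                     nx = 2, nCoils = 8, seed = 12)
  g <- e$groups[[5]]
  n <- nrow(groupMembers(g)) * g@nT
  set.seed(13)
  atk <- matrix(complex(real = rnorm(n), imaginary = rnorm(n)), ncol = 1)
  lam <- 2e-2
  x0 <- smstempo:::groupSolve(smstempo:::groupFactor(g, 0), atk)
  xs <- smoothingMatrix(smoothingOperator(g, lam)) %*% x0
  xd <- smstempo:::groupSolve(smstempo:::groupFactor(g, lam), atk)
  expect_lt(max(Mod(xs - xd)), 1e-8 * max(Mod(xd)))
})

test_that("smoothing preserves temporally constant signals exactly", {
  e <- smallEncoding(nKy = 12, nKz = 4, nT = 6, dkzDky = 1, dkzDt = 1,
                     nx = 2, nCoils = 8, seed = 14)
  d <- c(2, 12, 4, 6)
  img <- array(0i, d)
  img[] <- rep(randImage(c(2, 12, 4, 1), seed = 15), 6)   # constant in t
  img[array(!supportMask(e$sens), d)] <- 0i
  sm <- applySmoothing(e$groups, img, 5e-2)
  expect_lt(relErr(sm, img), 1e-10)
})

test_that("strong regularization drives a singleton voxel towards its temporal mean", {
  sens <- CoilSensitivities(array(1 + 0i, c(1, 8, 1, 1)),
                            array(TRUE, c(1, 8, 1)))
  scheme <- SamplingScheme(8, 1, 16, 1, 0, 0)
  groups <- aliasGroups(buildCaipiMask(scheme), sens)
  SInf <- smoothingOperator(groups[[3]], 1e9)
  set.seed(16)
  ts <- rnorm(16)
  sm <- as.vector(smoothingMatrix(SInf) %*% ts)
  expect_lt(max(abs(sm - mean(ts))), 1e-6)
})

test_that("post-hoc smoother matches the dense inverse and preserves constants", {
  nT <- 32
  kap <- 0.7
  Sk <- posthocSmoother(kap, nT)
  dense <- solve(diag(nT) + kap * tdiffPenalty(nT))
  expect_lt(max(abs(smoothingMatrix(Sk) - dense)), 1e-12)
  expect_equal(unname(rowSums(smoothingMatrix(Sk))), rep(1, nT),
               tolerance = 1e-12)
  expect_lt(max(abs(smoothingMatrix(posthocSmoother(0, nT)) - diag(nT))),
            1e-14)
})

test_that("kappa matching hits the DOF target and the DOF is monotone in kappa", {
  nT <- 48
  dofs <- vapply(c(0, 10^seq(-3, 2, by = 0.5)),
                 function(k) approxDof(posthocSmoother(k, nT)), 0)
  expect_true(all(diff(dofs) <= 1e-12))
  for (target in c(nT, 40, 20, 5)) {
    mk <- matchKappa(target, nT)
    expect_lt(abs(mk$dof - target), 1e-3 * nT)
    if (target == nT) expect_identical(mk$kappa, 0)
  }
  expect_error(matchKappa(0.5, nT), "range")
  expect_error(matchKappa(nT + 1, nT), "range")
})

test_that("CG and direct solutions agree across many random encodings", {
  ## property-style sweep over schemes, coils and regularization weights
  set.seed(20)
  for (i in 1:8) {
    nKz <- sample(c(2, 4), 1)
    ry <- sample(1:2, 1)
    e <- smallEncoding(nKy = sample(c(8, 12), 1), nKz = nKz,
                       nT = sample(c(4, 6), 1), ry = ry,
                       dkzDky = 1, dkzDt = sample(0:2, 1),
                       dkyDt = if (ry > 1) sample(0:1, 1) else 0,
                       nx = 2, nCoils = sample(6:8, 1), seed = i)
    k <- randKspace(e$enc, seed = 100 + i)
    lam <- 10^runif(1, -4, -1)
    rd <- solveDirect(e$enc, k, lam)
    rc <- solveCG(e$enc, k, reconConfig(lam, tol = 1e-9, maxiter = 800))
    expect_lt(relErr(reconImage(rc), reconImage(rd)), 1e-4)
  }
})
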