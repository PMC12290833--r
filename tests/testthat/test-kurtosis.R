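test_that("the kurtosis index table spans the 15 independent components", {
  tab <- kurtosisIndexTable()
  expect_identical(nrow(tab), 15L)
  expect_identical(sum(tab$mult), 81)           # 3^4 index assignments
  expect_true(all(tab$i <= tab$j & tab$j <= tab$k & tab$k <= tab$l))
})

test_that("DKI OLS recovers all 21 coefficients from noiseless signals", {
  sch <- twoShellScheme()
  set.seed(41)
  for (i in 1:5) {
    tw <- wmKurtosis(axis = { v <- rnorm(3); v / sqrt(sum(v^2)) },
                     MW = runif(1, 0.4, 1.2), AW = runif(1, 0.2, 0.9),
                     RW = runif(1, 0.8, 2))
    s <- voxelSignal(sch, tw$D, tw$w)
    fit <- fitDKI(seriesFromSignal(s, sch), algorithm = "OLS")
    cf <- fitCoefficients(fit)[1, 1, 1, ]
    expect_lt(max(abs(cf[2:7] - dwikit:::coefFromTensor(tw$D))), 1e-10)
    expect_lt(max(abs(cf[8:22] - tw$w)), 1e-8)
  }
  # mono-exponential input: all kurtosis coefficients vanish
  s0 <- voxelSignal(sch, wmTensor())
  fit0 <- fitDKI(seriesFromSignal(s0, sch), algorithm = "OLS")
  expect_lt(max(abs(fitCoefficients(fit0)[1, 1, 1, 8:22])), 1e-8)
})

test_that("DKI OLS equals an explicit 22-column normal-equation oracle", {
  sch <- twoShellScheme()
  X <- dkiDesignMatrix(sch)
  set.seed(42)
  for (i in 1:10) {
    tw <- wmKurtosis(MW = runif(1, 0.3, 1))
    s <- voxelSignal(sch, tw$D, tw$w) * exp(rnorm(nVolumes(sch), 0, 0.02))
    fit <- fitDKI(seriesFromSignal(s, sch), algorithm = "OLS")
    beta <- solve(t(X) %*% X, t(X) %*% log(s))[, 1]
    md <- mean(beta[c(2, 5, 7)])
    oracle <- c(beta[1:7], beta[8:22] / md^2)
    expect_lt(max(abs(fitCoefficients(fit)[1, 1, 1, ] - oracle)), 1e-10)
  }
})

test_that("single-shell input is rejected with the shell count", {
  sch <- oneShellScheme()
  dwi <- seriesFromSignal(voxelSignal(sch, wmTensor()), sch)
  expect_error(fitDKI(dwi), "1")
})

test_that("axisymmetric NLLS recovers its generating parameters", {
  sch <- twoShellScheme()
  set.seed(43)
  for (i in 1:5) {
    u <- rnorm(3); u <- u / sqrt(sum(u^2)); if (u[3] < 0) u <- -u
    truth <- c(Dpar = 1.7e-3, Dperp = 0.5e-3, MW = 0.8,
               AW = runif(1, 0.3, 0.7), RW = runif(1, 1, 2))
    tw <- dwikit:::axiTensors(u, truth[1], truth[2], truth[3], truth[4],
                              truth[5])
    s <- voxelSignal(sch, tw$D, tw$w)
    fit <- fitAxisymmetricDKI(seriesFromSignal(s, sch))
    p <- fitCoefficients(fit)[1, 1, 1, ]
    expect_lt(max(abs(p[4:8] - truth) / truth), 1e-6)
    uhat <- c(sin(p[2]) * cos(p[3]), sin(p[2]) * sin(p[3]), cos(p[2]))
    ang <- acos(min(abs(sum(uhat * u)), 1)) * 180 / pi
    expect_lt(ang, 0.1)                          # antipodal-safe axis error
    expect_lte(p[2], pi / 2 + 1e-9)              # gauge: theta in [0, pi/2]
  }
})

test_that("isotropic Gaussian input degenerates gracefully", {
  sch <- twoShellScheme()
  s <- voxelSignal(sch, 1e-3 * diag(3))
  fit <- fitAxisymmetricDKI(seriesFromSignal(s, sch))
  p <- fitCoefficients(fit)[1, 1, 1, ]
  expect_equal(p[4], p[5], tolerance = 1e-6)     # Dpar = Dperp
  expect_lt(max(abs(p[6:8])), 1e-6)              # all W terms 0
})

test_that("axisymmetric expansion is directionally equivalent to the model", {
  set.seed(44)
  u <- rnorm(3); u <- u / sqrt(sum(u^2))
  pars <- c(1.9e-3, 0.45e-3, 0.9, 0.55, 1.7)
  tw <- dwikit:::axiTensors(u, pars[1], pars[2], pars[3], pars[4], pars[5])
  md <- (pars[1] + 2 * pars[2]) / 3
  n <- matrix(rnorm(3000), 3)
  n <- sweep(n, 2, sqrt(colSums(n^2)), "/")
  c2 <- colSums(n * u)^2; s2 <- 1 - c2
  w13 <- (5 * pars[3] - pars[4] - (8 / 3) * pars[5]) / 4
  Dn_model <- pars[2] + (pars[1] - pars[2]) * c2
  Wn_model <- pars[5] * s2^2 + pars[4] * c2^2 + 6 * w13 * c2 * s2
  K_model <- (md / Dn_model)^2 * Wn_model
  Dn_full <- colSums(n * (tw$D %*% n))
  K_full <- (md / Dn_full)^2 * as.numeric(dwikit:::wDesignRow(n) %*% tw$w)
  expect_lt(max(abs(K_full - K_model)), 1e-10)
  # W = 0 whenever all three amplitudes vanish
  tw0 <- dwikit:::axiTensors(u, 1.7e-3, 0.4e-3, 0, 0, 0)
  expect_identical(max(abs(tw0$w)), 0)
})

test_that("expand -> resynthesize -> refit reproduces the 8 parameters", {
  sch <- twoShellScheme()
  truth <- c(log(1000), acos(0.8), 0.6, 1.8e-3, 0.5e-3, 0.85, 0.5, 1.4)
  u <- c(sin(truth[2]) * cos(truth[3]), sin(truth[2]) * sin(truth[3]),
         cos(truth[2]))
  tw <- dwikit:::axiTensors(u, truth[4], truth[5], truth[6], truth[7],
                            truth[8])
  afit <- fitAxisymmetricDKI(seriesFromSignal(
    voxelSignal(sch, tw$D, tw$w), sch))
  full <- axiToFull(afit)
  s2 <- voxelSignal(sch, tensorFromCoef(fitCoefficients(full)[1, 1, 1, 2:7]),
                    fitCoefficients(full)[1, 1, 1, 8:22])
  refit <- fitAxisymmetricDKI(seriesFromSignal(s2, sch))
  expect_lt(max(abs(fitCoefficients(refit)[1, 1, 1, ] - truth) /
                pmax(abs(truth), 1e-3)), 1e-5)
})

test_that("kurtosis metrics match symmetry limits and a Monte-Carlo mean", {
  # isotropic D with isotropic W: all six metrics equal the amplitude
  wiso <- numeric(15)
  for (q in list(c(1,1,1,1), c(2,2,2,2), c(3,3,3,3)))
    wiso[dwikit:::widx(q[1], q[2], q[3], q[4])] <- 0.7
  for (q in list(c(1,1,2,2), c(1,1,3,3), c(2,2,3,3)))
    wiso[dwikit:::widx(q[1], q[2], q[3], q[4])] <- 0.7 / 3
  m <- dwikit:::dkiMetricsVoxel(c(1e-3, 0, 0, 1e-3, 0, 1e-3), wiso)
  for (nm in c("MK", "AK", "RK", "MW", "AW", "RW"))
    expect_equal(m[[nm]], 0.7, tolerance = 1e-9)
  # W = 0: all metrics 0
  m0 <- dwikit:::dkiMetricsVoxel(dwikit:::coefFromTensor(wmTensor()),
                                 numeric(15))
  expect_lt(max(abs(unlist(m0[1:6]))), 1e-12)
  # MK quadrature against a large Monte-Carlo sphere average
  set.seed(45)
  tw <- wmKurtosis(axis = c(0.6, 0.64, 0.48))
  mq <- dwikit:::dkiMetricsVoxel(dwikit:::coefFromTensor(tw$D), tw$w)
  n <- matrix(rnorm(3e6), 3)
  n <- sweep(n, 2, sqrt(colSums(n^2)), "/")
  md <- mean(diag(tw$D))
  Dn <- colSums(n * (tw$D %*% n))
  Kn <- (md / Dn)^2 * as.numeric(dwikit:::wDesignRow(n) %*% tw$w)
  expect_lt(abs(mq$MK - mean(Kn)), 1e-3)
})

test_that("kurtosis metrics are rotation invariant", {
  set.seed(46)
  tw <- wmKurtosis()
  m0 <- dwikit:::dkiMetricsVoxel(dwikit:::coefFromTensor(tw$D), tw$w)
  for (i in 1:20) {
    R <- randomRotation()
    DR <- R %*% tw$D %*% t(R)
    wR <- dwikit:::wRotate(tw$w, R)
    m1 <- dwikit:::dkiMetricsVoxel(dwikit:::coefFromTensor(DR), wR)
    for (nm in c("MK", "AK", "RK", "MW", "AW", "RW"))
      expect_lt(abs(m1[[nm]] - m0[[nm]]), 1e-8)
  }
})

test_that("DTI underestimates diffusivity on strongly kurtotic signals", {
  sch <- twoShellScheme()                        # b_max = 2500 s/mm^2
  tw <- wmKurtosis(MW = 1, AW = 1, RW = 1)       # isotropic-kurtosis W
  s <- voxelSignal(sch, tw$D, tw$w)
  dwi <- seriesFromSignal(s, sch)
  md_dti <- dtiMetrics(fitDTI(dwi, algorithm = "OLS"))$MD[1, 1, 1]
  md_dki <- dtiMetrics(fitDKI(dwi, algorithm = "OLS"))$MD[1, 1, 1]
  expect_lt(md_dti, md_dki)
  expect_equal(md_dki, mean(diag(tw$D)), tolerance = 1e-6)
})

test_that("full DKI fits of axisymmetric signals obey the symmetry relations", {
  sch <- twoShellScheme()
  tw <- dwikit:::axiTensors(c(0, 0, 1), 1.8e-3, 0.5e-3, 0.9, 0.6, 1.5)
  fit <- fitDKI(seriesFromSignal(voxelSignal(sch, tw$D, tw$w), sch))
  w <- fitCoefficients(fit)[1, 1, 1, 8:22]
  expect_equal(w[dwikit:::widx(1, 1, 1, 1)], w[dwikit:::widx(2, 2, 2, 2)],
               tolerance = 1e-8)
  expect_equal(w[dwikit:::widx(1, 1, 2, 2)],
               w[dwikit:::widx(1, 1, 1, 1)] / 3, tolerance = 1e-8)
  expect_equal(w[dwikit:::widx(1, 1, 3, 3)], w[dwikit:::widx(2, 2, 3, 3)],
               tolerance = 1e-8)
  # odd-order components vanish
  for (q in list(c(1,1,1,3), c(2,2,2,3), c(1,2,3,3), c(1,3,3,3)))
    expect_lt(abs(w[dwikit:::widx(q[1], q[2], q[3], q[4])]), 1e-8)
})
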