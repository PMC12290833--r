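test_that("all algorithms recover an isotropic tensor exactly without noise", {
  sch <- oneShellScheme()
  d <- 1e-3
  s <- voxelSignal(sch, d * diag(3))
  dwi <- seriesFromSignal(s, sch)
  truth <- c(d, 0, 0, d, 0, d)
  ne <- new("NoiseEstimate", sigma = 1, ncoils = 1L, method = "standard",
            nSamples = 0L)
  for (alg in c("OLS", "WLS", "ROB", "NLLS")) {
    fit <- fitDTI(dwi, algorithm = alg, noise = ne)
    expect_lt(max(abs(fitCoefficients(fit)[1, 1, 1, 2:7] - truth)), 1e-10)
    expect_equal(rmsErrorMap(fit)[1, 1, 1], 0, tolerance = 1e-8)
  }
})

test_that("OLS equals an explicit normal-equation oracle", {
  sch <- oneShellScheme()
  X <- dtiDesignMatrix(sch)
  set.seed(31)
  for (i in 1:20) {
    D <- randomSPD()
    s <- voxelSignal(sch, D) * exp(rnorm(nVolumes(sch), 0, 0.03))
    fit <- fitDTI(seriesFromSignal(s, sch), algorithm = "OLS")
    oracle <- solve(t(X) %*% X, t(X) %*% log(s))[, 1]
    expect_lt(max(abs(fitCoefficients(fit)[1, 1, 1, ] - oracle)), 1e-12)
  }
})

test_that("NLLS recovers a known tensor from noiseless signals", {
  sch <- oneShellScheme()
  set.seed(32)
  for (i in 1:5) {
    D <- randomSPD()
    s <- voxelSignal(sch, D)
    fit <- fitDTI(seriesFromSignal(s, sch), algorithm = "NLLS")
    expect_lt(max(abs(fitCoefficients(fit)[1, 1, 1, 2:7] -
                      dwikit:::coefFromTensor(D))), 1e-8)
    expect_true(fit@converged[1, 1, 1])
  }
})

test_that("tensor metrics match closed forms and are rotation invariant", {
  iso <- tensorScalarMetrics(2e-3 * diag(3))
  expect_equal(iso$FA, 0)
  expect_equal(iso$MD, 2e-3)
  expect_equal(iso$AD, 2e-3)
  expect_equal(iso$RD, 2e-3)
  stick <- tensorScalarMetrics(diag(c(1e-3, 0, 0)))
  expect_equal(stick$FA, 1, tolerance = 1e-9)
  expect_equal(stick$MD, 1e-3 / 3)
  expect_equal(stick$AD, 1e-3)
  expect_equal(stick$RD, 0)
  set.seed(33)
  D <- randomSPD()
  m0 <- tensorScalarMetrics(D)
  for (i in 1:100) {
    R <- randomRotation()
    m1 <- tensorScalarMetrics(R %*% D %*% t(R))
    expect_lt(abs(m1$FA - m0$FA), 1e-10)
    expect_lt(abs(m1$MD - m0$MD), 1e-12)
  }
  # non-finite tensors map to missing-value flags
  expect_true(is.na(tensorScalarMetrics(matrix(NaN, 3, 3))$FA))
})

test_that("robust weight factors behave as designed", {
  # zero residuals: every factor is 1 (reduces to WLS)
  rw <- robustWeights(rep(0, 10), rep(100, 10), rep(1:2, 5))
  expect_true(all(rw$w == 1))
  # a single gross outlier is crushed; typical points keep w_local high
  set.seed(34)
  r <- rnorm(30)
  shat <- mad(r, center = 0)
  r[7] <- 10 * shat
  rw <- robustWeights(r, rep(100, 30))
  expect_lt(rw$w_local[7], 0.01)
  expect_gt(median(rw$w_local[-7]), 0.6)
  # a slice whose every observation is outlying is down-weighted wholesale
  r2 <- c(rnorm(20, 0, 0.01), rnorm(10, 1, 0.01))
  sl <- rep(c(1L, 2L, 3L), each = 10)
  rw2 <- robustWeights(r2, rep(100, 30), sl)
  expect_lt(max(rw2$w_slice[sl == 3]), min(rw2$w_slice[sl != 3]))
  # zero MAD with nonzero residuals floors the scale with a warning
  expect_warning(robustWeights(c(rep(0, 20), 5), rep(1, 21)), "floored")
  # signal factor is the normalized squared predicted magnitude
  rw3 <- robustWeights(rep(0.1, 3), c(100, 50, 10))
  expect_equal(rw3$w_signal, c(1, 0.25, 0.01))
})

test_that("robust fitting resists slice dropouts better than OLS", {
  sch <- oneShellScheme()
  ph <- synthesizePhantom(list(grid = c(4, 4, 6), scheme = sch,
                               layout = "uniform",
                               regions = list(list(D = wmTensor()))))
  truthFA <- tensorScalarMetrics(wmTensor())$FA
  noisy <- addNoise(ph$dwi, 20, 1L, seed = 7)
  corr <- injectOutliers(noisy, 0.2, 0.4, seed = 8)$dwi
  err <- sapply(c("OLS", "ROB"), function(alg)
    mean(abs(dtiMetrics(fitDTI(corr, algorithm = alg))$FA - truthFA)))
  expect_lt(err["ROB"], err["OLS"])
  # without contamination or noise the two coincide exactly
  clean <- sapply(c("OLS", "ROB"), function(alg)
    dtiMetrics(fitDTI(ph$dwi, algorithm = alg))$FA[1, 1, 1])
  expect_equal(clean[["ROB"]], clean[["OLS"]], tolerance = 1e-12)
})

test_that("rms error is computed in the fitting domain and saturates at 0", {
  # saturated fit: 7 observations, 7 parameters
  sch7 <- gradientScheme(
    c(0, rep(800, 6)),
    cbind(c(0, 0, 0),
          rbind(c(1, 0, 0, 1, 1, 0) / sqrt(c(1, 1, 1, 2, 2, 1)),
                c(0, 1, 0, 1, 0, 1) / sqrt(c(1, 1, 1, 2, 2, 1)),
                c(0, 0, 1, 0, 1, 1) / sqrt(c(1, 1, 1, 2, 2, 1)))))
  set.seed(35)
  s <- voxelSignal(sch7, randomSPD()) * exp(rnorm(7, 0, 0.05))
  fit <- fitDTI(seriesFromSignal(s, sch7), algorithm = "OLS")
  expect_equal(rmsErrorMap(fit)[1, 1, 1], 0)
})

test_that("degenerate designs and mutual exclusions are rejected", {
  # coplanar directions: singular design
  g <- rbind(cos(seq(0, pi, length.out = 8)),
             sin(seq(0, pi, length.out = 8)), rep(0, 8))
  sch <- gradientScheme(c(0, rep(900, 8)), cbind(c(0, 0, 0), g))
  dwi <- dwiSeries(array(100, c(1, 1, 1, 9)), sch)
  expect_error(fitDTI(dwi, algorithm = "OLS"), "coplanar|singular")
  # Rician-aware is NLLS-only and incompatible with prior RBC
  sch2 <- oneShellScheme()
  dwi2 <- seriesFromSignal(voxelSignal(sch2, wmTensor()), sch2)
  ne <- new("NoiseEstimate", sigma = 5, ncoils = 1L, method = "standard",
            nSamples = 0L)
  expect_error(fitDTI(dwi2, algorithm = "OLS", noise = ne,
                      ricianAware = TRUE), "NLLS")
  rbc <- ricianBiasCorrect(dwi2, ne)
  expect_error(fitDTI(rbc, algorithm = "NLLS", noise = ne,
                      ricianAware = TRUE), "RBC")
})

test_that("Rician-aware NLLS reduces MD bias at SNR 25", {
  sch <- twoShellScheme()
  ph <- synthesizePhantom(list(grid = c(5, 5, 4), scheme = sch,
                               layout = "uniform",
                               regions = list(list(D = wmTensor()))))
  truthMD <- mean(diag(wmTensor()))
  sigma <- 1000 / 25
  noisy <- addNoise(ph$dwi, sigma, 1L, seed = 11)
  ne <- new("NoiseEstimate", sigma = sigma, ncoils = 1L,
            method = "standard", nSamples = 0L)
  md_plain <- median(dtiMetrics(fitDTI(noisy, algorithm = "NLLS"))$MD)
  md_rice <- median(dtiMetrics(fitDTI(noisy, algorithm = "NLLS", noise = ne,
                                      ricianAware = TRUE))$MD)
  expect_lt(abs(md_rice - truthMD), abs(md_plain - truthMD))
})
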