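test_that("scheme presets reproduce the protocol layouts", {
  sch <- schemePreset("brain", seed = 1L)
  expect_identical(nVolumes(sch), 153L)          # 18 + 30 + 45 + 60
  expect_identical(sum(shellIds(sch) == 0L), 18L)
  tab <- table(round(bValues(sch)[shellIds(sch) > 0]))
  expect_identical(as.integer(tab[c("600", "1100", "2500")]),
                   c(30L, 45L, 60L))
})

test_that("repulsion directions are unit, separated, and deterministic", {
  d30 <- dwikit:::repulsionDirections(30, seed = 3L)
  expect_lt(max(abs(sqrt(colSums(d30^2)) - 1)), 1e-12)
  ang30 <- acos(pmin(abs(crossprod(d30)), 1)) * 180 / pi
  diag(ang30) <- NA
  d12 <- dwikit:::repulsionDirections(12, seed = 3L)
  ang12 <- acos(pmin(abs(crossprod(d12)), 1)) * 180 / pi
  diag(ang12) <- NA
  expect_gt(min(ang12, na.rm = TRUE), min(ang30, na.rm = TRUE))
  expect_gt(min(ang30, na.rm = TRUE), 10)
  expect_identical(dwikit:::repulsionDirections(30, seed = 3L), d30)
})

test_that("6 directions reach the brute-force minimum-energy arrangement", {
  e1 <- dwikit:::pointsetEnergy(dwikit:::repulsionDirections(6, seed = 1L))
  e_best <- min(vapply(2:8, function(s)
    dwikit:::pointsetEnergy(
      dwikit:::repulsionDirections(6, seed = 100 + s, n_restart = 3L)),
    numeric(1)))
  expect_lt(abs(e1 - e_best), 1e-6)
})

test_that("uniform isotropic phantoms give identical within-shell volumes", {
  sch <- oneShellScheme()
  ph <- synthesizePhantom(list(grid = c(3, 3, 2), scheme = sch,
                               layout = "uniform",
                               regions = list(list(D = 1e-3 * diag(3)))))
  dw <- which(shellIds(sch) == 1L)
  vols <- apply(dwiData(ph$dwi)[, , , dw, drop = FALSE], 4, identity)
  expect_lt(max(vols) - min(vols), 1e-10)
})

test_that("phantom DKI signals round trip through the fitter exactly", {
  sch <- twoShellScheme()
  tw <- wmKurtosis()
  ph <- synthesizePhantom(list(grid = c(2, 2, 1), scheme = sch,
                               layout = "uniform",
                               regions = list(list(D = tw$D, W = tw$w))))
  fit <- fitDKI(ph$dwi, algorithm = "OLS")
  expect_lt(max(abs(fitCoefficients(fit)[2, 2, 1, 8:22] - tw$w)), 1e-8)
})

test_that("standard-model phantoms are cumulant-consistent at moderate b", {
  sch <- twoShellScheme()                        # b_max = 2500 s/mm^2
  p <- StandardModelParams(0.55, 2.0e-3, 1.3e-3, 0.6e-3, 10)
  # beyond the cumulant-faithful range the generator warns but proceeds
  expect_warning(
    ph <- synthesizePhantom(list(grid = c(1, 1, 1), scheme = sch,
                                 layout = "uniform", regions = list(p))),
    "cumulant")
  fit <- fitDKI(ph$dwi, algorithm = "OLS")
  km <- dkiMetrics(fit); dm <- dtiMetrics(fit)
  fm <- smForwardMoments(p)
  # diffusivities are cumulant-faithful to 1%; the O(b^3) truncation of the
  # exact convolution signal concentrates in the kurtosis amplitudes
  expect_lt(abs(dm$AD[1] - fm$AD) / fm$AD, 0.01)
  expect_lt(abs(dm$RD[1] - fm$RD) / fm$RD, 0.01)
  expect_lt(abs(km$MW[1] - fm$MW) / fm$MW, 0.05)
  expect_lt(abs(km$AW[1] - fm$AW) / fm$AW, 0.12)
  expect_lt(abs(km$RW[1] - fm$RW) / fm$RW, 0.12)
})

test_that("noise generator matches the noncentral-chi moment identities", {
  set.seed(61)
  # Rayleigh mean at A = 0, n = 1
  s0 <- dwikit:::ncChiSample(rep(0, 1e6), 7, 1)
  expect_lt(abs(mean(s0) - 7 * sqrt(pi / 2)) / (7 * sqrt(pi / 2)), 0.01)
  # E[S^2] - A^2 = 2 n sigma^2 for n in {1, 4}; A/sigma = 5 keeps the
  # Monte-Carlo error of the left side well below the 1% band
  for (n in c(1L, 4L)) {
    s <- dwikit:::ncChiSample(rep(50, 1e6), 10, n)
    expect_lt(abs(mean(s^2) - 50^2 - 2 * n * 100) / (2 * n * 100), 0.01)
  }
  # sigma = 0 is the identity
  sch <- gradientScheme(rep(0, 2), matrix(0, 3, 2))
  dwi <- dwiSeries(array(5, c(2, 2, 1, 2)), sch)
  expect_identical(dwiData(addNoise(dwi, 0, 1L, seed = 1)), dwiData(dwi))
})

test_that("noise is bit-reproducible given the seed", {
  sch <- gradientScheme(rep(0, 3), matrix(0, 3, 3))
  dwi <- dwiSeries(array(100, c(4, 4, 2, 3)), sch)
  a <- addNoise(dwi, 10, 2L, seed = 123)
  b <- addNoise(dwi, 10, 2L, seed = 123)
  expect_identical(dwiData(a), dwiData(b))
  expect_false(identical(dwiData(a),
                         dwiData(addNoise(dwi, 10, 2L, seed = 124))))
})

test_that("outlier injection selects slices at the requested rate", {
  sch <- makeScheme(list(c(1000, 55)), n_b0 = 5L, seed = 2L)
  dwi <- dwiSeries(array(100, c(3, 3, 14, 60)), sch)
  # rate 0: identity, empty log
  o0 <- injectOutliers(dwi, 0, 0.5, seed = 1)
  expect_identical(dwiData(o0$dwi), dwiData(dwi))
  expect_identical(nrow(o0$log), 0L)
  # rate 1: every slice attenuated
  o1 <- injectOutliers(dwi, 1, 0.5, seed = 1)
  expect_true(all(dwiData(o1$dwi) == 50))
  expect_identical(nrow(o1$log), 60L * 14L)
  # binomial count at rate 0.2 over 840 slots (within 3 sigma)
  o2 <- injectOutliers(dwi, 0.2, 0.5, seed = 5)
  expect_false(any(duplicated(o2$log[, c("volume", "slice")])))
  n <- 60 * 14
  expect_lt(abs(nrow(o2$log) - 0.2 * n), 3 * sqrt(n * 0.2 * 0.8))
})

test_that("robust fitting's advantage grows with contamination", {
  sch <- oneShellScheme()
  ph <- synthesizePhantom(list(grid = c(4, 4, 4), scheme = sch,
                               layout = "uniform",
                               regions = list(list(D = wmTensor()))))
  truthFA <- tensorScalarMetrics(wmTensor())$FA
  noisy <- addNoise(ph$dwi, 20, 1L, seed = 71)
  err <- function(dwi, alg)
    mean(abs(dtiMetrics(fitDTI(dwi, algorithm = alg))$FA - truthFA))
  adv <- sapply(c(0, 0.1, 0.2), function(rate) {
    d <- if (rate == 0) noisy else
      injectOutliers(noisy, rate, 0.4, seed = 72)$dwi
    err(d, "OLS") - err(d, "ROB")
  })
  expect_gt(adv[3], adv[1])                       # advantage grows
  expect_gt(adv[3], 0)
  expect_lt(abs(adv[1]), 0.02)                    # vanishes without outliers
})

test_that("noise generator and estimator are mutually consistent", {
  sch <- gradientScheme(rep(0, 10), matrix(0, 3, 10))
  dwi <- dwiSeries(array(0, c(10, 10, 10, 10)), sch)
  noisy <- addNoise(dwi, 12, 1L, seed = 73)
  est <- estimateNoiseStandard(noisy, array(1, c(10, 10, 10)), 1L)
  expect_lt(abs(noiseSigma(est) - 12) / 12, 0.02)
})
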