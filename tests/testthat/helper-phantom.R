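# shared fixtures, all built in code

# small 2-shell scheme suitable for DTI and DKI fitting
twoShellScheme <- function(seed = 1L)
  makeScheme(list(c(1000, 30), c(2500, 30)), n_b0 = 5L, seed = seed)

oneShellScheme <- function(seed = 1L)
  makeScheme(list(c(1000, 30)), n_b0 = 5L, seed = seed)

# prolate axisymmetric ground truths (white-matter-like diffusivities)
wmTensor <- function(axis = c(1, 0, 0))
  dwikit:::axiTensors(axis, 1.7e-3, 0.4e-3, 0, 0, 0)$D

wmKurtosis <- function(axis = c(1, 0, 0), MW = 0.9, AW = 0.6, RW = 1.6)
  dwikit:::axiTensors(axis, 1.7e-3, 0.4e-3, MW, AW, RW)

# noiseless single-voxel signals from tensor(+kurtosis) ground truth
voxelSignal <- function(sch, D, W = NULL, S0 = 1000) {
  b <- bValues(sch); g <- bVectors(sch)
  s <- S0 * exp(-b * colSums(g * (D %*% g)))
  if (!is.null(W)) {
    md <- mean(diag(D))
    s <- s * exp(b^2 / 6 * md^2 * as.numeric(dwikit:::wDesignRow(g) %*% W))
  }
  s
}

seriesFromSignal <- function(s, sch, grid = c(1, 1, 1)) {
  dwiSeries(array(rep(s, each = prod(grid)), c(grid, length(s))), sch)
}

randomRotation <- function() {
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  cbind(c(1 - 2 * (q[3]^2 + q[4]^2), 2 * (q[2] * q[3] + q[1] * q[4]),
          2 * (q[2] * q[4] - q[1] * q[3])),
        c(2 * (q[2] * q[3] - q[1] * q[4]), 1 - 2 * (q[2]^2 + q[4]^2),
          2 * (q[3] * q[4] + q[1] * q[2])),
        c(2 * (q[2] * q[4] + q[1] * q[3]), 2 * (q[3] * q[4] - q[1] * q[2]),
          1 - 2 * (q[2]^2 + q[3]^2)))
}

randomSPD <- function(scale = 1.7e-3) {
  R <- randomRotation()
  ev <- sort(runif(3, 0.1, 1), decreasing = TRUE) * scale
  R %*% diag(ev) %*% t(R)
}

# admissible standard-model parameter draw (plus-branch territory)
randomSMParams <- function() {
  f <- runif(1, 0.25, 0.85)
  Da <- runif(1, 1.6e-3, 2.8e-3)
  DePar <- Da * runif(1, 0.4, 0.9)
  DePerp <- DePar * runif(1, 0.3, 0.9)
  kappa <- runif(1, 1, 40)
  StandardModelParams(f, Da, DePar, DePerp, kappa)
}
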