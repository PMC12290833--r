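# antipodally symmetric electrostatic energy of unit directions (3 x n)
pointsetEnergy <- function(x) {
  n <- ncol(x)
  e <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d1 <- sqrt(sum((x[, i] - x[, j])^2))
    d2 <- sqrt(sum((x[, i] + x[, j])^2))
    e <- e + 1 / max(d1, 1e-12) + 1 / max(d2, 1e-12)
  }
  e
}

# minimize the antipodal electrostatic energy over n directions (angles
# parameterization, BFGS with analytic gradient); deterministic given seed
repulsionDirections <- function(n_dirs, seed = 1L, n_restart = 2L) {
  if (n_dirs == 1L) return(matrix(c(0, 0, 1), 3, 1))
  obj <- function(ang) {
    th <- ang[1:n_dirs]; ph <- ang[-(1:n_dirs)]
    x <- rbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    pointsetEnergy(x)
  }
  grad <- function(ang) {
    th <- ang[1:n_dirs]; ph <- ang[-(1:n_dirs)]
    x <- rbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
    Fm <- matrix(0, 3, n_dirs)
    for (i in seq_len(n_dirs)) for (j in seq_len(n_dirs)) {
      if (i == j) next
      dm <- x[, i] - x[, j]; dp <- x[, i] + x[, j]
      Fm[, i] <- Fm[, i] - dm / max(sum(dm^2)^1.5, 1e-18) -
        dp / max(sum(dp^2)^1.5, 1e-18)
    }
    dth <- rbind(cos(th) * cos(ph), cos(th) * sin(ph), -sin(th))
    dph <- rbind(-sin(th) * sin(ph), sin(th) * cos(ph), 0 * th)
    c(colSums(Fm * dth), colSums(Fm * dph))
  }
  best <- NULL
  set.seed(as.integer(seed))
  for (r in seq_len(n_restart)) {
    z <- runif(n_dirs, -1, 1)
    th0 <- acos(z)
    ph0 <- runif(n_dirs, 0, 2 * pi)
    o <- optim(c(th0, ph0), obj, grad, method = "BFGS",
               control = list(maxit = 500, reltol = 1e-14))
    if (is.null(best) || o$value < best$value) best <- o
  }
  th <- best$par[1:n_dirs]; ph <- best$par[-(1:n_dirs)]
  x <- rbind(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  sweep(x, 2, sqrt(colSums(x^2)), "/")
}

#' Build a multi-shell gradient scheme with uniform sphere coverage
#'
#' Per-shell directions are placed by minimizing the antipodally symmetric
#' electrostatic-repulsion energy on the sphere (deterministic given the
#' seed). b0 volumes are placed at the start of the series.
#'
#' @param shells list of \code{c(b, n_dirs)} pairs (b in s/mm^2); any shell
#'   meant for tensor fitting needs n_dirs >= 6.
#' @param n_b0 number of b = 0 volumes.
#' @param seed RNG seed for the repulsion initialization.
#' @param b0Threshold b0 cutoff passed to the scheme.
#' @return a \linkS4class{GradientScheme}.
#' @export
makeScheme <- function(shells, n_b0 = 1L, seed = 1L, b0Threshold = 50) {
  bvals <- rep(0, n_b0)
  bvecs <- matrix(0, 3, n_b0)
  shells <- shells[order(vapply(shells, `[`, numeric(1), 1))]
  for (k in seq_along(shells)) {
    b <- shells[[k]][1]; nd <- as.integer(shells[[k]][2])
    dirs <- repulsionDirections(nd, seed = seed + k)
    bvals <- c(bvals, rep(b, nd))
    bvecs <- cbind(bvecs, dirs)
  }
  gradientScheme(bvals, bvecs, b0Threshold = b0Threshold)
}

#' Table-4-style phantom scheme presets
#' @param preset "brain", "cord", or "exvivo".
#' @param seed RNG seed.
#' @export
schemePreset <- function(preset = c("brain", "cord", "exvivo"), seed = 1L) {
  preset <- match.arg(preset)
  layout <- switch(preset,
    brain = list(n_b0 = 18L, shells = list(c(600, 30), c(1100, 45),
                                           c(2500, 60))),
    cord = list(n_b0 = 11L, shells = list(c(500, 30), c(1000, 30),
                                          c(1500, 30))),
    exvivo = list(n_b0 = 36L, shells = list(c(550, 30), c(1100, 75),
                                            c(2200, 45), c(2500, 60),
                                            c(5000, 60))))
  makeScheme(layout$shells, layout$n_b0, seed = seed)
}

# noiseless signal vector for one region ground truth
regionSignal <- function(gt, scheme, S0 = 1000) {
  b <- bValues(scheme); g <- bVectors(scheme)
  if (is(gt, "StandardModelParams"))
    return(S0 * smSignal(gt, b, g))
  if (!is.list(gt)) stop("region ground truth must be a list or ",
                         "StandardModelParams")
  if (!is.null(gt$S0)) S0 <- gt$S0
  D <- if (is.matrix(gt$D)) gt$D else tensorFromCoef(gt$D)
  dg <- colSums(g * (D %*% g))
  s <- S0 * exp(-b * dg)
  if (!is.null(gt$W)) {
    md <- mean(diag(D))
    s <- s * exp(b^2 / 6 * md^2 * as.numeric(wDesignRow(g) %*% gt$W))
  }
  s
}

#' Synthesize a noiseless phantom dataset with known ground truth
#'
#' Region generators reuse the fitters' forward models, so noiseless round
#' trips are exact by construction: "dti" regions follow
#' S0 exp(-b g' D g), "dki" regions add the (b^2/6) MD^2 W(g) term, and
#' StandardModelParams regions use the exact Watson spherical convolution.
#' Layouts: "uniform" (one region), "two-region" (split along x), and
#' "crossing-band" (a central band along y mixing the signals of two
#' populations 50/50 at the signal level, beyond every single-fiber model's
#' validity).
#'
#' @param spec list with: \code{grid} (c(nx, ny, nz)), \code{voxel_size}
#'   [mm], \code{layout}, \code{regions} (list of ground truths: either a
#'   \linkS4class{StandardModelParams} or \code{list(D =, W =, S0 =)}),
#'   \code{scheme} (a \linkS4class{GradientScheme}), optional \code{S0}.
#' @return list: \code{dwi} (noiseless \linkS4class{DWISeries}),
#'   \code{region} (3D region-id array; 3 = mixed band), \code{regions}
#'   (the ground truths), \code{scheme}.
#' @export
synthesizePhantom <- function(spec) {
  grid <- spec$grid
  vs <- if (is.null(spec$voxel_size)) c(2, 2, 2) else spec$voxel_size
  layout <- if (is.null(spec$layout)) "uniform" else spec$layout
  S0 <- if (is.null(spec$S0)) 1000 else spec$S0
  sch <- spec$scheme
  nvol <- nVolumes(sch)
  sigs <- lapply(spec$regions, regionSignal, scheme = sch, S0 = S0)
  region <- array(1L, grid)
  if (layout == "two-region") {
    if (length(sigs) < 2L) stop("two-region layout needs 2 region truths")
    region[(grid[1] %/% 2 + 1):grid[1], , ] <- 2L
  } else if (layout == "crossing-band") {
    if (length(sigs) < 2L) stop("crossing-band layout needs 2 populations")
    band <- seq.int(max(1L, round(grid[2] / 3) + 1L),
                    min(grid[2], round(2 * grid[2] / 3)))
    region[, band, ] <- 3L
    sigs[[3]] <- 0.5 * sigs[[1]] + 0.5 * sigs[[2]]
  }
  dat <- array(0, c(grid, nvol))
  for (rid in sort(unique(as.integer(region)))) {
    sel <- region == rid
    nv <- sum(sel)
    block <- matrix(rep(sigs[[rid]], each = nv), nrow = nv)
    for (k in seq_len(nvol)) {
      vol <- dat[, , , k]
      vol[sel] <- block[, k]
      dat[, , , k] <- vol
    }
  }
  list(dwi = dwiSeries(dat, sch, voxelSize = vs),
       region = region, regions = spec$regions, scheme = sch)
}

# noncentral-chi sample: magnitude of 2 n independent Gaussian channels with
# the noiseless amplitude in the first channel's mean (exact for any n)
ncChiSample <- function(A, sigma, ncoils = 1L) {
  if (sigma == 0) return(A)
  n <- length(A)
  # first complex channel: real part carries the signal
  ss <- (A + rnorm(n, 0, sigma))^2 + rnorm(n, 0, sigma)^2
  if (ncoils > 1L)
    for (k in seq_len(2L * (ncoils - 1L))) ss <- ss + rnorm(n, 0, sigma)^2
  sqrt(ss)
}

#' Add noncentral-chi (Rician for n = 1) noise to a series
#'
#' Synthesized channel-wise: the magnitude of 2 ncoils independent Gaussian
#' channels of standard deviation sigma, with the noiseless signal as the
#' first channel's mean. This is exactly noncentral chi for any n and
#' validates the second-moment identity E[S^2] = A^2 + 2 n sigma^2 by
#' construction.
#'
#' @param dwi a \linkS4class{DWISeries}.
#' @param sigma channel noise standard deviation (>= 0; 0 is the identity).
#' @param ncoils effective coil count n.
#' @param seed RNG seed (mandatory).
#' @return noisy \linkS4class{DWISeries}.
#' @export
addNoise <- function(dwi, sigma, ncoils = 1L, seed) {
  stopifnot(sigma >= 0, !missing(seed))
  if (sigma == 0) return(dwi)
  set.seed(as.integer(seed))
  out <- dwi
  out@data <- array(ncChiSample(as.numeric(dwi@data), sigma, ncoils),
                    dim = dim(dwi@data))
  out
}

#' Inject slice-wise signal-dropout outliers
#'
#' Each (volume, slice) pair is independently selected with probability
#' \code{rate}; selected slices are multiplied by \code{attenuation}
#' (multiplicative dropout, modelling cardiac-pulsation signal loss).
#'
#' @param dwi a \linkS4class{DWISeries}.
#' @param rate selection probability in [0, 1].
#' @param attenuation multiplicative factor in [0, 1).
#' @param seed RNG seed (mandatory).
#' @return list: \code{dwi} (corrupted series), \code{log} (data.frame with
#'   volume, slice, attenuation; unique rows).
#' @export
injectOutliers <- function(dwi, rate, attenuation, seed) {
  stopifnot(rate >= 0, rate <= 1, attenuation >= 0, attenuation < 1,
            !missing(seed))
  set.seed(as.integer(seed))
  d <- dim(dwi@data)
  out <- dwi
  hits <- which(matrix(runif(d[4] * d[3]) < rate, d[4], d[3]),
                arr.ind = TRUE)
  if (nrow(hits)) {
    for (r in seq_len(nrow(hits)))
      out@data[, , hits[r, 2], hits[r, 1]] <-
        out@data[, , hits[r, 2], hits[r, 1]] * attenuation
  }
  list(dwi = out,
       log = data.frame(volume = if (nrow(hits)) hits[, 1] else integer(),
                        slice = if (nrow(hits)) hits[, 2] else integer(),
                        attenuation = rep(attenuation, nrow(hits))))
}
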