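#' @import methods
#' @importFrom stats median mad sd integrate uniroot rnorm runif rbinom quantile
#' @importFrom utils head packageVersion write.csv
NULL

#' Gradient scheme: b-values, directions, and shell assignment
#'
#' The acquisition contract every fitter consumes: one b-value [s/mm^2] and one
#' unit gradient direction per volume, plus an integer shell label. Shell 0 is
#' the b ~ 0 shell; nonzero shells are ordered by ascending mean b-value.
#'
#' @slot bvals numeric vector of diffusion weightings [s/mm^2], one per volume.
#' @slot bvecs 3 x N matrix of gradient directions in the image frame; unit
#'   norm for every volume with b above \code{b0Threshold}.
#' @slot shellId integer shell label per volume (0 = b0 shell).
#' @slot b0Threshold scalar [s/mm^2] below which a volume counts as b0.
#' @export
setClass("GradientScheme",
  representation(bvals = "numeric", bvecs = "matrix",
                 shellId = "integer", b0Threshold = "numeric"))

setValidity("GradientScheme", function(object) {
  n <- length(object@bvals)
  if (!all(is.finite(object@bvals))) return("non-finite bvals")
  if (any(object@bvals < 0)) return("bvals must be >= 0")
  if (!is.numeric(object@bvecs) || nrow(object@bvecs) != 3L ||
      ncol(object@bvecs) != n)
    return("bvecs must be a 3 x N matrix matching length(bvals)")
  if (length(object@shellId) != n) return("shellId length mismatch")
  dw <- object@bvals > object@b0Threshold
  if (any(dw)) {
    nrm <- sqrt(colSums(object@bvecs[, dw, drop = FALSE]^2))
    if (any(abs(nrm - 1) > 1e-3))
      return("zero or non-unit direction at nonzero b")
  }
  TRUE
})

#' 4D diffusion-weighted series bound to a gradient scheme
#'
#' @slot data 4D non-negative intensity array (X, Y, Z, N).
#' @slot voxelSize voxel dimensions [mm], length 3, all positive.
#' @slot affine 4 x 4 voxel-to-world transform.
#' @slot scheme a \linkS4class{GradientScheme} with N entries.
#' @slot labels character vector of processing-step labels already applied
#'   (BIDS \code{desc} vocabulary), in application order.
#' @export
setClass("DWISeries",
  representation(data = "array", voxelSize = "numeric", affine = "matrix",
                 scheme = "GradientScheme", labels = "character"))

setValidity("DWISeries", function(object) {
  d <- dim(object@data)
  if (length(d) != 4L) return("data must be a 4D array")
  if (d[4] != length(object@scheme@bvals))
    return(sprintf("4th dimension (%d) must equal scheme length (%d)",
                   d[4], length(object@scheme@bvals)))
  if (length(object@voxelSize) != 3L || any(object@voxelSize <= 0))
    return("voxelSize must be 3 positive values")
  if (!all(dim(object@affine) == c(4L, 4L))) return("affine must be 4 x 4")
  TRUE
})

#' Noise level estimate for magnitude dMRI data
#'
#' A single global noise standard deviation (homogeneous-variance assumption)
#' plus the effective number of receiver coil elements n that contributed to
#' the measured signal. Feeds Rician bias correction, Rician-aware NLLS, and
#' the WLS/robust weighting.
#'
#' @slot sigma noise standard deviation [signal units], > 0.
#' @slot ncoils effective coil count n (integer >= 1).
#' @slot method "standard" or "repeated_measures".
#' @slot nSamples number of voxel samples the estimate used.
#' @export
setClass("NoiseEstimate",
  representation(sigma = "numeric", ncoils = "integer",
                 method = "character", nSamples = "integer"))

setValidity("NoiseEstimate", function(object) {
  if (length(object@sigma) != 1L || !is.finite(object@sigma) ||
      object@sigma <= 0) return("sigma must be a single positive number")
  if (object@ncoils < 1L) return("ncoils must be >= 1")
  TRUE
})

#' Per-voxel diffusion tensor fit
#'
#' Coefficient order per voxel: lnS0, Dxx, Dxy, Dxz, Dyy, Dyz, Dzz [mm^2/s]
#' (6 independent tensor coefficients).
#'
#' @slot coef 4D array (X, Y, Z, 7).
#' @slot algorithm one of "OLS", "WLS", "ROB", "NLLS".
#' @slot rmsError 3D per-voxel root-mean-square model-fit error rms(eps),
#'   computed on the residuals in the fitting domain.
#' @slot converged 3D logical array (always TRUE for linear algorithms).
#' @slot mask 3D logical analysis mask.
#' @export
setClass("TensorFit",
  representation(coef = "array", algorithm = "character", rmsError = "array",
                 converged = "array", mask = "array"))

setValidity("TensorFit", function(object) {
  if (dim(object@coef)[4] != 7L) return("TensorFit needs 7 coefficients")
  if (!object@algorithm %in% c("OLS", "WLS", "ROB", "NLLS"))
    return("unknown algorithm")
  rms <- object@rmsError[object@mask]
  if (any(!is.finite(rms) | rms < 0))
    return("rmsError must be finite and >= 0 inside the mask")
  TRUE
})

#' Per-voxel diffusion kurtosis fit
#'
#' Coefficients per voxel: lnS0, the 6 tensor coefficients, and the 15
#' independent kurtosis tensor coefficients W_ijkl (dimensionless,
#' MD^2-scaled convention) in lexicographic index order (see
#' \code{\link{kurtosisIndexTable}}).
#'
#' @slot coef 4D array (X, Y, Z, 22).
#' @slot algorithm "OLS" or "NLLS".
#' @slot rmsError 3D rms model-fit error map.
#' @slot converged 3D logical.
#' @slot mask 3D logical analysis mask.
#' @export
setClass("KurtosisFit",
  representation(coef = "array", algorithm = "character", rmsError = "array",
                 converged = "array", mask = "array"))

setValidity("KurtosisFit", function(object) {
  if (dim(object@coef)[4] != 22L)
    return("KurtosisFit needs 22 coefficients (lnS0 + 6 D + 15 W)")
  TRUE
})

#' Per-voxel axisymmetric diffusion kurtosis fit
#'
#' Eight independent parameters per voxel: lnS0; the symmetry-axis polar
#' angles (theta, phi) with the antipodal gauge theta in [0, pi/2]; the
#' parallel and perpendicular diffusivities Dpar, Dperp [mm^2/s]; and the
#' mean, axial, and radial kurtosis-tensor amplitudes MW, AW, RW
#' (dimensionless).
#'
#' @slot coef 4D array (X, Y, Z, 8) ordered
#'   (lnS0, theta, phi, Dpar, Dperp, MW, AW, RW).
#' @slot rmsError 3D rms model-fit error map.
#' @slot converged 3D logical.
#' @slot mask 3D logical analysis mask.
#' @export
setClass("AxiKurtosisFit",
  representation(coef = "array", rmsError = "array", converged = "array",
                 mask = "array"))

setValidity("AxiKurtosisFit", function(object) {
  if (dim(object@coef)[4] != 8L)
    return("AxiKurtosisFit needs 8 parameters")
  TRUE
})

#' Two-compartment Watson standard-model parameters
#'
#' Intra-axonal "sticks" of zero radius with diffusivity Da and water fraction
#' f; an axisymmetric extra-axonal Gaussian compartment (DePar, DePerp); axon
#' orientations Watson-distributed with concentration kappa about axis mu.
#'
#' @slot f axonal water fraction in [0, 1].
#' @slot Da intra-axonal diffusivity [mm^2/s].
#' @slot DePar,DePerp extra-axonal diffusivities [mm^2/s].
#' @slot kappa Watson concentration (>= 0; 0 = isotropic orientations).
#' @slot mu unit symmetry axis (length 3).
#' @export
setClass("StandardModelParams",
  representation(f = "numeric", Da = "numeric", DePar = "numeric",
                 DePerp = "numeric", kappa = "numeric", mu = "numeric"))

setValidity("StandardModelParams", function(object) {
  if (object@f < 0 || object@f > 1) return("f must lie in [0, 1]")
  if (any(c(object@Da, object@DePar, object@DePerp) < 0))
    return("diffusivities must be >= 0")
  if (object@kappa < 0) return("kappa must be >= 0 (oblate Watson unsupported)")
  if (abs(sqrt(sum(object@mu^2)) - 1) > 1e-6) return("mu must be unit norm")
  TRUE
})

#' @export
StandardModelParams <- function(f, Da, DePar, DePerp, kappa,
                                mu = c(0, 0, 1)) {
  if (DePerp > DePar)
    warning("DePerp > DePar: unusual for white matter, proceeding")
  new("StandardModelParams", f = f, Da = Da, DePar = DePar,
      DePerp = DePerp, kappa = kappa, mu = mu / sqrt(sum(mu^2)))
}
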