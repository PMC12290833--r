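#' @rdname accessors
#' @export
setGeneric("bValues", function(x) standardGeneric("bValues"))
#' @rdname accessors
#' @export
setGeneric("bVectors", function(x) standardGeneric("bVectors"))
#' @rdname accessors
#' @export
setGeneric("shellIds", function(x) standardGeneric("shellIds"))
#' @rdname accessors
#' @export
setGeneric("nVolumes", function(x) standardGeneric("nVolumes"))
#' @rdname accessors
#' @export
setGeneric("dwiData", function(x) standardGeneric("dwiData"))
#' @rdname accessors
#' @export
setGeneric("scheme", function(x) standardGeneric("scheme"))
#' @rdname accessors
#' @export
setGeneric("descLabels", function(x) standardGeneric("descLabels"))
#' @rdname accessors
#' @export
setGeneric("fitCoefficients", function(x) standardGeneric("fitCoefficients"))
#' @rdname accessors
#' @export
setGeneric("rmsErrorMap", function(x) standardGeneric("rmsErrorMap"))
#' @rdname accessors
#' @export
setGeneric("noiseSigma", function(x) standardGeneric("noiseSigma"))
#' @rdname accessors
#' @export
setGeneric("nCoils", function(x) standardGeneric("nCoils"))

#' Accessors for dwikit S4 objects
#'
#' Small read-only accessors so downstream code never touches slots directly.
#'
#' @param x a dwikit S4 object.
#' @name accessors
NULL

#' @rdname accessors
setMethod("bValues", "GradientScheme", function(x) x@bvals)
#' @rdname accessors
setMethod("bVectors", "GradientScheme", function(x) x@bvecs)
#' @rdname accessors
setMethod("shellIds", "GradientScheme", function(x) x@shellId)
#' @rdname accessors
setMethod("nVolumes", "GradientScheme", function(x) length(x@bvals))
#' @rdname accessors
setMethod("bValues", "DWISeries", function(x) x@scheme@bvals)
#' @rdname accessors
setMethod("bVectors", "DWISeries", function(x) x@scheme@bvecs)
#' @rdname accessors
setMethod("nVolumes", "DWISeries", function(x) dim(x@data)[4])
#' @rdname accessors
setMethod("dwiData", "DWISeries", function(x) x@data)
#' @rdname accessors
setMethod("scheme", "DWISeries", function(x) x@scheme)
#' @rdname accessors
setMethod("descLabels", "DWISeries", function(x) x@labels)
#' @rdname accessors
setMethod("fitCoefficients", "TensorFit", function(x) x@coef)
#' @rdname accessors
setMethod("fitCoefficients", "KurtosisFit", function(x) x@coef)
#' @rdname accessors
setMethod("fitCoefficients", "AxiKurtosisFit", function(x) x@coef)
#' @rdname accessors
setMethod("rmsErrorMap", "TensorFit", function(x) x@rmsError)
#' @rdname accessors
setMethod("rmsErrorMap", "KurtosisFit", function(x) x@rmsError)
#' @rdname accessors
setMethod("rmsErrorMap", "AxiKurtosisFit", function(x) x@rmsError)
#' @rdname accessors
setMethod("noiseSigma", "NoiseEstimate", function(x) x@sigma)
#' @rdname accessors
setMethod("nCoils", "NoiseEstimate", function(x) x@ncoils)

setMethod("show", "GradientScheme", function(object) {
  sh <- split(object@bvals, object@shellId)
  cat("GradientScheme with", length(object@bvals), "volumes,",
      length(sh), "shells\n")
  for (s in names(sh))
    cat(sprintf("  shell %s: b ~ %.0f s/mm^2 (%d dirs)\n",
                s, mean(sh[[s]]), length(sh[[s]])))
})

setMethod("show", "DWISeries", function(object) {
  d <- dim(object@data)
  cat(sprintf("DWISeries %d x %d x %d x %d, voxels %.2f x %.2f x %.2f mm\n",
              d[1], d[2], d[3], d[4], object@voxelSize[1],
              object@voxelSize[2], object@voxelSize[3]))
  if (length(object@labels))
    cat("  desc labels:", paste(object@labels, collapse = "-"), "\n")
  show(object@scheme)
})

setMethod("show", "NoiseEstimate", function(object) {
  cat(sprintf("NoiseEstimate: sigma = %.4g (%s, n = %d coils, %d samples)\n",
              object@sigma, object@method, object@ncoils, object@nSamples))
})

setMethod("show", "TensorFit", function(object) {
  cat(sprintf("TensorFit (%s): %d voxels in mask, median rms(eps) = %.4g\n",
              object@algorithm, sum(object@mask),
              median(object@rmsError[object@mask])))
})

setMethod("show", "KurtosisFit", function(object) {
  cat(sprintf("KurtosisFit (%s): %d voxels in mask (6 D + 15 W coefficients)\n",
              object@algorithm, sum(object@mask)))
})

setMethod("show", "AxiKurtosisFit", function(object) {
  cat(sprintf("AxiKurtosisFit (NLLS): %d voxels in mask, 8 parameters\n",
              sum(object@mask)))
})

setMethod("show", "StandardModelParams", function(object) {
  cat(sprintf(
    "StandardModelParams: f = %.3f, Da = %.3g, DePar = %.3g, DePerp = %.3g mm^2/s, kappa = %.3g\n",
    object@f, object@Da, object@DePar, object@DePerp, object@kappa))
})
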