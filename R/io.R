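#' BIDS desc-label vocabulary
#'
#' Processing-step labels used in the output filename's \code{desc} field.
#' User-defined labels can be registered per call via the \code{extra}
#' argument of \code{\link{derivativeName}}.
#' @export
bidsLabels <- c(
  "ECMOCO", "msPOAS", "RBC", "HySCO", "fmap", "COMB-WM", "COMB-AM",
  "DTI", "OLS", "WLS", "ROB", "NLLS",
  "FA", "MD", "AD", "RD", "L1", "L2", "L3", "V1", "V2", "V3",
  "DKI", "DKIax", "MK", "AK", "RK", "MW", "AW", "RW",
  "WMTI-W", "NODDI-DTI", "AWF", "DA", "DE-PARA", "DE-PERP", "KAPPA", "ODI",
  "RMS-ERROR")

#' Group b-values into shells
#'
#' Volumes whose b-values differ by at most \code{tolerance} share a shell.
#' Shell 0 contains every volume with b <= \code{b0Threshold}; the remaining
#' shells are numbered by ascending mean b-value.
#'
#' @param bvals numeric vector of b-values [s/mm^2].
#' @param tolerance grouping tolerance [s/mm^2], > 0.
#' @param b0Threshold b-value below which a volume counts as b0 [s/mm^2].
#' @return integer shell label per volume.
#' @export
groupShells <- function(bvals, tolerance = 50, b0Threshold = 50) {
  stopifnot(tolerance > 0, all(is.finite(bvals)))
  n <- length(bvals)
  id <- integer(n)
  isb0 <- bvals <= b0Threshold
  rest <- which(!isb0)
  if (length(rest)) {
    ord <- rest[order(bvals[rest])]
    grp <- integer(length(ord))
    g <- 1L
    anchor <- bvals[ord[1]]
    for (i in seq_along(ord)) {
      if (bvals[ord[i]] - anchor > tolerance) {
        g <- g + 1L
        anchor <- bvals[ord[i]]
      }
      grp[i] <- g
    }
    id[ord] <- grp
  }
  id
}

#' Construct a GradientScheme
#'
#' Normalizes directions for b > \code{b0Threshold} volumes and assigns shells
#' via \code{\link{groupShells}}.
#'
#' @param bvals numeric b-values [s/mm^2].
#' @param bvecs 3 x N direction matrix (image frame).
#' @param b0Threshold b0 cutoff [s/mm^2] (default 50).
#' @param shellTolerance shell grouping tolerance [s/mm^2] (default 50).
#' @export
gradientScheme <- function(bvals, bvecs, b0Threshold = 50,
                           shellTolerance = 50) {
  if (!all(is.finite(bvals))) stop("non-finite bvals")
  bvecs <- as.matrix(bvecs)
  if (nrow(bvecs) != 3L && ncol(bvecs) == 3L) bvecs <- t(bvecs)
  nrm <- sqrt(colSums(bvecs^2))
  dw <- bvals > b0Threshold
  if (any(dw & nrm < 1e-6))
    stop("zero direction at nonzero b (volumes: ",
         paste(which(dw & nrm < 1e-6), collapse = ", "), ")")
  bvecs[, dw] <- sweep(bvecs[, dw, drop = FALSE], 2, nrm[dw], "/")
  new("GradientScheme", bvals = as.numeric(bvals), bvecs = bvecs,
      shellId = groupShells(bvals, shellTolerance, b0Threshold),
      b0Threshold = b0Threshold)
}

#' Construct a DWISeries from in-memory data
#' @param data 4D array (X, Y, Z, N).
#' @param scheme a \linkS4class{GradientScheme}.
#' @param voxelSize voxel dimensions [mm].
#' @param affine 4 x 4 transform; default diag(voxelSize, 1).
#' @param labels processing-step labels already applied.
#' @export
dwiSeries <- function(data, scheme, voxelSize = c(1, 1, 1), affine = NULL,
                      labels = character()) {
  if (is.null(affine)) affine <- diag(c(voxelSize, 1))
  new("DWISeries", data = data, voxelSize = as.numeric(voxelSize),
      affine = affine, scheme = scheme, labels = labels)
}

readBvalBvec <- function(bval_path, bvec_path) {
  bvals <- scan(bval_path, quiet = TRUE)
  bvec_rows <- lapply(readLines(bvec_path), function(l) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    v[!is.na(v)]
  })
  bvec_rows <- bvec_rows[vapply(bvec_rows, length, 1L) > 0]
  if (length(bvec_rows) != 3L)
    stop("bvec file must have 3 rows (FSL dialect), found ",
         length(bvec_rows))
  bvecs <- do.call(rbind, bvec_rows)
  list(bvals = bvals, bvecs = bvecs)
}

#' Read a 4D diffusion-weighted dataset (NIfTI + FSL bval/bvec)
#'
#' @param image_path NIfTI-1 file (.nii or .nii.gz).
#' @param bval_path whitespace-separated b-value file (one row of N).
#' @param bvec_path FSL-dialect b-vector file (3 rows of N).
#' @param b0Threshold b0 cutoff [s/mm^2].
#' @param shellTolerance shell grouping tolerance [s/mm^2].
#' @return a \linkS4class{DWISeries} with normalized directions and shells
#'   assigned.
#' @export
readDWI <- function(image_path, bval_path, bvec_path, b0Threshold = 50,
                    shellTolerance = 50) {
  img <- RNifti::readNifti(image_path)
  dat <- array(as.numeric(img), dim = dim(img))
  if (length(dim(dat)) == 3L) dat <- array(dat, c(dim(dat), 1L))
  g <- readBvalBvec(bval_path, bvec_path)
  nvol <- dim(dat)[4]
  if (length(g$bvals) != nvol || ncol(g$bvecs) != nvol)
    stop(sprintf(
      "volume count mismatch: image has %d volumes, bval has %d, bvec has %d",
      nvol, length(g$bvals), ncol(g$bvecs)))
  sch <- gradientScheme(g$bvals, g$bvecs, b0Threshold, shellTolerance)
  pix <- attr(img, "pixdim")
  if (is.null(pix)) pix <- RNifti::pixdim(img)
  dwiSeries(dat, sch, voxelSize = abs(pix[1:3]),
            affine = structure(RNifti::xform(img), class = "matrix",
                               dim = c(4, 4)))
}

#' Render a BIDS-style derivative filename
#'
#' The labels are concatenated into the filename's \code{desc} field:
#' base \code{"_desc-"} labels joined by \code{"-"}, then the suffix. An empty
#' label list returns the base name unchanged. Appending labels stepwise is
#' equivalent to appending the concatenated list once.
#'
#' @param base filename stem, e.g. \code{"sub01_dwi"} (the final underscore
#'   suffix, e.g. \code{_dwi}, is preserved after the desc entity).
#' @param labels character vector of processing-step labels, in application
#'   order, drawn from \code{\link{bidsLabels}} or \code{extra}.
#' @param suffix file extension (default \code{".nii"}).
#' @param extra additional registered labels allowed beyond the built-in
#'   vocabulary.
#' @export
derivativeName <- function(base, labels = character(), suffix = ".nii",
                           extra = character()) {
  if (!length(labels)) return(paste0(base, suffix))
  bad <- setdiff(labels, c(bidsLabels, extra))
  if (length(bad))
    stop("labels outside the desc vocabulary: ", paste(bad, collapse = ", "))
  m <- regexpr("_[a-zA-Z0-9]+$", base)
  if (m > 0) {
    stem <- substr(base, 1, m - 1)
    tail <- substr(base, m, nchar(base))
  } else {
    stem <- base
    tail <- ""
  }
  # merge with any desc entity already present in the stem
  dm <- regexpr("_desc-[A-Za-z0-9-]+$", stem)
  if (dm > 0) {
    prev <- sub("^_desc-", "", regmatches(stem, dm))
    stem <- substr(stem, 1, dm - 1)
    labels <- c(strsplit(prev, "-")[[1]], labels)
    # re-join multi-token labels like COMB-WM conservatively: keep as-is
  }
  paste0(stem, "_desc-", paste(labels, collapse = "-"), tail, suffix)
}

#' Write a volume as a BIDS-style derivative
#'
#' Writes under \code{out_dir/derivatives/<step>/}; when the volume is a 4D
#' \linkS4class{DWISeries}, accompanying .bval and .bvec files are emitted.
#'
#' @param volume a \linkS4class{DWISeries} or a plain 3D/4D array.
#' @param base filename stem (e.g. \code{"sub01_dwi"}).
#' @param labels desc labels to append (in addition to labels the series
#'   already carries).
#' @param out_dir output root.
#' @param step derivatives subfolder name; defaults to the last label.
#' @param voxelSize,affine geometry for plain arrays.
#' @param overwrite allow clobbering an existing file.
#' @param extra additional registered labels.
#' @return invisibly, the path written.
#' @export
writeDerivative <- function(volume, base, labels = character(), out_dir,
                            step = NULL, voxelSize = c(1, 1, 1),
                            affine = NULL, overwrite = FALSE,
                            extra = character()) {
  is_series <- is(volume, "DWISeries")
  all_labels <- c(if (is_series) volume@labels else character(), labels)
  if (is.null(step))
    step <- if (length(all_labels)) all_labels[length(all_labels)] else "raw"
  dir <- file.path(out_dir, "derivatives", step)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  nm <- derivativeName(base, all_labels, suffix = ".nii", extra = extra)
  path <- file.path(dir, nm)
  if (file.exists(path) && !overwrite)
    stop("output exists (use overwrite = TRUE): ", path)
  if (is_series) {
    img <- RNifti::asNifti(volume@data)
    RNifti::pixdim(img) <- volume@voxelSize
    RNifti::writeNifti(img, path)
    stem <- sub("\\.nii(\\.gz)?$", "", path)
    writeLines(paste(format(bValues(volume), scientific = FALSE,
                            trim = TRUE), collapse = " "),
               paste0(stem, ".bval"))
    writeLines(apply(bVectors(volume), 1, function(r)
      paste(sprintf("%.10g", r), collapse = " ")), paste0(stem, ".bvec"))
  } else {
    img <- RNifti::asNifti(volume)
    RNifti::pixdim(img) <- voxelSize
    RNifti::writeNifti(img, path)
  }
  invisible(path)
}

#' Create a brain mask from tissue probability maps
#'
#' Sums the gray-matter, white-matter, and CSF probability maps and thresholds
#' the sum.
#'
#' @param tpm_gm,tpm_wm,tpm_csf aligned 3D probability maps in [0, 1].
#' @param threshold sum threshold in (0, 1); default 0.8.
#' @return 3D binary (0/1) array.
#' @export
createBrainMask <- function(tpm_gm, tpm_wm, tpm_csf, threshold = 0.8) {
  stopifnot(threshold > 0, threshold < 1)
  if (!all(dim(tpm_gm) == dim(tpm_wm)) || !all(dim(tpm_gm) == dim(tpm_csf)))
    stop("tissue probability maps are not aligned (grid mismatch)")
  s <- tpm_gm + tpm_wm + tpm_csf
  array((s > threshold) * 1L, dim = dim(tpm_gm))
}

#' Reliability mask from the rms model-fit error map
#'
#' Voxels whose rms(eps) exceeds the threshold are considered irreversibly
#' corrupted ("unreliable") and excluded (mask 0). Monotone in the threshold:
#' a larger threshold yields a superset mask.
#'
#' @param rms_error_map 3D rms(eps) map (label RMS-ERROR).
#' @param threshold positive scalar; +Inf keeps every voxel.
#' @return 3D binary (0/1) array.
#' @export
reliabilityMask <- function(rms_error_map, threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stop("threshold must be a single positive number")
  array((rms_error_map <= threshold) * 1L, dim = dim(rms_error_map))
}

#' ROI means with optional reliability masking
#'
#' Computes the mean of each map within each ROI; when reliability masks are
#' supplied, the intersection of ROI and reliability mask is applied. An empty
#' intersection yields \code{NA} with \code{empty = TRUE}, never zero.
#'
#' @param map_list named list of 3D maps (one per subject/image).
#' @param roi_masks named list of 3D binary ROI masks (recycled across maps if
#'   length one).
#' @param reliability_masks optional list parallel to \code{map_list}.
#' @param by_slice also report slice-wise (z) means.
#' @return data.frame with columns map, roi, (slice,) mean, n_voxels, empty.
#' @export
roiMean <- function(map_list, roi_masks, reliability_masks = NULL,
                    by_slice = FALSE) {
  if (!is.list(map_list)) map_list <- list(map = map_list)
  if (!is.list(roi_masks)) roi_masks <- list(roi = roi_masks)
  if (is.null(names(map_list)))
    names(map_list) <- paste0("map", seq_along(map_list))
  if (is.null(names(roi_masks)))
    names(roi_masks) <- paste0("roi", seq_along(roi_masks))
  out <- list()
  for (mi in names(map_list)) {
    m <- map_list[[mi]]
    rel <- if (is.null(reliability_masks)) NULL else
      reliability_masks[[if (mi %in% names(reliability_masks)) mi else 1L]]
    for (ri in names(roi_masks)) {
      roi <- roi_masks[[ri]]
      if (!all(dim(m) == dim(roi)))
        stop("ROI grid does not match map grid for ", mi, "/", ri)
      sel <- roi > 0
      if (!is.null(rel)) {
        if (!all(dim(rel) == dim(m))) stop("reliability mask grid mismatch")
        sel <- sel & rel > 0
      }
      if (by_slice) {
        for (z in seq_len(dim(m)[3])) {
          sz <- sel[, , z]
          out[[length(out) + 1L]] <- data.frame(
            map = mi, roi = ri, slice = z,
            mean = if (any(sz)) mean(m[, , z][sz]) else NA_real_,
            n_voxels = sum(sz), empty = !any(sz))
        }
      } else {
        out[[length(out) + 1L]] <- data.frame(
          map = mi, roi = ri,
          mean = if (any(sel)) mean(m[sel]) else NA_real_,
          n_voxels = sum(sel), empty = !any(sel))
      }
    }
  }
  do.call(rbind, out)
}
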