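#' DTI design matrix
#'
#' One row per volume: (1, -b gx^2, -2b gx gy, -2b gx gz, -b gy^2,
#' -2b gy gz, -b gz^2), so that X beta with beta = (lnS0, Dxx, Dxy, Dxz,
#' Dyy, Dyz, Dzz) gives ln S = ln S0 - b g' D g.
#'
#' @param scheme a \linkS4class{GradientScheme}.
#' @return N x 7 matrix.
#' @export
dtiDesignMatrix <- function(scheme) {
  b <- bValues(scheme)
  g <- bVectors(scheme)
  cbind(1,
        -b * g[1, ]^2, -2 * b * g[1, ] * g[2, ], -2 * b * g[1, ] * g[3, ],
        -b * g[2, ]^2, -2 * b * g[2, ] * g[3, ], -b * g[3, ]^2)
}

#' Assemble a symmetric tensor from the 6-coefficient vector
#' @param d numeric length 6: (Dxx, Dxy, Dxz, Dyy, Dyz, Dzz).
#' @export
tensorFromCoef <- function(d) {
  matrix(c(d[1], d[2], d[3],
           d[2], d[4], d[5],
           d[3], d[5], d[6]), 3, 3)
}

#' @keywords internal
coefFromTensor <- function(D) c(D[1, 1], D[1, 2], D[1, 3],
                                D[2, 2], D[2, 3], D[3, 3])

#' Rotation-invariant scalar metrics of one diffusion tensor
#'
#' @param D symmetric 3 x 3 tensor [mm^2/s].
#' @return list with FA, MD, AD, RD, evals (descending), evecs (columns,
#'   sign convention: first nonzero component positive), negEig flag.
#' @export
tensorScalarMetrics <- function(D) {
  if (any(!is.finite(D)))
    return(list(FA = NA_real_, MD = NA_real_, AD = NA_real_, RD = NA_real_,
                evals = rep(NA_real_, 3), evecs = matrix(NA_real_, 3, 3),
                negEig = NA))
  e <- eigen(D, symmetric = TRUE)   # eigenvalues already descending
  ev <- e$values
  V <- e$vectors
  for (j in 1:3) {
    nz <- which(abs(V[, j]) > 1e-12)
    if (length(nz) && V[nz[1], j] < 0) V[, j] <- -V[, j]
  }
  md <- mean(ev)
  ss <- sum(ev^2)
  fa <- if (ss > 0) sqrt(1.5 * sum((ev - md)^2) / ss) else 0
  fa <- min(max(fa, 0), 1)
  list(FA = fa, MD = md, AD = ev[1], RD = (ev[2] + ev[3]) / 2,
       evals = ev, evecs = V, negEig = any(ev < 0))
}

# solve weighted linear least squares; with ridge = TRUE (robust fitting),
# a Tikhonov term is added to the tensor rows of the normal matrix when the
# weighted normal matrix is ill-conditioned (outlier-dominated weights)
wlsSolve <- function(X, y, w = NULL, ridge = FALSE, ridge_cond = 1e8,
                     ridge_scale = 1e-4) {
  if (is.null(w)) w <- rep(1, length(y))
  Xw <- X * w
  A <- crossprod(Xw, X)
  bvec <- crossprod(Xw, y)
  if (ridge && rcond(A) < 1 / ridge_cond) {
    lam <- ridge_scale * sum(diag(A)[-1]) / 6
    A <- A + diag(c(0, rep(lam, ncol(X) - 1L)))
  }
  solve(A, bvec)[, 1]
}

#' Three-factor robust weights for IRLS tensor fitting
#'
#' Factorizes the IRLS weight into w_signal * w_local * w_slice, each in
#' (0, 1]: w_signal is the WLS magnitude weighting (squared predicted signal,
#' normalized); w_local = exp(-(r / (C shat))^2) down-weights locally outlying
#' observations, with shat = 1.4826 MAD(r) a robust residual scale and
#' C = 1.5; w_slice = exp(-(m_s / (C shat))^2) down-weights whole slices,
#' with m_s the median absolute residual of the observation's slice group.
#' All factors are 1 when the residuals are 0.
#'
#' @param residuals residual vector from the current IRLS iterate.
#' @param predicted_signal predicted (non-log) signal magnitudes.
#' @param slice_index integer slice label per observation (used to pool the
#'   slice statistic); ignored when \code{options$slice_weight} supplies a
#'   precomputed per-observation slice factor.
#' @param options list: \code{C} (default 1.5), \code{slice_weight}.
#' @return list with \code{w} (the product) and the three factors.
#' @export
robustWeights <- function(residuals, predicted_signal,
                          slice_index = rep(1L, length(residuals)),
                          options = list()) {
  C <- if (is.null(options$C)) 1.5 else options$C
  r <- residuals
  shat <- mad(r, center = 0)
  if (shat <= 0) {
    if (any(r != 0))
      warning("zero MAD with nonzero residuals; scale floored")
    shat <- max(.Machine$double.eps * 100, 1e-12 * max(abs(r), 1))
  }
  w_local <- exp(-(r / (C * shat))^2)
  ps <- abs(predicted_signal)
  mx <- max(ps)
  w_signal <- if (mx > 0) (ps / mx)^2 else rep(1, length(r))
  if (!is.null(options$slice_weight)) {
    w_slice <- options$slice_weight
  } else {
    m_s <- tapply(abs(r), slice_index, median)
    w_slice_g <- exp(-(m_s / (C * shat))^2)
    w_slice <- as.numeric(w_slice_g[as.character(slice_index)])
  }
  if (all(r == 0)) {
    w_local <- rep(1, length(r))
    w_slice <- rep(1, length(r))
  }
  w <- w_signal * w_local * w_slice
  list(w = w, w_signal = w_signal, w_local = w_local, w_slice = w_slice)
}

# Gauss-Newton with step-halving for models S = pred(beta); shared by the
# DTI and DKI NLLS paths. X is the log-domain design (pred = exp(X beta) or
# its noncentral-chi mean under ricianAware).
gaussNewtonExp <- function(s, X, beta0, sigma = NULL, ncoils = 1L,
                           ricianAware = FALSE, max_iter = 50L,
                           grad_tol = 1e-8) {
  beta <- beta0
  predict <- function(b) {
    A <- exp(pmin(X %*% b, 700))
    if (ricianAware) ncChiMean(as.numeric(A), sigma, ncoils) else as.numeric(A)
  }
  amp <- function(b) as.numeric(exp(pmin(X %*% b, 700)))
  sse <- function(b) sum((s - predict(b))^2)
  f_old <- sse(beta)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    A <- amp(beta)
    if (ricianAware) {
      h <- pmax(A, sigma) * 1e-5
      m <- length(A)
      # one batched quadrature call for the value and both FD points
      mm <- ncChiMean(c(A, A + h, pmax(A - h, 0)), sigma, ncoils)
      mu <- mm[seq_len(m)]
      dmu <- (mm[m + seq_len(m)] - mm[2 * m + seq_len(m)]) /
        (A + h - pmax(A - h, 0))
      J <- (dmu * A) * X
    } else {
      mu <- A
      J <- A * X
    }
    r <- s - mu
    g <- crossprod(J, r)
    if (max(abs(g)) < grad_tol * (1 + f_old)) { converged <- TRUE; break }
    JtJ <- crossprod(J)
    if (rcond(JtJ) < 1e-14)
      JtJ <- JtJ + diag(1e-10 * max(diag(JtJ)), ncol(X))
    delta <- solve(JtJ, g)[, 1]
    step <- 1
    improved <- FALSE
    for (h_it in 1:20) {       # step-halving line search
      f_new <- sse(beta + step * delta)
      if (is.finite(f_new) && f_new < f_old) { improved <- TRUE; break }
      step <- step / 2
    }
    if (!improved) { converged <- TRUE; break }  # stalled at a minimum
    rel_step <- max(abs(step * delta) / pmax(abs(beta), 1e-12))
    beta <- beta + step * delta
    if (abs(f_old - f_new) < grad_tol * (1 + f_old) || rel_step < 1e-8) {
      f_old <- f_new; converged <- TRUE; break
    }
    f_old <- f_new
  }
  list(beta = beta, converged = converged,
       residuals = s - predict(beta))
}

# single-voxel DTI fit on a signal vector; the engine behind fitDTI
fitDTIVoxel <- function(s, scheme, algorithm = "OLS", sigma = NULL,
                        ncoils = 1L, ricianAware = FALSE,
                        slice_weight = NULL, options = list()) {
  X <- dtiDesignMatrix(scheme)
  pos <- s > 0
  if (sum(pos) < 7L)
    return(list(coef = rep(NA_real_, 7), converged = FALSE, rms = NA_real_))
  y <- log(s[pos])
  Xp <- X[pos, , drop = FALSE]
  beta <- tryCatch(wlsSolve(Xp, y), error = function(e) NULL)
  if (is.null(beta))
    return(list(coef = rep(NA_real_, 7), converged = FALSE, rms = NA_real_))
  converged <- TRUE
  if (algorithm == "OLS") {
    res <- y - Xp %*% beta
  } else if (algorithm %in% c("WLS", "ROB")) {
    for (it in 1:2) {  # WLS: weights from predicted signal magnitude
      pred <- exp(pmin(Xp %*% beta, 700))
      w <- (pred / max(pred))^2
      beta <- wlsSolve(Xp, y, as.numeric(w))
    }
    res <- y - Xp %*% beta
    if (algorithm == "ROB") {
      max_it <- if (is.null(options$irls_max_iter)) 20L else options$irls_max_iter
      for (it in seq_len(max_it)) {
        pred <- as.numeric(exp(pmin(Xp %*% beta, 700)))
        r <- as.numeric(y - Xp %*% beta)
        rw <- robustWeights(r, pred, options = list(
          C = options$C,
          slice_weight = if (is.null(slice_weight)) NULL else
            slice_weight[pos]))
        beta_new <- wlsSolve(Xp, y, rw$w, ridge = TRUE)
        rel <- max(abs(beta_new - beta) / pmax(abs(beta), 1e-12))
        beta <- beta_new
        if (rel < 1e-6) break
      }
      res <- y - Xp %*% beta
    }
  } else if (algorithm == "NLLS") {
    gn <- gaussNewtonExp(s[pos], Xp, beta, sigma = sigma, ncoils = ncoils,
                         ricianAware = ricianAware)
    beta <- gn$beta
    converged <- gn$converged
    res <- gn$residuals   # signal-domain residuals (fitting domain)
  } else stop("unknown algorithm: ", algorithm)
  dof <- length(res)
  rms <- if (dof > 0) sqrt(mean(res^2)) else 0
  if (dof == ncol(Xp)) rms <- 0  # saturated fit
  list(coef = as.numeric(beta), converged = converged, rms = rms)
}

#' Fit the diffusion tensor per voxel
#'
#' Solves ln S = ln S0 - b g' D g per voxel. Algorithms: "OLS" (unweighted
#' pseudoinverse), "WLS" (weights from the predicted signal magnitude,
#' correcting the log-domain noise distortion), "ROB" (iteratively reweighted
#' least squares with the three-factor weights of
#' \code{\link{robustWeights}} and Tikhonov regularization of
#' ill-conditioned normal matrices), and "NLLS" (Gauss-Newton on the
#' non-logarithmic signal, OLS initialization, step-halving line search,
#' max 50 iterations; optionally Rician-aware, predicting the noncentral-chi
#' mean of the model signal).
#'
#' Intensities <= 0 are excluded from the linearized fits rather than
#' clipped. The slice factor of the robust weights is computed dataset-wide:
#' an initial WLS pass yields per-(volume, slice) median absolute residuals,
#' which down-weight whole corrupted slices in every voxel's IRLS.
#'
#' @param dwi a \linkS4class{DWISeries}.
#' @param mask 3D binary analysis mask (default: all voxels).
#' @param algorithm "OLS", "WLS", "ROB", or "NLLS".
#' @param noise optional \linkS4class{NoiseEstimate}; required for
#'   Rician-aware NLLS, recommended for WLS/ROB.
#' @param ricianAware logical; model the noncentral-chi first moment during
#'   NLLS fitting. Mutually exclusive with prior RBC (label "RBC").
#' @param options list of tuning parameters (\code{C}, \code{irls_max_iter}).
#' @return a \linkS4class{TensorFit}.
#' @export
fitDTI <- function(dwi, mask = NULL, algorithm = c("OLS", "WLS", "ROB",
                                                   "NLLS"),
                   noise = NULL, ricianAware = FALSE, options = list()) {
  algorithm <- match.arg(algorithm)
  d <- dim(dwi@data)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  mask <- array(mask > 0, d[1:3])
  sch <- scheme(dwi)
  nb0 <- sum(shellIds(sch) == 0L)
  if (nVolumes(sch) < 7L || nb0 < 1L)
    stop("need >= 7 volumes spanning >= 6 non-coplanar directions plus b0")
  X <- dtiDesignMatrix(sch)
  if (qr(X)$rank < 7L)
    stop("singular design: gradient directions are coplanar")
  if (ricianAware) {
    if (algorithm != "NLLS")
      stop("Rician-aware fitting is only available for NLLS")
    if ("RBC" %in% dwi@labels)
      stop("Rician-aware NLLS must not be combined with prior RBC ",
           "(data already bias-corrected)")
    if (is.null(noise))
      stop("Rician-aware NLLS requires a NoiseEstimate")
  }
  sigma <- if (!is.null(noise)) noiseSigma(noise) else NULL
  ncoils <- if (!is.null(noise)) nCoils(noise) else 1L
  vox <- which(mask)
  idx <- arrayInd(vox, d[1:3])
  sig_mat <- matrix(aperm(dwi@data, c(4, 1, 2, 3)), d[4])[, vox, drop = FALSE]

  slice_w <- NULL
  if (algorithm == "ROB") {
    # dataset-wide slice statistic from an initial WLS pass
    resmat <- matrix(NA_real_, d[4], length(vox))
    for (j in seq_along(vox)) {
      s <- sig_mat[, j]
      f0 <- fitDTIVoxel(s, sch, "WLS")
      if (!any(is.na(f0$coef))) {
        pos <- s > 0
        resmat[pos, j] <- log(s[pos]) - X[pos, ] %*% f0$coef
      }
    }
    shat_all <- mad(resmat[is.finite(resmat)], center = 0)
    if (!is.finite(shat_all) || shat_all <= 0) shat_all <- 1e-12
    C <- if (is.null(options$C)) 1.5 else options$C
    zs <- idx[, 3]
    slice_w <- matrix(1, d[4], length(vox))
    for (z in unique(zs)) {
      cols <- which(zs == z)
      m_kz <- apply(abs(resmat[, cols, drop = FALSE]), 1, median,
                    na.rm = TRUE)
      m_kz[!is.finite(m_kz)] <- 0
      slice_w[, cols] <- exp(-(m_kz / (C * shat_all))^2)
    }
  }

  coef <- array(NA_real_, c(d[1:3], 7L))
  rms <- array(NA_real_, d[1:3])
  conv <- array(TRUE, d[1:3])
  for (j in seq_along(vox)) {
    f <- fitDTIVoxel(sig_mat[, j], sch, algorithm, sigma = sigma,
                     ncoils = ncoils, ricianAware = ricianAware,
                     slice_weight = if (is.null(slice_w)) NULL else
                       slice_w[, j],
                     options = options)
    i <- idx[j, ]
    coef[i[1], i[2], i[3], ] <- f$coef
    rms[i[1], i[2], i[3]] <- f$rms
    conv[i[1], i[2], i[3]] <- f$converged
  }
  rms_in <- rms[mask]
  rms_in[!is.finite(rms_in)] <- 0
  rms[mask] <- rms_in
  new("TensorFit", coef = coef, algorithm = algorithm, rmsError = rms,
      converged = conv, mask = mask)
}

#' Scalar maps from a tensor fit
#'
#' Per-voxel symmetric eigendecomposition; eigenvalues sorted descending,
#' eigenvector sign fixed (first nonzero component positive). MD, AD, RD in
#' the tensor's units; FA dimensionless in [0, 1]. Negative eigenvalues are
#' retained in the L maps but flagged in \code{negEig}.
#'
#' @param fit a \linkS4class{TensorFit} (or \linkS4class{KurtosisFit}, whose
#'   tensor part is used).
#' @return list of 3D maps: FA, MD, AD, RD, L1, L2, L3; 4D maps V1, V2, V3;
#'   logical negEig.
#' @export
dtiMetrics <- function(fit) {
  d3 <- dim(fit@coef)[1:3]
  out <- list(FA = array(NA_real_, d3), MD = array(NA_real_, d3),
              AD = array(NA_real_, d3), RD = array(NA_real_, d3),
              L1 = array(NA_real_, d3), L2 = array(NA_real_, d3),
              L3 = array(NA_real_, d3),
              V1 = array(NA_real_, c(d3, 3)), V2 = array(NA_real_, c(d3, 3)),
              V3 = array(NA_real_, c(d3, 3)), negEig = array(FALSE, d3))
  vox <- which(fit@mask)
  idx <- arrayInd(vox, d3)
  for (j in seq_along(vox)) {
    i <- idx[j, ]
    D <- tensorFromCoef(fit@coef[i[1], i[2], i[3], 2:7])
    m <- tensorScalarMetrics(D)
    out$FA[i[1], i[2], i[3]] <- m$FA
    out$MD[i[1], i[2], i[3]] <- m$MD
    out$AD[i[1], i[2], i[3]] <- m$AD
    out$RD[i[1], i[2], i[3]] <- m$RD
    out$L1[i[1], i[2], i[3]] <- m$evals[1]
    out$L2[i[1], i[2], i[3]] <- m$evals[2]
    out$L3[i[1], i[2], i[3]] <- m$evals[3]
    out$V1[i[1], i[2], i[3], ] <- m$evecs[, 1]
    out$V2[i[1], i[2], i[3], ] <- m$evecs[, 2]
    out$V3[i[1], i[2], i[3], ] <- m$evecs[, 3]
    out$negEig[i[1], i[2], i[3]] <- isTRUE(m$negEig)
  }
  out
}
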