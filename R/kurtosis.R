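#' Index table for the 15 independent kurtosis tensor components
#'
#' Lexicographic order of the sorted index quadruples (i <= j <= k <= l) with
#' the permutation multiplicity of each, used consistently for the design
#' matrix, tensor expansion, and metric contractions.
#'
#' @return data.frame with columns i, j, k, l, mult (multiplicities sum
#'   to 81 = 3^4).
#' @export
kurtosisIndexTable <- function() {
  idx <- NULL
  for (i in 1:3) for (j in i:3) for (k in j:3) for (l in k:3)
    idx <- rbind(idx, c(i, j, k, l))
  mult <- apply(idx, 1, function(q) {
    tab <- tabulate(q, 3)
    factorial(4) / prod(factorial(tab))
  })
  data.frame(i = idx[, 1], j = idx[, 2], k = idx[, 3], l = idx[, 4],
             mult = mult)
}

kIdx <- kurtosisIndexTable()

# per-direction evaluation rows: mult * g_i g_j g_k g_l for the 15 components
wDesignRow <- function(g) {
  t(apply(g, 2, function(v)
    kIdx$mult * v[kIdx$i] * v[kIdx$j] * v[kIdx$k] * v[kIdx$l]))
}

#' DKI design matrix (22 columns)
#'
#' ln S = ln S0 - b D(g) + (b^2/6) Wtilde(g), with D(g) = g' D g and
#' Wtilde(g) = sum g_i g_j g_k g_l Wtilde_ijkl. The 15 kurtosis unknowns are
#' the MD^2-scaled products Wtilde = MD^2 W, keeping the model linear; the
#' fitted values are divided by MD^2 of the fitted tensor to give the
#' dimensionless W stored in \linkS4class{KurtosisFit}.
#'
#' @param scheme a \linkS4class{GradientScheme}.
#' @return N x 22 matrix.
#' @export
dkiDesignMatrix <- function(scheme) {
  b <- bValues(scheme)
  g <- bVectors(scheme)
  Xd <- dtiDesignMatrix(scheme)
  Ww <- wDesignRow(g) * (b^2 / 6)
  cbind(Xd, Ww)
}

# evaluate the W form W(n) = sum_ijkl n_i n_j n_k n_l W_ijkl for unit
# direction matrix n (3 x m) and 15-vector w (dimensionless)
wForm <- function(n, w) as.numeric(wDesignRow(n) %*% w)

# expand the 15-vector into the full symmetric 3x3x3x3 array
wExpand <- function(w) {
  W <- array(0, c(3, 3, 3, 3))
  for (r in seq_len(nrow(kIdx))) {
    q <- as.integer(kIdx[r, 1:4])
    perms <- unique(matrix(q[permut4()], ncol = 4))
    for (p in seq_len(nrow(perms)))
      W[perms[p, 1], perms[p, 2], perms[p, 3], perms[p, 4]] <- w[r]
  }
  W
}

perm_cache <- new.env(parent = emptyenv())
permut4 <- function() {
  if (is.null(perm_cache$p)) {
    p <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
    p <- p[apply(p, 1, function(r) length(unique(r)) == 4L), ]
    perm_cache$p <- p
  }
  perm_cache$p
}

# contract full W array back to the 15-vector
wContract <- function(W) {
  vapply(seq_len(nrow(kIdx)), function(r)
    W[kIdx$i[r], kIdx$j[r], kIdx$k[r], kIdx$l[r]], numeric(1))
}

# rotate a 15-vector W by rotation matrix R: W'_ijkl = R_ia R_jb R_kc R_ld W
wRotate <- function(w, R) {
  W <- wExpand(w)
  W1 <- array(0, c(3, 3, 3, 3))
  # successive index rotations via tensor-matrix products
  Wm <- matrix(W, 3, 27); W1 <- array(R %*% Wm, c(3, 3, 3, 3))
  W1 <- aperm(W1, c(2, 3, 4, 1))
  Wm <- matrix(W1, 3, 27); W1 <- array(R %*% Wm, c(3, 3, 3, 3))
  W1 <- aperm(W1, c(2, 3, 4, 1))
  Wm <- matrix(W1, 3, 27); W1 <- array(R %*% Wm, c(3, 3, 3, 3))
  W1 <- aperm(W1, c(2, 3, 4, 1))
  Wm <- matrix(W1, 3, 27); W1 <- array(R %*% Wm, c(3, 3, 3, 3))
  W1 <- aperm(W1, c(2, 3, 4, 1))
  wContract(W1)
}

# spherical product quadrature: Gauss-Legendre in cos(theta) x uniform phi.
# Integrates smooth functions on the sphere to ~1e-10; sized so kurtosis
# metrics meet a 1e-6 tolerance with margin.
sphereQuadrature <- function(n_theta = 24L) {
  gl <- pracma::gaussLegendre(n_theta, -1, 1)
  n_phi <- 2L * n_theta
  phi <- (seq_len(n_phi) - 0.5) / n_phi * 2 * pi
  u <- rep(gl$x, each = n_phi)
  ph <- rep(phi, n_theta)
  s <- sqrt(pmax(1 - u^2, 0))
  dirs <- rbind(s * cos(ph), s * sin(ph), u)
  w <- rep(gl$w, each = n_phi) / n_phi / 2  # weights sum to 1
  list(dirs = dirs, w = w)
}

sq_cache <- new.env(parent = emptyenv())
sphereQuadratureCached <- function(n_theta = 24L) {
  key <- as.character(n_theta)
  if (is.null(sq_cache[[key]])) sq_cache[[key]] <- sphereQuadrature(n_theta)
  sq_cache[[key]]
}

#' Fit the diffusion kurtosis model per voxel
#'
#' Linearized model ln S = ln S0 - b D(g) + (b^2/6) MD^2 W(g) with the 15
#' independent kurtosis coefficients (see \code{\link{dkiDesignMatrix}} for
#' the scaling convention). "OLS" solves the 22-column design; "NLLS" refines
#' in the signal domain (Gauss-Newton, OLS initialization, step-halving),
#' optionally with the Rician-aware noncentral-chi signal prediction.
#'
#' @param dwi a \linkS4class{DWISeries}; needs >= 2 nonzero shells and
#'   >= 22 volumes.
#' @param mask 3D binary analysis mask.
#' @param algorithm "OLS" or "NLLS".
#' @param noise optional \linkS4class{NoiseEstimate} (required when
#'   \code{ricianAware}).
#' @param ricianAware logical (NLLS only; mutually exclusive with prior RBC).
#' @return a \linkS4class{KurtosisFit}.
#' @export
fitDKI <- function(dwi, mask = NULL, algorithm = c("OLS", "NLLS"),
                   noise = NULL, ricianAware = FALSE) {
  algorithm <- match.arg(algorithm)
  sch <- scheme(dwi)
  nshell <- length(unique(shellIds(sch)[shellIds(sch) > 0]))
  if (nshell < 2L)
    stop("kurtosis fitting requires >= 2 nonzero shells, found ", nshell)
  if (nVolumes(sch) < 22L)
    stop("kurtosis fitting requires >= 22 volumes")
  if (ricianAware) {
    if (algorithm != "NLLS") stop("Rician-aware fitting requires NLLS")
    if ("RBC" %in% dwi@labels)
      stop("Rician-aware NLLS must not be combined with prior RBC")
    if (is.null(noise)) stop("Rician-aware NLLS requires a NoiseEstimate")
  }
  d <- dim(dwi@data)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  mask <- array(mask > 0, d[1:3])
  X <- dkiDesignMatrix(sch)
  sigma <- if (!is.null(noise)) noiseSigma(noise) else NULL
  ncoils <- if (!is.null(noise)) nCoils(noise) else 1L
  vox <- which(mask)
  idx <- arrayInd(vox, d[1:3])
  sig_mat <- matrix(aperm(dwi@data, c(4, 1, 2, 3)), d[4])[, vox, drop = FALSE]
  coef <- array(NA_real_, c(d[1:3], 22L))
  rms <- array(NA_real_, d[1:3])
  conv <- array(TRUE, d[1:3])
  for (j in seq_along(vox)) {
    s <- sig_mat[, j]
    pos <- s > 0
    i <- idx[j, ]
    if (sum(pos) < 22L) { conv[i[1], i[2], i[3]] <- FALSE; next }
    Xp <- X[pos, , drop = FALSE]
    beta <- tryCatch(wlsSolve(Xp, log(s[pos])),
                     error = function(e) NULL)
    if (is.null(beta)) { conv[i[1], i[2], i[3]] <- FALSE; next }
    if (algorithm == "NLLS") {
      gn <- gaussNewtonExp(s[pos], Xp, beta, sigma = sigma,
                           ncoils = ncoils, ricianAware = ricianAware)
      beta <- gn$beta
      conv[i[1], i[2], i[3]] <- gn$converged
      res <- gn$residuals
    } else {
      res <- log(s[pos]) - Xp %*% beta
    }
    md <- mean(beta[c(2, 5, 7)])            # (Dxx + Dyy + Dzz)/3
    wcoef <- if (md > 0) beta[8:22] / md^2 else rep(NA_real_, 15)
    coef[i[1], i[2], i[3], ] <- c(beta[1:7], wcoef)
    rms[i[1], i[2], i[3]] <-
      if (length(res) == ncol(Xp)) 0 else sqrt(mean(res^2))
  }
  new("KurtosisFit", coef = coef, algorithm = algorithm, rmsError = rms,
      converged = conv, mask = mask)
}

# build the full (D coef, W 15-vector) pair from axisymmetric parameters
# axis u; Dpar, Dperp [mm^2/s]; MW, AW, RW dimensionless
axiTensors <- function(u, Dpar, Dperp, MW, AW, RW) {
  u <- u / sqrt(sum(u^2))
  D <- Dperp * diag(3) + (Dpar - Dperp) * tcrossprod(u)
  # eigenframe components (axis = e3): W3333 = AW, W1111 = W2222 = RW,
  # W1122 = RW/3, W1133 = W2233 = (5 MW - AW - (8/3) RW)/4
  w <- numeric(15)
  w13 <- (5 * MW - AW - (8 / 3) * RW) / 4
  set_w <- function(w, i, j, k, l, val) {
    q <- sort(c(i, j, k, l))
    r <- which(kIdx$i == q[1] & kIdx$j == q[2] & kIdx$k == q[3] &
               kIdx$l == q[4])
    w[r] <- val
    w
  }
  w <- set_w(w, 1, 1, 1, 1, RW)
  w <- set_w(w, 2, 2, 2, 2, RW)
  w <- set_w(w, 3, 3, 3, 3, AW)
  w <- set_w(w, 1, 1, 2, 2, RW / 3)
  w <- set_w(w, 1, 1, 3, 3, w13)
  w <- set_w(w, 2, 2, 3, 3, w13)
  # rotate e3 -> u
  R <- rotationToAxis(u)
  list(D = D, w = wRotate(w, R))
}

# rotation matrix taking e3 to the unit vector u
rotationToAxis <- function(u) {
  e3 <- c(0, 0, 1)
  v <- pracma::cross(e3, u)
  c_ <- sum(e3 * u)
  if (sum(v^2) < 1e-20) return(if (c_ > 0) diag(3) else diag(c(1, -1, -1)))
  vx <- matrix(c(0, v[3], -v[2], -v[3], 0, v[1], v[2], -v[1], 0), 3, 3)
  diag(3) + vx + vx %*% vx / (1 + c_)
}

# axisymmetric DKI signal prediction for parameter vector
# p = (lnS0, theta, phi, Dpar, Dperp, MW, AW, RW)
axiPredictLog <- function(p, b, g) {
  u <- c(sin(p[2]) * cos(p[3]), sin(p[2]) * sin(p[3]), cos(p[2]))
  c2 <- (colSums(g * u))^2
  s2 <- 1 - c2
  Dn <- p[5] + (p[4] - p[5]) * c2
  w13 <- (5 * p[6] - p[7] - (8 / 3) * p[8]) / 4
  Wn <- p[8] * s2^2 + p[7] * c2^2 + 6 * w13 * c2 * s2
  md <- (p[4] + 2 * p[5]) / 3
  p[1] - b * Dn + b^2 / 6 * md^2 * Wn
}

#' Fit the axisymmetric diffusion kurtosis model (NLLS)
#'
#' Eight independent parameters per voxel: lnS0, the symmetry axis (theta,
#' phi), parallel/perpendicular diffusivities, and the mean/axial/radial
#' kurtosis-tensor amplitudes. Initialization comes from a full 22-parameter
#' OLS kurtosis fit (axis = principal eigenvector); refinement is
#' Levenberg-Marquardt on the signal-domain residuals, optionally with the
#' Rician-aware noncentral-chi prediction. The axis gauge is antipodal:
#' theta is folded into [0, pi/2].
#'
#' @inheritParams fitDKI
#' @return an \linkS4class{AxiKurtosisFit}.
#' @export
fitAxisymmetricDKI <- function(dwi, mask = NULL, noise = NULL,
                               ricianAware = FALSE) {
  sch <- scheme(dwi)
  d <- dim(dwi@data)
  if (is.null(mask)) mask <- array(TRUE, d[1:3])
  mask <- array(mask > 0, d[1:3])
  init_fit <- fitDKI(dwi, mask, algorithm = "OLS")
  sigma <- if (!is.null(noise)) noiseSigma(noise) else NULL
  ncoils <- if (!is.null(noise)) nCoils(noise) else 1L
  if (ricianAware && ("RBC" %in% dwi@labels))
    stop("Rician-aware NLLS must not be combined with prior RBC")
  if (ricianAware && is.null(sigma))
    stop("Rician-aware NLLS requires a NoiseEstimate")
  b <- bValues(sch)
  g <- bVectors(sch)
  vox <- which(mask)
  idx <- arrayInd(vox, d[1:3])
  sig_mat <- matrix(aperm(dwi@data, c(4, 1, 2, 3)), d[4])[, vox, drop = FALSE]
  coef <- array(NA_real_, c(d[1:3], 8L))
  rms <- array(NA_real_, d[1:3])
  conv <- array(TRUE, d[1:3])
  # scaling so LM sees O(1) parameters (diffusivities in um^2/ms)
  sc <- c(1, 1, 1, 1e3, 1e3, 1, 1, 1)
  for (j in seq_along(vox)) {
    i <- idx[j, ]
    s <- sig_mat[, j]
    ic <- init_fit@coef[i[1], i[2], i[3], ]
    if (any(!is.finite(ic))) { conv[i[1], i[2], i[3]] <- FALSE; next }
    Dm <- tensorFromCoef(ic[2:7])
    met <- tensorScalarMetrics(Dm)
    km <- dkiMetricsVoxel(ic[2:7], ic[8:22])
    u0 <- met$evecs[, 1]
    if (u0[3] < 0) u0 <- -u0
    th0 <- acos(min(max(u0[3], -1), 1))
    ph0 <- atan2(u0[2], u0[1])
    p0 <- c(ic[1], th0, ph0, met$AD, met$RD,
            ifelse(is.finite(km$MW), km$MW, 0),
            ifelse(is.finite(km$AW), km$AW, 0),
            ifelse(is.finite(km$RW), km$RW, 0))
    resid_fn <- function(ps) {
      p <- ps / sc
      mu <- exp(pmin(axiPredictLog(p, b, g), 700))
      if (ricianAware) mu <- ncChiMean(mu, sigma, ncoils)
      s - mu
    }
    fit <- tryCatch(
      minpack.lm::nls.lm(par = p0 * sc, fn = resid_fn,
                         control = minpack.lm::nls.lm.control(
                           maxiter = 200, ftol = 1e-14, ptol = 1e-14)),
      error = function(e) NULL)
    if (is.null(fit)) { conv[i[1], i[2], i[3]] <- FALSE; next }
    p <- fit$par / sc
    # antipodal gauge: fold axis into theta in [0, pi/2]
    u <- c(sin(p[2]) * cos(p[3]), sin(p[2]) * sin(p[3]), cos(p[2]))
    if (u[3] < 0) u <- -u
    p[2] <- acos(min(max(u[3], -1), 1))
    p[3] <- atan2(u[2], u[1])
    coef[i[1], i[2], i[3], ] <- p
    r <- fit$fvec
    rms[i[1], i[2], i[3]] <- if (length(r) == 8L) 0 else sqrt(mean(r^2))
    conv[i[1], i[2], i[3]] <- fit$info %in% 1:4
  }
  new("AxiKurtosisFit", coef = coef, rmsError = rms, converged = conv,
      mask = mask)
}

#' Expand an axisymmetric kurtosis fit to full tensors
#'
#' Builds the full diffusion tensor and 15-component kurtosis tensor with the
#' symmetry axis along the stored direction. The directional kurtosis of the
#' expanded tensors equals the axisymmetric model's prediction for every
#' direction, which makes this the equivalence bridge between the two
#' parameterizations.
#'
#' @param fit an \linkS4class{AxiKurtosisFit}.
#' @return a \linkS4class{KurtosisFit}.
#' @export
axiToFull <- function(fit) {
  d3 <- dim(fit@coef)[1:3]
  coef <- array(NA_real_, c(d3, 22L))
  vox <- which(fit@mask)
  idx <- arrayInd(vox, d3)
  for (j in seq_along(vox)) {
    i <- idx[j, ]
    p <- fit@coef[i[1], i[2], i[3], ]
    if (any(!is.finite(p))) next
    u <- c(sin(p[2]) * cos(p[3]), sin(p[2]) * sin(p[3]), cos(p[2]))
    tw <- axiTensors(u, p[4], p[5], p[6], p[7], p[8])
    coef[i[1], i[2], i[3], ] <- c(p[1], coefFromTensor(tw$D), tw$w)
  }
  new("KurtosisFit", coef = coef, algorithm = "NLLS",
      rmsError = fit@rmsError, converged = fit@converged, mask = fit@mask)
}

# kurtosis metrics for one voxel given tensor coefs (6) and W 15-vector
dkiMetricsVoxel <- function(dcoef, w, n_theta = 24L, n_circle = 64L) {
  D <- tensorFromCoef(dcoef)
  met <- tensorScalarMetrics(D)
  md <- met$MD
  if (!is.finite(md) || any(!is.finite(w)))
    return(list(MK = NA_real_, AK = NA_real_, RK = NA_real_,
                MW = NA_real_, AW = NA_real_, RW = NA_real_, flagged = TRUE))
  q <- sphereQuadratureCached(n_theta)
  Dn <- colSums(q$dirs * (D %*% q$dirs))
  flagged <- any(Dn <= 0)
  Wn <- wForm(q$dirs, w)
  Kn <- (md / Dn)^2 * Wn
  MK <- if (flagged) NA_real_ else sum(q$w * Kn)
  v1 <- met$evecs[, 1]
  D1 <- sum(v1 * (D %*% v1))
  AK <- if (D1 > 0) (md / D1)^2 * wForm(matrix(v1), w) else NA_real_
  # perpendicular great circle (64-point trapezoid)
  v2 <- met$evecs[, 2]; v3 <- met$evecs[, 3]
  ang <- (seq_len(n_circle) - 1) / n_circle * 2 * pi
  perp <- v2 %o% cos(ang) + v3 %o% sin(ang)
  Dp <- colSums(perp * (D %*% perp))
  RK <- if (all(Dp > 0)) mean((md / Dp)^2 * wForm(perp, w)) else NA_real_
  # W-tensor contractions (eigenframe evaluations)
  wr <- vapply(1:15, function(r) w[r], numeric(1))
  MW <- (wr[widx(1,1,1,1)] + wr[widx(2,2,2,2)] + wr[widx(3,3,3,3)] +
         2 * wr[widx(1,1,2,2)] + 2 * wr[widx(1,1,3,3)] +
         2 * wr[widx(2,2,3,3)]) / 5
  AW <- wForm(matrix(v1), w)
  RW <- mean(wForm(perp, w))
  list(MK = MK, AK = AK, RK = RK, MW = MW, AW = AW, RW = RW,
       flagged = flagged || !all(Dp > 0) || D1 <= 0)
}

widx <- function(i, j, k, l) {
  q <- sort(c(i, j, k, l))
  which(kIdx$i == q[1] & kIdx$j == q[2] & kIdx$k == q[3] & kIdx$l == q[4])
}

#' Kurtosis scalar maps
#'
#' Directional apparent kurtosis K(n) = (MD/D(n))^2 W(n). MK is the spherical
#' mean of K(n) by Gauss-Legendre x trapezoid product quadrature (1152
#' points, tolerance well below 1e-6 for smooth integrands); AK is K along
#' the principal eigenvector; RK is the mean of K over the perpendicular
#' great circle (64-point trapezoid). MW/AW/RW are kurtosis-tensor
#' contractions: MW = (1/5)(W1111 + W2222 + W3333 + 2 W1122 + 2 W1133 +
#' 2 W2233), AW/RW evaluate W along/perpendicular to the principal axis.
#' Voxels where D(n) <= 0 along any quadrature direction are flagged
#' (metrics NA), never clipped.
#'
#' @param fit a \linkS4class{KurtosisFit}.
#' @return list of 3D maps MK, AK, RK, MW, AW, RW and logical \code{flagged}.
#' @export
dkiMetrics <- function(fit) {
  d3 <- dim(fit@coef)[1:3]
  out <- list(MK = array(NA_real_, d3), AK = array(NA_real_, d3),
              RK = array(NA_real_, d3), MW = array(NA_real_, d3),
              AW = array(NA_real_, d3), RW = array(NA_real_, d3),
              flagged = array(FALSE, d3))
  vox <- which(fit@mask)
  idx <- arrayInd(vox, d3)
  for (j in seq_along(vox)) {
    i <- idx[j, ]
    cf <- fit@coef[i[1], i[2], i[3], ]
    if (any(!is.finite(cf))) { out$flagged[i[1], i[2], i[3]] <- TRUE; next }
    m <- dkiMetricsVoxel(cf[2:7], cf[8:22])
    for (nm in c("MK", "AK", "RK", "MW", "AW", "RW"))
      out[[nm]][i[1], i[2], i[3]] <- m[[nm]]
    out$flagged[i[1], i[2], i[3]] <- m$flagged
  }
  out
}
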