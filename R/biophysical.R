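#' Second moment of the Watson axial distribution
#'
#' E[cos^2 psi] for orientation psi between an axon and the mean axis, under
#' the Watson distribution with concentration kappa >= 0 (the oblate case
#' kappa < 0 is unsupported). Evaluated by adaptive quadrature on [0, 1] with
#' tolerance 1e-12. kappa = 0 gives 1/3 (uniform sphere); kappa -> Inf
#' approaches 1 (full alignment). Monotone increasing in kappa.
#'
#' @param kappa Watson concentration parameter (vectorized).
#' @return E[cos^2 psi], same length as kappa.
#' @export
watsonMoment <- function(kappa) {
  vapply(kappa, function(k) watsonMoments(k)$p, numeric(1))
}

# p = <cos^2>, q = <cos^4> under Watson(kappa); density on x = cos(psi) in
# [0,1] proportional to exp(kappa x^2)
watsonMoments <- function(kappa) {
  stopifnot(kappa >= 0)
  if (kappa == 0) return(list(p = 1 / 3, q = 1 / 5))
  # factor exp(-kappa) for numerical stability at large kappa
  f0 <- integrate(function(x) exp(kappa * (x^2 - 1)), 0, 1,
                  rel.tol = 1e-12, abs.tol = 0)$value
  f2 <- integrate(function(x) x^2 * exp(kappa * (x^2 - 1)), 0, 1,
                  rel.tol = 1e-12, abs.tol = 0)$value
  f4 <- integrate(function(x) x^4 * exp(kappa * (x^2 - 1)), 0, 1,
                  rel.tol = 1e-12, abs.tol = 0)$value
  list(p = f2 / f0, q = f4 / f0)
}

#' Convert Watson concentration to orientation dispersion index (and back)
#'
#' ODI = (2/pi) arctan(1/kappa); kappa = 0 maps to ODI = 1 (maximal
#' dispersion), kappa -> Inf to ODI -> 0. \code{odiToKappa} inverts for
#' ODI in (0, 1].
#'
#' @param kappa Watson concentration (>= 0).
#' @export
kappaToOdi <- function(kappa) {
  stopifnot(all(kappa >= 0, na.rm = TRUE))
  ifelse(kappa == 0, 1, (2 / pi) * atan(1 / kappa))
}

#' @rdname kappaToOdi
#' @param odi orientation dispersion index in (0, 1].
#' @export
odiToKappa <- function(odi) {
  stopifnot(all(odi > 0, na.rm = TRUE), all(odi <= 1, na.rm = TRUE))
  ifelse(odi == 1, 0, 1 / tan(pi * odi / 2))
}

#' Forward moments of the two-compartment Watson standard model
#'
#' Treats the voxel as a Watson-ODF mixture of Gaussian micro-compartments: a
#' stick with diffusivity Da along each axon direction u (weight f) and an
#' axisymmetric extra-axonal tensor (DePar, DePerp) along u (weight 1 - f).
#' The directional diffusivity is D(n) = <compartment D(n)> and the
#' directional kurtosis K(n) = 3 Var[compartment D(n)] / D(n)^2, with
#' averages over compartments x Watson orientations (azimuthal integrals
#' analytic, polar moments by adaptive quadrature). Both are exact
#' fourth-order tensor forms in n, and are returned as the axisymmetric DKI
#' tensor metrics (AD, RD, MW, AW, RW) in the kurtosis module's conventions.
#'
#' @param params a \linkS4class{StandardModelParams}.
#' @return named list: AD, RD [mm^2/s]; MW, AW, RW (dimensionless); plus MD.
#' @export
smForwardMoments <- function(params) {
  f <- params@f; Da <- params@Da
  Dep <- params@DePar; Det <- params@DePerp
  if (Da == 0 && Dep == 0 && Det == 0)
    stop("degenerate standard-model parameters: all diffusivities zero")
  mom <- watsonMoments(params@kappa)
  p <- mom$p; q <- mom$q
  dDe <- Dep - Det
  pperp <- (1 - p) / 2
  delta <- (3 * p - 1) / 2
  # E[D](c) = A1 + B1 c^2 with c = n . mu
  a <- f * Da + (1 - f) * dDe
  A1 <- (1 - f) * Det + a * pperp
  B1 <- a * delta
  # m4(c) = t0 + t2 c^2 + t4 c^4 (4th orientation moment contraction)
  t0 <- 3 / 8 * (1 - 2 * p + q)
  t2 <- -2 * t0 + 3 * (p - q)
  t4 <- t0 + q - 3 * (p - q)
  # E[D^2](c): quadratic-in-c^2 polynomial
  cA <- f * Da^2 + (1 - f) * dDe^2
  e0 <- (1 - f) * Det^2 + 2 * (1 - f) * Det * dDe * pperp + cA * t0
  e2 <- 2 * (1 - f) * Det * dDe * delta + cA * t2
  e4 <- cA * t4
  alpha <- e0 - A1^2
  beta <- e2 - 2 * A1 * B1
  gamma <- e4 - B1^2
  AD <- A1 + B1
  RD <- A1
  MD <- (AD + 2 * RD) / 3
  list(AD = AD, RD = RD,
       MW = 3 * (alpha + beta / 3 + gamma / 5) / MD^2,
       AW = 3 * (alpha + beta + gamma) / MD^2,
       RW = 3 * alpha / MD^2,
       MD = MD)
}

# DTI-level tensor of the standard model (axisymmetric about mu)
smTensorD <- function(params) {
  m <- smForwardMoments(params)
  u <- params@mu
  m$RD * diag(3) + (m$AD - m$RD) * tcrossprod(u)
}

#' Exact standard-model signal (normalized to S0 = 1)
#'
#' Numeric spherical convolution of the two-compartment kernel with the
#' Watson ODF: S(b, g) = f Int w(u) exp(-b Da (g.u)^2) du +
#' (1 - f) exp(-b DePerp) Int w(u) exp(-b (DePar - DePerp) (g.u)^2) du.
#' At b beyond the cumulant-faithful range (b * max diffusivity > ~ 3) the
#' second-order DKI representation of these signals degrades; a warning is
#' emitted, not an error.
#'
#' @param params a \linkS4class{StandardModelParams}.
#' @param bvals,gvecs the scheme to evaluate on.
#' @param n_theta polar quadrature order for the ODF convolution.
#' @return numeric vector of normalized signals.
#' @export
smSignal <- function(params, bvals, gvecs, n_theta = 64L) {
  if (max(bvals) * max(params@Da, params@DePar) > 3.5)
    warning("b-values beyond the cumulant-faithful range of the ",
            "standard-model generator; DKI fits will be b-dependent")
  q <- sphereQuadratureCached(n_theta)
  wts <- q$w * exp(params@kappa * (colSums(q$dirs * params@mu)^2 - 1))
  wts <- wts / sum(wts)
  cu2 <- crossprod(gvecs, q$dirs)^2          # N x npts
  dDe <- params@DePar - params@DePerp
  stick <- exp(-outer(bvals * params@Da, rep(1, ncol(cu2))) * cu2) %*% wts
  extra <- exp(-bvals * params@DePerp) *
    (exp(-outer(bvals * dDe, rep(1, ncol(cu2))) * cu2) %*% wts)
  as.numeric(params@f * stick + (1 - params@f) * extra)
}

# forward observables used by the inversions, from a parameter vector
# th = (f, Da, DePar, DePerp, kappa)
smForwardVec <- function(th, mu = c(0, 0, 1)) {
  p <- new("StandardModelParams", f = th[1], Da = th[2], DePar = th[3],
           DePerp = th[4], kappa = th[5], mu = mu)
  m <- smForwardMoments(p)
  c(AD = m$AD, RD = m$RD, MW = m$MW, AW = m$AW, RW = m$RW)
}

#' WMTI-Watson inversion of axisymmetric DKI metrics
#'
#' Recovers the five standard-model parameters (f, Da, DePar, DePerp, kappa)
#' from the axisymmetric DKI tensor metrics (AD, RD, MW, AW, RW) by damped
#' least-squares root finding (Levenberg-Marquardt) against the quadrature
#' forward model \code{\link{smForwardMoments}}. The estimation is
#' degenerate with two solutions: the plus branch assumes Da > DePar at the
#' solution and the minus branch Da < DePar; the branch selects the
#' initialization half-space and the accepted root. The plus branch is the
#' default (the minus branch is typically the biologically invalid one).
#' Voxels with no in-bounds root are flagged invalid, mirroring the
#' unphysical-voxel behaviour of map-level inversions.
#'
#' @param metrics data.frame (or named vector for one voxel) with columns
#'   AD, RD [mm^2/s], MW, AW, RW.
#' @param branch "plus" or "minus".
#' @param bounds list with \code{d_max} (diffusivity upper bound [mm^2/s],
#'   default 4e-3; use 1.5e-3 for ex vivo data) and \code{kappa_max}
#'   (default 128).
#' @return data.frame: f, Da, DePar, DePerp, kappa, odi, branch, valid.
#' @export
wmtiWatson <- function(metrics, branch = c("plus", "minus"),
                       bounds = list(d_max = 4e-3, kappa_max = 128)) {
  branch <- match.arg(branch)
  if (!is.data.frame(metrics)) metrics <- as.data.frame(as.list(metrics))
  d_max <- bounds$d_max; k_max <- bounds$kappa_max
  n <- nrow(metrics)
  out <- data.frame(f = rep(NA_real_, n), Da = NA_real_, DePar = NA_real_,
                    DePerp = NA_real_, kappa = NA_real_, odi = NA_real_,
                    branch = branch, valid = FALSE)
  sc <- c(1, 1e3, 1e3, 1e3, 1 / 8)  # O(1) scaling for the optimizer
  lower <- c(1e-4, 1e-3, 1e-3, 1e-3, 1e-5)
  upper <- c(1, d_max, d_max, d_max, k_max) * sc
  for (v in seq_len(n)) {
    tgt <- as.numeric(metrics[v, c("AD", "RD", "MW", "AW", "RW")])
    if (any(!is.finite(tgt))) next
    scale_t <- pmax(abs(tgt), c(1e-4, 1e-4, 0.05, 0.05, 0.05))
    md <- (tgt[1] + 2 * tgt[2]) / 3
    if (!is.finite(md) || md <= 0) next
    grid <- expand.grid(f0 = c(0.5, 0.35, 0.65, 0.8, 0.9),
                        k0 = c(4, 16, 1.5, 48))
    inits <- lapply(seq_len(nrow(grid)), function(r) {
      if (branch == "plus")
        c(grid$f0[r], 2.2 * md, 1.1 * md, 0.55 * md, grid$k0[r])
      else
        c(grid$f0[r], 0.6 * md, 1.7 * md, 0.55 * md, grid$k0[r])
    })
    best <- NULL
    for (p0 in inits) {
      p0s <- pmin(pmax(p0 * sc, lower * 1.01), upper * 0.99)
      fit <- tryCatch(minpack.lm::nls.lm(
        par = p0s,
        fn = function(ps) (smForwardVec(ps / sc) - tgt) / scale_t,
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 300,
                                             ftol = 1e-15, ptol = 1e-15)),
        error = function(e) NULL)
      if (is.null(fit)) next
      rn <- sqrt(sum(fit$fvec^2))
      th0 <- fit$par / sc
      gap <- th0[2] - th0[3]
      tol_b <- 1e-6 * max(th0[2], th0[3])  # branch-boundary tolerance
      s_ok <- if (branch == "plus") gap >= -tol_b else gap <= tol_b
      root_ok <- rn < 1e-6
      # lexicographic preference: genuine root > requested branch > residual
      better <- is.null(best) ||
        (root_ok && !best$root_ok) ||
        (root_ok == best$root_ok &&
         ((s_ok && !best$s_ok) || (s_ok == best$s_ok && rn < best$rn)))
      if (better) best <- list(par = th0, rn = rn, s_ok = s_ok,
                               root_ok = root_ok)
      if (rn < 1e-7 && s_ok) break   # exact root found; stop multi-start
    }
    if (is.null(best)) next
    th <- best$par
    tol_b <- 1e-6 * max(th[2], th[3])
    sign_ok <- if (branch == "plus") th[2] >= th[3] - tol_b else
      th[2] <= th[3] + tol_b
    in_bounds <- th[1] <= 1 && th[1] >= 0 &&
      all(th[2:4] <= d_max + 1e-12) && th[5] <= k_max + 1e-9
    valid <- best$rn < 1e-5 && sign_ok && in_bounds
    out$f[v] <- th[1]; out$Da[v] <- th[2]; out$DePar[v] <- th[3]
    out$DePerp[v] <- th[4]; out$kappa[v] <- th[5]
    out$odi[v] <- kappaToOdi(th[5])
    out$valid[v] <- valid
  }
  out
}

#' WMTI-Watson maps from an axisymmetric DKI fit
#'
#' Applies \code{\link{wmtiWatson}} voxel-wise to the AxiKurtosisFit metrics
#' (Dpar, Dperp as AD/RD and the MW/AW/RW amplitudes).
#'
#' @param fit an \linkS4class{AxiKurtosisFit}.
#' @inheritParams wmtiWatson
#' @return list of 3D maps: AWF, DA, DE_PARA, DE_PERP, KAPPA, ODI, valid.
#' @export
wmtiWatsonFit <- function(fit, branch = "plus",
                          bounds = list(d_max = 4e-3, kappa_max = 128)) {
  d3 <- dim(fit@coef)[1:3]
  vox <- which(fit@mask)
  idx <- arrayInd(vox, d3)
  cf <- matrix(fit@coef, prod(d3), 8L)[vox, , drop = FALSE]
  met <- data.frame(AD = cf[, 4], RD = cf[, 5], MW = cf[, 6],
                    AW = cf[, 7], RW = cf[, 8])
  res <- wmtiWatson(met, branch = branch, bounds = bounds)
  mk <- function(vals) { a <- array(NA_real_, d3); a[vox] <- vals; a }
  list(AWF = mk(res$f), DA = mk(res$Da), DE_PARA = mk(res$DePar),
       DE_PERP = mk(res$DePerp), KAPPA = mk(res$kappa), ODI = mk(res$odi),
       valid = mk(as.numeric(res$valid)))
}

# constrained (NODDI-DTI) forward: Da = DePar = d, DePerp = (1 - f) d
noddiForward <- function(f, kappa, d) {
  p <- new("StandardModelParams", f = f, Da = d, DePar = d,
           DePerp = (1 - f) * d, kappa = kappa, mu = c(0, 0, 1))
  m <- smForwardMoments(p)
  ev <- c(m$AD, m$RD, m$RD)
  md <- mean(ev)
  fa <- if (sum(ev^2) > 0) sqrt(1.5 * sum((ev - md)^2) / sum(ev^2)) else 0
  list(FA = fa, MD = md)
}

#' NODDI-DTI inversion of FA and MD maps
#'
#' Constrained standard model with fixed intraneurite diffusivity
#' Da = DePar = d_fixed and extra-axonal tortuosity DePerp = (1 - f) d_fixed.
#' The two observables (FA, MD) determine the two unknowns (f, kappa):
#' under the constraint the model MD depends only on f (monotone), so f is
#' found by 1D root finding of the forward MD, and kappa by 1D root finding
#' of the forward FA at that f. Voxels whose MD lies outside the admissible
#' range (no real solution f in [0, 1], i.e. MD outside
#' [d_fixed/3, d_fixed]) are flagged invalid rather than extrapolated, as
#' are voxels whose FA exceeds the attainable range at kappa <= kappa_max.
#'
#' @param fa_map,md_map 3D maps (or plain vectors) of FA and MD [mm^2/s].
#' @param d_fixed fixed intraneurite diffusivity [mm^2/s]; presets
#'   \code{noddiDTIPresets()}: 1.7e-3 (in vivo), 0.6e-3 (ex vivo).
#' @param mask optional binary mask.
#' @param kappa_max upper bound for kappa (default 128).
#' @return list of maps (or vectors): f, kappa, odi, valid; plus d_fixed.
#' @export
noddiDTI <- function(fa_map, md_map, d_fixed = noddiDTIPresets()$invivo,
                     mask = NULL, kappa_max = 128) {
  if (d_fixed <= 0) stop("d_fixed must be > 0")
  dm <- dim(fa_map)
  fa <- as.numeric(fa_map); md <- as.numeric(md_map)
  sel <- if (is.null(mask)) rep(TRUE, length(fa)) else as.numeric(mask) > 0
  n <- length(fa)
  f_out <- rep(NA_real_, n); k_out <- rep(NA_real_, n)
  valid <- rep(FALSE, n)
  for (v in which(sel)) {
    if (!is.finite(fa[v]) || !is.finite(md[v])) next
    # admissible MD range under the constraint: MD(f) = d/3 (3 - 4f + 2f^2)
    if (md[v] > d_fixed || md[v] < d_fixed / 3) next
    fr <- tryCatch(uniroot(function(f) noddiForward(f, 1, d_fixed)$MD - md[v],
                           c(0, 1), tol = 1e-12)$root,
                   error = function(e) NA_real_)
    if (!is.finite(fr)) next
    f_out[v] <- fr
    fa_max <- noddiForward(fr, kappa_max, d_fixed)$FA
    if (fa[v] > fa_max + 1e-9) { k_out[v] <- NA_real_; next }
    if (fa[v] <= 1e-9 || fa_max <= 1e-9) {
      k_out[v] <- 0
    } else {
      k_out[v] <- tryCatch(
        uniroot(function(k) noddiForward(fr, k, d_fixed)$FA - fa[v],
                c(0, kappa_max), tol = 1e-10)$root,
        error = function(e) NA_real_)
    }
    valid[v] <- is.finite(k_out[v])
  }
  shape <- function(x) if (is.null(dm)) x else array(x, dm)
  list(f = shape(f_out), kappa = shape(k_out),
       odi = shape(ifelse(is.finite(k_out), kappaToOdi(pmax(k_out, 0)), NA)),
       valid = shape(as.numeric(valid)), d_fixed = d_fixed)
}

#' Fixed intraneurite diffusivities for NODDI-DTI
#'
#' @return list with \code{invivo} = 1.7e-3 and \code{exvivo} = 0.6e-3
#'   [mm^2/s].
#' @export
noddiDTIPresets <- function() list(invivo = 1.7e-3, exvivo = 0.6e-3)
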