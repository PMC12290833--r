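---
title: "Models and estimators in dwikit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and estimators in dwikit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

dwikit estimates diffusion tensor, diffusion kurtosis, and two-compartment
white-matter model parameters from diffusion-weighted MRI magnitude data, and
ships a synthetic phantom generator so that every estimator can be validated
end to end without any scanner data. This vignette documents the models, the
numerical choices, and what the bundled validation does and does not show.

## Signal models

**DTI.** The log-signal is linear in the seven unknowns,
$\ln S = \ln S_0 - b\, g^\top D g$, with $D$ a symmetric tensor holding six
independent coefficients (stored as Dxx, Dxy, Dxz, Dyy, Dyz, Dzz, in
mm²/s). Rotation-invariant summaries are FA, MD, AD = $\lambda_1$, and
RD = $(\lambda_2+\lambda_3)/2$.

**DKI.** The kurtosis extension adds a fully symmetric fourth-order tensor
$W$ with 15 independent components:
$\ln S = \ln S_0 - b\,D(g) + \tfrac{b^2}{6}\,\mathrm{MD}^2\,W(g)$.
We use the MD²-scaled convention in which $W$ is dimensionless; the linear
design therefore estimates $\mathrm{MD}^2 W_{ijkl}$ (22 columns in total)
and divides by the fitted MD² afterwards. This convention is stated
explicitly because the two common scalings differ exactly by that factor.

Directional apparent kurtosis is $K(n) = (\mathrm{MD}/D(n))^2\,W(n)$. Two
metric families are kept deliberately distinct: MK/AK/RK summarize $K(n)$
(sphere mean, value along the principal eigenvector, mean around the
perpendicular great circle), while MW/AW/RW are contractions of the $W$
tensor itself (its sphere mean and its evaluations along/perpendicular to
the principal axis).

**Axisymmetric DKI.** Under a single symmetry axis the parameter space
reduces to eight: $\ln S_0$, the axis $(\theta,\phi)$, $D_\parallel$,
$D_\perp$, and the three kurtosis amplitudes $\bar W$ (MW), $W_\parallel$
(AW), $W_\perp$ (RW). The axis carries an antipodal gauge, $\theta \in [0,
\pi/2]$, which removes the sign degeneracy from the optimizer. Internally the
three amplitudes determine the full axisymmetric $W$ tensor through
$W_{1111}=W_{2222}=W_\perp$, $W_{1122}=W_\perp/3$, $W_{3333}=W_\parallel$,
and $W_{1133}=W_{2233}=(5\bar W - W_\parallel - \tfrac83 W_\perp)/4$ in the
eigenframe; `axiToFull()` exposes this bridge, and a test verifies that the
directional kurtosis of the expanded tensors matches the axisymmetric
prediction on random directions to 1e-10.

## Estimator families

* **OLS** solves the linearized model by unweighted least squares.
  Non-positive intensities are excluded from all log-domain fits (weight
  zero) rather than clipped; clipping would bias the residual distribution
  that the weighted estimators are designed to repair.
* **WLS** weights observations by the squared predicted signal magnitude
  (two reweighting passes from the OLS prediction), which counteracts the
  log-transform's distortion of the noise distribution.
* **Robust (IRLS)** factorizes the weight into three components,
  $w = w_\text{signal}\, w_\text{local}\, w_\text{slice}$, each in (0, 1]:
  the WLS magnitude weight; a Gaussian kernel on studentized residuals,
  $w_\text{local} = \exp\{-(r/(C\hat s))^2\}$ with $\hat s = 1.4826\,
  \mathrm{MAD}$ and $C = 1.5$; and a slice factor built from the median
  absolute residual of each (volume, slice) group, computed dataset-wide
  from an initial WLS pass, so whole corrupted slices are down-weighted even
  where a voxel's own residual happens to be small. The factorization is the
  contract; the Gaussian kernel and $C$ are this package's commitment and
  are configurable. IRLS runs at most 20 iterations, stopping when the
  largest relative coefficient change falls below 1e-6; when the weighted
  normal matrix becomes ill-conditioned (condition number above 1e8, as
  happens when outlier-dominated weights collapse), a Tikhonov term
  $\lambda_T = 10^{-4}\,\mathrm{tr}(X^\top W X)/6$ is added to the tensor
  rows.
* **NLLS** is Gauss–Newton on the non-logarithmic signal with OLS
  initialization, step-halving line search, at most 50 iterations, and a
  1e-8 relative tolerance on the objective decrease and step size.
  Non-converged voxels are flagged, never fatal.

The per-voxel root-mean-square model-fit error rms($\varepsilon$) is
computed in the fitting domain (log for the linearized fits, signal for
NLLS); thresholding it yields the reliability mask, which is monotone in
the threshold.

## Noise model and Rician handling

Magnitude data with $n$ receiver channels follow a noncentral-$\chi$
distribution ($n=1$: Rician) whose second moment obeys
$E[S^2] = A^2 + 2n\sigma^2$. Three consequences are implemented:

1. **Noise estimation.** The background (standard) estimator
   $\hat\sigma = \sqrt{\sum S_i^2 / (2Ln)}$ is exactly unbiased for
   $\sigma^2$ on pure-noise voxels; all volumes are pooled under the
   homogeneous-variance assumption, so a single scalar $\sigma$ is
   returned. The repeated-measures estimator averages per-voxel standard
   deviations across repeated b0 (or highest-shell) volumes, using the
   $n-1$ denominator; its small-sample downward bias at few repeats is the
   known property of the sample standard deviation.
2. **M2 correction** replaces each intensity by
   $\hat A = \sqrt{\max(S^2 - 2n\sigma^2,\, 0)}$. The clamp at zero keeps
   magnitudes non-negative; the clamped fraction is recorded as a QC
   metric. One property deserves emphasis: the *pointwise* corrected
   amplitude, averaged over draws, retains a Jensen bias of order
   $-\mathrm{Var}(S^2)/(8A^3)$, which at $A/\sigma = 5$ is comparable in
   magnitude (and opposite in sign) to the raw Rician bias. The correction
   is therefore consistent at the level of second moments — the pooled
   estimate $\sqrt{\overline{S^2} - 2n\sigma^2}$ is nearly unbiased — and
   that is the level at which the test suite asserts the bias reduction.
   Applying the correction twice over-corrects; the implementation warns.
3. **Rician-aware NLLS** replaces the model prediction by the first moment
   of the noncentral-$\chi$ distribution during fitting. For $n = 1$ this
   moment is evaluated in closed form (the $\sigma\sqrt{\pi/2}\,
   L_{1/2}$ expression expanded in exponentially scaled Bessel functions);
   for $n \ge 2$ by 64-node Gauss–Laguerre quadrature. Because this route
   assumes uncorrected data, it is mutually exclusive with a prior M2 step;
   both the fitters and the pipeline validator enforce the exclusion.

## Spherical quadrature

MK and the standard-model forward moments need averages over the sphere. We
use a Gauss–Legendre (in $\cos\theta$) × equispaced-$\phi$ product rule
(24 × 48 = 1152 nodes), which integrates the smooth integrands involved far
below the 1e-6 tolerance documented for the kurtosis metrics; a test checks
MK against a 10⁶-sample Monte-Carlo sphere average. A product rule was
chosen over tabulated quadratures of comparable degree because it is
generated in code at any order, keeping the node count a plain tuning
parameter. RK uses a 64-point trapezoid on the perpendicular great circle,
exact for the trigonometric polynomials that arise there.

## Two-compartment Watson standard model

A voxel is modelled as a Watson-distributed population of micro-domains,
each containing a zero-radius stick (diffusivity $D_a$, water fraction $f$)
and an axisymmetric extra-axonal Gaussian ($D_{e,\parallel}$,
$D_{e,\perp}$, weight $1-f$) sharing the domain orientation. With
$p(\kappa) = \langle\cos^2\psi\rangle$ and $q(\kappa) =
\langle\cos^4\psi\rangle$ (1D adaptive quadrature, tolerance 1e-12; the
azimuthal integrals are analytic), the directional moments
$E[D_c(n)]$ and $E[D_c(n)^2]$ are exact even polynomials in $\cos^2$ of the
angle to the mean axis, so $D(n)$ and the kurtosis field $K(n) = 3\,
\mathrm{Var}[D_c(n)]/D(n)^2$ are exact second/fourth-order tensor forms.
These are returned as the axisymmetric metrics (AD, RD, MW, AW, RW), and a
Monte-Carlo orientation average validates them in the tests.

**WMTI-Watson inversion.** The five metrics are inverted for
$(f, D_a, D_{e,\parallel}, D_{e,\perp}, \kappa)$ by Levenberg–Marquardt
root finding against this forward model, with residuals scaled per metric
and diffusivities rescaled to order one. The inversion is numeric by
design: the round-trip oracle (forward → invert on 200 random admissible
sets, max relative error below 1e-3) makes correctness testable without
transcribing closed forms, and a closed-form backend added later would have
to match the numeric route to 1e-6. The estimation is degenerate with two
branches; the requested branch ("plus", the default, with $D_a >
D_{e,\parallel}$ at the solution) selects the initialization half-space and
the accepted root, with a small tolerance at the branch boundary
$D_a = D_{e,\parallel}$ where the two roots merge (this boundary is exactly
where NODDI-DTI-constrained data live). Multi-start initialization over a
small $(f_0, \kappa_0)$ grid stops at the first on-branch root with
residual norm below 1e-7. Roots outside $f \in [0,1]$, diffusivities
outside $[0, 4\times10^{-3}]$ mm²/s (ex vivo preset: $1.5\times10^{-3}$),
or $\kappa > 128$ are flagged invalid rather than clamped, mirroring how
unphysical voxels appear in map-level inversions. Zero-kurtosis
(single-Gaussian) inputs have no valid two-compartment root and come back
flagged.

**NODDI-DTI.** The constrained model fixes $D_a = D_{e,\parallel} =
d$ (presets: 1.7·10⁻³ mm²/s in vivo, 0.6·10⁻³ mm²/s ex vivo) and the
tortuosity $D_{e,\perp} = (1-f)\,d$. At the DTI level the model MD depends
only on $f$ — $\mathrm{MD}(f) = \tfrac{d}{3}(3 - 4f + 2f^2)$, monotone on
[0, 1] — so $f$ is recovered by 1D root finding on the forward MD and
$\kappa$ by 1D root finding on the forward FA at that $f$. MD is admissible
iff a real $f \in [0,1]$ exists, i.e. $\mathrm{MD} \in [d/3,\, d]$; voxels
outside that range (a known failure mode when noise floor or kurtosis bias
depress MD) are flagged invalid, never extrapolated. ODI uses the fixed
convention $\mathrm{ODI} = \tfrac{2}{\pi}\arctan(1/\kappa)$, with
$\kappa = 0 \mapsto \mathrm{ODI} = 1$.

Both inversions are white-matter models; applying them to gray matter or
CSF-contaminated voxels is outside their validity, which is a documentation
contract rather than a runtime check.

## Phantom generator

`synthesizePhantom()` builds multi-shell datasets whose statistical
structure matches what the fitters assume: gradient schemes with uniform
sphere coverage by antipodally symmetric electrostatic-repulsion
minimization (deterministic given a seed; presets mirror the brain
18/30/45/60 volume layout at b = 0/600/1100/2500 s/mm², a cervical-cord
layout, and a six-shell ex vivo layout), noiseless signals from the DTI,
DKI, or standard-model generators, exact noncentral-$\chi$ noise
synthesized channel-wise (which validates the $2n\sigma^2$ identity by
construction), and slice-wise multiplicative dropouts as the outlier model
— the phenomenology of cardiac-pulsation signal loss, rather than additive
spikes. The crossing-band layout mixes two orthogonal populations 50/50 at
the signal level and is documented as beyond every single-fiber model's
validity; tests must not assert parameter recovery there.

What passing these tests shows: the estimators implement their equations
correctly, the noise stack is self-consistent, and the robust/Rician
machinery moves errors in the documented direction under the generator's
assumptions. What it does not show: behaviour under motion, eddy currents,
susceptibility distortion, spatially varying noise, partial volume, or
non-Watson fiber configurations — none of which the generator emulates.

The standard-model generator evaluates the exact Watson spherical
convolution, so fitting the (second-order) DKI model to it leaves an
$O(b^3)$ truncation gap: at $b_\text{max} = 2500$ s/mm² the diffusivities
agree with the forward moments to ~1%, while the kurtosis amplitudes carry
up to ~10% truncation error; the generator warns once $b \cdot D_\text{max}$
exceeds the cumulant-faithful range.

## Problem sizes and reproducibility

The bundled validation uses single-voxel fits for oracle comparisons (100
random voxels), 200 parameter sets for each inversion round trip, 10⁴
pooled background samples for noise recovery, 10⁵–10⁶ draws for the moment
identities, a 5×5×8 phantom at SNR 50 with 20% slice dropouts for the
robust-versus-OLS sweep, and a 10×10×5 phantom at SNR 25 for the
Rician-aware comparison. These sizes make the full suite run in a few
minutes on one core while leaving the Monte-Carlo margins comfortably
inside the asserted tolerances. Every stochastic step takes an explicit
seed; pipelines write a JSON provenance record (package version, options,
seed, input hashes) sufficient to replay a run byte-identically.

## Known limitations

* $\sigma$ is a single global scalar; spatially varying noise fields and
  coil-map-based estimators are out of scope.
* No positive-definiteness or positive-kurtosis constraints are imposed;
  out-of-range values are flagged, not clipped, so that downstream
  biophysical inversions see unbiased inputs.
* ECMOCO-style registration, susceptibility correction, and adaptive
  denoising are not part of this package; inputs are assumed aligned.
* The robust slice factor assumes slices are acquired axially (third array
  dimension); oblique or non-slice-wise artifact structure will dilute it.
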