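---
title: "Standard Model imaging of white matter: model, estimators and the sensitivity-specificity benchmark"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Standard Model imaging of white matter}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(smikit)
```

## The model

Diffusion MRI in brain white matter is commonly modeled as a collection of
identical fiber fascicles distributed over orientations. Each fascicle has
two non-exchanging water compartments: an intra-axonal "stick" (zero radial
diffusivity, axial diffusivity $D_a$, water fraction $f$) and an
extra-axonal axially symmetric Gaussian "zeppelin" (eigenvalues
$D_e^\parallel, D_e^\perp$). The fascicle response at diffusion weighting
$b$ and direction cosine $\xi = \hat g \cdot \hat n$ is

$$K(b,\xi) = s_0\left[f\,e^{-b D_a \xi^2} +
(1-f)\,e^{-b D_e^\parallel \xi^2 - b D_e^\perp (1-\xi^2)}\right],$$

and the voxel signal is the spherical convolution of $K$ with the fiber
orientation distribution function (ODF) $\mathcal P(\hat n)$. Diffusivities
are in $\mu m^2/ms$ and $b$-values in $ms/\mu m^2$ throughout; the free-water
ceiling $D_0 = 3\,\mu m^2/ms$ bounds all diffusivities. An optional isotropic
free-water compartment ($f_{iso} e^{-b D_0}$) is available in the forward
model but deliberately excluded from estimation: two-shell protocols at
clinical SNR do not carry enough information to resolve it.

Key assumptions inherited from the model class: no exchange between
compartments at clinical diffusion times, negligible axonal radius (sticks),
and Gaussian (long-time) extra-axonal diffusion, i.e. no residual diffusion
time dependence.

## Spherical-harmonic factorization and rotational invariants

In the even-order spherical-harmonic (SH) basis the convolution factorizes,
$S_{lm}(b) = p_{lm} K_l(b)$, where $K_l(b) = \int_0^1 K(b,\xi) P_l(\xi)
\,d\xi$ are Legendre projections of the kernel. Basis-independent per-shell
invariants

$$S_l^2(b) = \frac{\sum_m |S_{lm}(b)|^2}{4\pi(2l+1)}, \qquad
p_l^2 = \frac{\sum_m |p_{lm}|^2}{4\pi(2l+1)}$$

obey $S_l(b) = p_l K_l(b)$ for $l = 0, 2, 4, \dots$ — the identity the whole
package is built around, and the property the test suite checks most
aggressively (noise-free, to $10^{-6}$ relative, across random parameter and
ODF draws).

Convention: the package uses real SH, orthonormal on the sphere under the
solid-angle measure and without the Condon–Shortley phase. The $4\pi(2l+1)$
factor then makes a fully aligned (delta) ODF yield $p_l = 1$ and an
isotropic one $p_l = 0$; $p_0 \equiv 1$ by ODF normalization. Any internally
consistent convention would do — this one is fixed so that invariants are
directly interpretable as alignment metrics and results are reproducible.

With two shells and invariants up to $l = 4$ the data compress to
$2 \times 3 = 6$ independent features, matching the six model parameters
$\{f, D_a, D_e^\parallel, D_e^\perp, p_2, p_4\}$. This is why the benchmark
protocol has exactly two nonzero shells and why the feature set of the
learned estimator is $\{S_0, S_2, S_4\}$ per shell.

## The acquisition protocol

`default_protocol()` mirrors a ~6 minute clinical two-shell acquisition:
4 volumes at $b=0$, 20 directions at $b=1$, 60 at $b=2\,ms/\mu m^2$. The
clinical protocol it emulates specifies 4–5 $b=0$ volumes; 4 is used for
determinism. Directions follow a spherical-Fibonacci layout under a seeded
random rotation — the source publications do not print their direction
tables, so any quasi-uniform scheme is acceptable and the one used is
recorded in the protocol sidecar. Since only even-order SH are used,
$\hat g$ and $-\hat g$ are equivalent. Shells are grouped with a tolerance
of $0.1\,ms/\mu m^2$ (scanner b-values jitter); unit conversion from FSL
s/mm$^2$ tables is exactly $\div 1000$ and happens only at the file
boundary.

## Estimators

**SMI (learned).** A third-order polynomial regression (all monomials of
total degree $\le 3$; 84 terms for 6 features) maps the noisy, $b_0$-normalized
invariants to each parameter, fit by ordinary least squares on synthetic
training data. The training prior is Gaussian with mean
$(0.5, 2, 2, 0.7, 0.45)$ and variance $(0.06, 1, 1, 0.1, 0.06)$ over
$(f, D_a, D_e^\parallel, D_e^\perp, p_2)$, truncated to the physical box,
with $D_e^\perp \le D_e^\parallel$ by rejection and $p_4/p_2 \sim U(0.75,
0.85)$ (a histology-motivated range). The "variance" vector is interpreted
literally as variance, not standard deviation — the alternative reading was
kept in reserve but never needed: the benchmark reproduces the published
correlation pattern under the literal reading. Training noise is Gaussian at
the benchmark SNR of 25 and the model stores its SNR, prior and protocol
fingerprint so mismatched use is refused. The default training size is
$10^5$ draws, large enough that the regression is prior-limited rather than
sample-limited; the test suite trains at $5 \times 10^4$, which already
changes coefficients by well under 1%. Feature normalization by the measured
$b_0$ mean (not the true $s_0$) makes proton density a nuisance parameter
and is applied identically in training and inference. Outputs are clipped to
physical bounds with clip counts kept in diagnostics.

**NODDI-style.** Gaussian maximum likelihood on the directional signals
under hard constraints $D_a = D_e^\parallel = 1.7\,\mu m^2/ms$, tortuosity
$D_e^\perp = 1.7(1-f)$ and a Watson ODF; free parameters $(f, \kappa,
\hat\mu)$, with the scale $s_0$ profiled out analytically. The CSF
compartment is omitted to match the two-compartment simulations. The Watson
forward model is truncated at $l = 8$, where the neglected terms are far
below the benchmark noise floor. Multi-start is deterministic: a dense
$12 \times 12$ grid of $(f, \kappa)$ starts evaluated in one vectorized
sweep with the axis at the DTI principal eigenvector, then a per-voxel
Nelder–Mead refinement of $(f, \log\kappa, \theta, \phi)$ from the best
start. Watson invariants $p_l(\kappa)$ and constrained kernel projections
$K_l(b; f)$ come from cached spline tables (220-point log-$\kappa$ grid,
121-point $f$ grid), accurate to ~$10^{-6}$. Reported parameters: $f$ and
$p_2 = p_2(\hat\kappa)$ only — constrained parameters are never reported.

**SMT-style.** Nonlinear least squares of the two-compartment
spherical-mean model over $(f, D)$ with $D_a = D_e^\parallel = D$ and
$D_e^\perp = D(1-f)$. The stick mean uses the closed form
$\sqrt{\pi/(4bD)}\,\mathrm{erf}(\sqrt{bD})$ and the zeppelin mean
$e^{-bD_e^\perp}$ times the same form in $b\Delta$, $\Delta = D_e^\parallel -
D_e^\perp$, with a series branch below $b\Delta = 10^{-4}$ (agreeing with
the closed form to $10^{-9}$ at the branch point). The per-shell spherical
mean is taken as the $l=0$ SH coefficient rather than the plain directional
average: on 20–60 direction shells the plain average retains $l = 2, 4$
leakage of order $10^{-2}$, which would break the estimator's noise-free
self-consistency. A dense $(f, D)$ start grid is swept vectorized and the
best start refined per voxel by bounded Levenberg–Marquardt; $\hat f$ pinned
at a bound is flagged.

**WMTI-style.** Weighted linear least squares (two-pass, signal-squared
weights) fits the diffusion and kurtosis tensors; the two-compartment moment
relations are then evaluated along a 128-point direction grid:
$f = \max_n K(n)/(K(n)+3)$, per-direction compartment diffusivities from the
square-root branch with $D_a \le D_e^\parallel$, the intra-axonal tensor's
trace reported as $D_a$ and the extra-axonal tensor's axial/radial
eigenvalues as $D_e^\parallel, D_e^\perp$. Negative directional kurtosis
(common under noise) is clamped at zero before the square root rather than
flagging the voxel — flagging would discard a large, biased subset of the
benchmark and distort the comparison; only non-finite intermediates or
$f \notin (0,1)$ flag a voxel. WMTI's relations assume aligned fibers, so
dispersion leaks into its estimates; quantifying that leakage is precisely
what the benchmark does.

**W-WMTI (experimental).** The opposite branch ($D_a \ge D_e^\parallel$)
plus a Watson-type dispersion readout from the intra-axonal tensor's
normalized principal eigenvalue. This simplified per-direction construction
does not reproduce the full closed-form Watson algebra of the literature it
gestures at (the correct compartment assignment flips with direction when
the stick is axially faster but radially slower), so the estimator is
exported for completeness, excluded from the headline benchmark, and tested
only for structural properties.

Every estimator returns an `sm_estimates` object carrying only the
parameters it actually estimates, per-voxel failure flags and diagnostics.

## The sensitivity-specificity benchmark

Ground truths $(f, D_a, D_e^\parallel, D_e^\perp, p_2)$ are drawn uniformly
from $[0.3, 1.5, 1.5, 0.4, 0.3]$–$[0.8, 2.5, 2.5, 1, 0.8]$ (the most
probable white-matter range; with this box $D_e^\parallel \ge D_e^\perp$
never needs rejection), $p_4 = \rho\, p_2$ with $\rho \sim U(0.75, 0.85)$,
and each voxel gets a zonal (axially symmetric) ODF with exactly those
invariants at a uniformly random orientation. How full SH coefficient sets
should be realized from target $(p_2, p_4)$ is underdetermined; zonal ODFs
with random rotation are the simplest choice consistent with the stated
invariants, and invariants-based estimators are insensitive to the residual
freedom. ODF positivity is not enforced (a warning is available on request);
the corner of the box with $p_4/p_2$ large can dip slightly negative, which
affects none of the estimators studied. Signals are synthesized with SH
orders up to $l = 4$, and Gaussian noise with $\sigma = s_0/\mathrm{SNR}$,
SNR 25, is added once per volume — every estimator sees the same noisy
realization, so estimator differences are not noise-realization artifacts.

The Sensitivity-Specificity Matrix (SSM) is estimated by regressing each
estimated parameter on all five ground truths (with an intercept — the SSM
is a derivative statement and an intercept-free fit would bias the slopes),

$$S_{ij} = \frac{\langle\theta_i\rangle}{\langle\hat\theta_j\rangle}\,
\frac{\partial \hat\theta_j}{\partial \theta_i}.$$

Rows are normalized by ground-truth means and columns by the mean of the
estimates over the same voxels. The column convention matters for strongly
biased estimators: WMTI's dispersion-deflated $\hat D_a$ (mean
$\approx 1\,\mu m^2/ms$ against a truth mean of 2) roughly doubles its
column under the estimate-mean convention, and only that convention
reproduces the published values of the benchmark; for an unbiased estimator
the two coincide. An ideal estimator gives the identity; the matrix is
rectangular because constrained parameters are left out. $p_4$ is excluded
from the rows (nearly collinear with $p_2$ by construction); the SMI $p_4$
column is reported but should be read with that in mind. Flagged voxels are
dropped listwise per estimator with counts reported.

The prior-impact matrix repeats the regression against the prior mean
$\mu_{\theta_i}$: the learned estimator is retrained at each point of a
90–110% sweep (2.5% steps) of one prior mean at a time, applied to the same
fixed test set, and the mean estimate regressed on $\mu_{\theta_i}$. At
SNR 25 the response is close to linear ($R^2 > 0.99$ for the diffusivities
in this implementation); its magnitude is the complement of the parameter's
sensitivity, which is why the hard-to-estimate diffusivities are the most
prior-driven — and why absolute SMI values are only comparable across
studies using the same prior.

## What the generator does and does not emulate

The synthetic study emulates: the two-shell clinical protocol geometry, the
factorized signal model with realistic parameter ranges, dispersion through
zonal $l \le 4$ ODFs, and homoscedastic Gaussian noise at SNR 25 referenced
to $b_0$. It does not emulate: Rician noise floors (a Rician option exists
for robustness studies but is not the benchmark setting), spatially varying
coil sensitivity, preprocessing residuals (Gibbs ringing, motion, eddy
currents), partial-volume CSF, exchange in unmyelinated axons, or diffusion
time dependence. Passing the benchmark therefore demonstrates correctness
of the estimators and the claimed correlation structure under the stated
model, not performance on scanner data.

## Numerical choices

* Kernel Legendre projections: fixed 64-point Gauss–Legendre quadrature on
  $[0,1]$; doubling the order moves results by $<10^{-10}$ (tested).
* Watson moments: adaptive quadrature of the scaled integrand
  $e^{\kappa(\xi^2-1)}$, restricted to the boundary layer
  $[1 - 10/\sqrt\kappa,\, 1]$ for $\kappa > 100$; stable to $\kappa = 10^4$
  and beyond, cross-checked against a rejection-sampling Monte-Carlo oracle.
* SH designs: per-shell least squares via the normal equations with a
  condition-number guard ($>10^8$ errors out); shells with fewer directions
  than coefficients get a lowered `lmax` with a warning.
* Non-positive signals entering log-linear kurtosis fits are clipped at
  machine epsilon with a warning; the WLLS weights suppress their influence.
* Degenerate exponential fits (constant data) either fail cleanly or return
  a near-zero amplitude; the reported time constant is always $|\tau|$, with
  Jacobian-based 95% confidence intervals (t quantiles, $n-3$ df) — the CI
  construction for $\tau$ is not specified by the source analyses, and the
  Jacobian covariance is the standard default.
* ROI outlier exclusion computes $\sigma$ once, after removing unphysical
  values, and applies the $\pm 2\sigma$ cut in a single pass (not iterated);
  iteration is not specified in the source procedure and a single pass
  matches the reported typical exclusion fractions.

## Problem sizes

The full study runs 10,000 test voxels and is what `scripts/acceptance.R`
executes (roughly ten minutes, dominated by the per-voxel NODDI
refinement). The test suite runs a scaled-down replica — 2,000 test voxels,
$5 \times 10^4$ training draws, a 3-parameter 5-point prior sweep at
$2 \times 10^4$ draws per retraining — sizes chosen so the Monte-Carlo error
of any checked SSM entry stays below ~0.03 while the suite remains quick to
iterate on.

## Known limitations

* The learned estimator is protocol-specific by design; applying it to a
  different acquisition requires retraining (enforced via the protocol
  fingerprint).
* W-WMTI is a simplified construction (see above) and should not be used
  for quantitative comparisons.
* The benchmark's zonal ODFs cannot represent crossing-fiber asymmetries;
  rotational invariants are blind to the distinction by construction, but
  directional estimators (NODDI's axis fit) see slightly easier data than
  in crossing regions.
* No Rician-likelihood baselines: the Gaussian-noise benchmark setting makes
  Gaussian MLE the matched likelihood.
```
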