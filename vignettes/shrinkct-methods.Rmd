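---
title: "Learned-shrinkage low-dose CT reconstruction: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learned-shrinkage low-dose CT reconstruction: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(shrinkct)
```

This vignette is the package's account of the science it implements: the
measurement model, the two-stage learned-shrinkage reconstructor and its
training objective, the comparison algorithms, the evaluation measures, and
the numerical and design choices that were genuinely open.

## Measurement model and geometry

A 2D parallel-beam scan of an attenuation map $f$ (1/cm) measures photon
counts per detector bin,
$$ Y_\ell \sim \mathrm{Poiss}(\lambda_0 e^{-[Rf]_\ell}) +
   \mathcal{N}(d, \sigma_n^2), $$
where $R$ is the Radon transform (line integrals), $\lambda_0$ the source
photon count per ray — the dose control — and $\sigma_n$ the electronic
noise level. Throughout, $d = 0$. The default scan conditions are
$\lambda_0 = 1.5\times10^5$, $\sigma_n = 5$; Hounsfield units relate to
attenuation through $\mu = \mu_\mathrm{water}(1 + \mathrm{HU}/1000)$ with
$\mu_\mathrm{water} = 0.19\ \mathrm{cm}^{-1}$.

The discrete geometry (`ct_geometry()`) uses $n$ views evenly spaced over
$[0,\pi)$ for an $n\times n$ image and a centered detector of half-pixel
bins covering the image diagonal, giving $\approx 2.82\,n^2$ measurements.
The projector is pixel driven: the Radon transform of a square pixel at
angle $\theta$ is exactly a trapezoid of support $|\cos\theta| +
|\sin\theta|$, and each pixel deposits bin-box-averaged trapezoid masses
onto the bins it overlaps. This is the converged limit of integrating
narrow sub-rays and recombining them with linear weights, and it makes
projections of symmetric objects view-consistent to well under 1%. The
operator is materialized once per geometry as a sparse matrix, so the back
projector is its exact transpose: the adjoint identity
$\langle Rf, g\rangle = \langle f, R^*g\rangle$ holds to machine precision,
which the training gradients rely on. `back_project()` also offers an
`"integral"` weighting ($\Delta\theta \cdot \Delta s$) that approximates
the continuous angular integral; FBP and all gradients use the plain
adjoint with a single calibrated global scale (below).

## FBP

`fbp_reconstruct()` convolves each view with the discrete band-limited ramp
$$ \kappa(p) = \mathrm{sinc}(\pi p) - \tfrac12\,\mathrm{sinc}(\pi p/2)^2, $$
optionally composed in the frequency domain with the Butterworth window
$|H(\omega)| = (1 + (\omega/\varphi_0)^{2p})^{-1/2}$ (normalized frequency,
Nyquist = 1), then back projects. Numerical choices: the effective kernel is
computed with zero padding to at least twice the detector length (no
circular wrap-around) and applied as a symmetric Toeplitz matrix, so the
filter is exactly self-adjoint — convenient for the training chain. The
kernel length defaults to the full detector support. The absolute scale of
the discrete chain (the $\Delta\theta$, bin-spacing and kernel-normalization
factors) is calibrated once per geometry by projecting and reconstructing a
noiseless analytic disc and matching the known attenuation; the calibration
is independent of the Butterworth cutoff because the window has unit DC
gain.

## Variance stabilization

Shrinkage uses one scalar function per transform band, which presumes
homogeneous noise. The data-adjustment chain `omega_forward()` maps counts
to near-unit variance: remove the Gaussian component ($\hat y = y +
\sigma_n^2$, whose first two moments match a Poisson variable) and apply
the Anscombe root $z = 2\sqrt{\hat y + 3/8}$. Empirically the variance is
within [0.85, 1.15] for $\lambda \ge 20$. The inverse clamps at
`floor_counts = 1` photon before the $-\log$ — the filtered data can dip
below the transform's range, a case the measurement model itself never
produces, so the package must decide; one photon is the smallest physically
meaningful count.

## Learned shrinkage

Overlapping $d\times d$ patches ($d = 11$) are analysed in the unitary 2D
DCT; each of the $d^2$ coefficient bands gets an antisymmetric piecewise
linear shrinkage function through the origin with $K = 20$ positive knots
$(q_{ij}, p_{ij})$ (by antisymmetry, $2\times20$ pieces). Knot domains
$q_i$ are $K$ evenly spaced points from $r_i/K$ to $r_i$, where $r_i$ is
the band's maximal coefficient magnitude over the training set — frozen
with the model and reused at test time. Out-of-range coefficients extend
the last linear segment rather than clamping, which keeps the
parameterization exactly identity at $p = q$ for *all* inputs. Patch
lattices include windows flush with the borders so every pixel is covered
at any stride; overlapping contributions are averaged.

The slice transform writes the shrinkage of a coefficient vector as
$U_{q,\alpha}\,p$ with $U_{q,\alpha}\,q = \alpha$, i.e. the filter output
is linear in the knot values $p$. The package uses the same interval
weights for evaluation, for the explicit sparse `slice_transform()` matrix,
and for the training gradient, and tests both routes against each other.

## The MSEg error measure

Plain MSE rewards oversmoothing: large homogeneous regions dominate, and
fine low-contrast edges cost little. The training/evaluation measure adds a
one-sided penalty on *lost* gradient energy,
$$ \mathrm{MSEg}(f_0, \tilde f) = \|f_0 - \tilde f\|^2_{2,H} +
   \mu \sum_x W(x)\, \psi_\delta\!\big(\|\nabla f_0(x)\|^2 -
   \|\nabla \tilde f(x)\|^2\big), $$
with $H$ a binary HU-window mask (default $[-220, 350]$, the soft-tissue
display window, applied in training and evaluation alike), $W$ a binary
mask removing pixels whose reference gradient norm exceeds 2% of its
maximum (strong flesh–bone transitions would otherwise absorb the learning
capacity), and $\psi_\delta$ the one-sided Huber function (zero for
negative arguments). Defaults: $\mu = 100$ — the gradient term runs about
two orders of magnitude below the MSE term, so a weight near 100 makes it
effective — and $\delta = 25\ \mathrm{HU}^2$, a value the source material
never fixes; it sits at the crossover between the quadratic and linear
Huber regimes for per-pixel gradient losses of a few HU. Sums (not means)
over pixels are used, so the stated weights apply verbatim. Numerical
choices: $\nabla$ is forward differences with replicate boundary; a
constant reference yields an all-ones $W$ (a zero maximum would otherwise
make the threshold 0/0); the penalty is differentiable in $\tilde f$ and
its analytic gradient is finite-difference checked in the tests.

## Two-stage training

Stage I learns sinogram-domain shrinkage *through the reconstruction
operator*: with $z = \omega(y)$,
$$ \tilde f_p(z) = -T\big(\log\tfrac{1}{\lambda_0}
   \omega^{-1}(G_p(z))\big), \qquad
   \Gamma_p = \textstyle\sum_\mathrm{items} \mathrm{MSEg}(f_0, \tilde f_p(z))
   + \gamma\,\mathrm{reg}(p - q), $$
where $T$ is the *unwindowed* FBP. The filter is thus optimized for the
final image, not for raw-data fidelity. Stage II learns image-domain
shrinkage on the stage-I outputs (so it is tuned for exactly the images it
will receive), with weight $\gamma_I$. Defaults $\gamma = 10^{-4}$,
$\gamma_I = 250$; the regularizer `reg` is implemented as the *squared*
Euclidean distance from the identity — the unsquared norm is
non-differentiable exactly at the initialization $p = q$ where optimization
starts, and the squared form preserves the weights' meaning of restraining
deviation from identity. Optimization is L-BFGS (`optim`) from $p = q$;
gradients chain the MSEg gradient through the linear FBP adjoint, the
elementwise derivative of $-\log \circ\, \omega^{-1}$ (zero where the
count floor clamps), and the slice-transform linear path. Both objectives
pass central finite-difference checks at random off-identity points. One
fixed noise realization per training image is drawn (seeded and stored with
the model). Objective traces are recorded; the accepted-iterate trace is
non-increasing by construction of the line search.

## Comparison algorithms

*PWLS* minimizes $\tfrac12\sum_\ell W_\ell([R\tilde f]_\ell - g_\ell)^2 +
\gamma \sum_p \sum_{k \in N_4(p)} \psi(\tilde f_p - \tilde f_k)$ with
statistical weights $W_\ell = y_\ell^2/(y_\ell + \sigma_n^2)$ and a
symmetric Huber penalty on 4-neighbor differences, by L-BFGS-B with the
physical box constraint $f \ge -1000$ HU, initialized from windowed FBP,
90 iterations. The source protocol tunes the penalty weight and Huber
parameter by hand on training images; the package's defaults were fixed the
same way on the synthetic training phantoms (the objective is stated in HU,
so the weight is not numerically comparable to one stated for other units).

*ATM* replaces each count by a trimmed mean of its $M$ nearest bins
(discrete disc, ties broken row-major), discarding the $\lfloor M\alpha
\rfloor$ highest and lowest, with $M = 2\beta\lambda^2/(\lambda + \max(0,
x - \delta))$ and $\alpha = \alpha_m x / \lambda$ clipped to $[0, 0.5)$ —
strong smoothing for unreliable low counts. The inner parameters have no
prescribed scale; `atm_tune()` runs the coordinate-descent grid search on
training MSE that the protocol describes.

## Evaluation suite

`snr()` maximizes over a global intensity scale (closed form
$\alpha^* = \langle f,\hat f\rangle/\|\hat f\|^2$). `ssim()` is the
standard structural similarity (Gaussian 11×11 window, $\sigma = 1.5$,
$K_1 = 0.01$, $K_2 = 0.03$); no vetted R implementation is pre-installed,
so the package implements it and pins it in a test to a value computed
independently with scikit-image. SNR and SSIM are reported on
display-window-clamped images. `lir_fwhm()` probes spatial resolution:
single-pixel implants at maximal image intensity, reconstruction with and
without them, bicubic ×16 upsampling of each response, and the count of
above-half-maximum pixels converted to an equivalent full width
$2\sqrt{A/\pi}/16$ — a raw pixel count divided by the refinement factor is
not dimensionally a width for 2D spots; the equivalent-diameter convention
reproduces the closed-form Gaussian FWHM $2\sqrt{2\ln 2}\,\sigma$ and is
validated against it in the tests.

## Synthetic phantoms: what they emulate and what they do not

`random_phantom_spec()` draws abdomen-like slices: an elliptical
soft-tissue body (~45–60 HU) with a smooth ±20 HU low-frequency ramp, four
to five low-contrast organ ellipses (20–55 HU contrast — targets for the
gradient term), an annular long-bone cross-section with marrow plus a
solid bone disc (≥ 900 HU — the streak sources at low dose), and
optionally a sharp disc lesion. Primitive edges are feathered over 3 px,
slightly wider than the ~2 px point-spread function of the reconstruction
chain. This matters: clinical reference images are themselves
reconstructions and contain no spatial frequencies beyond the scanner's
passband, and an evaluation measure that penalizes lost gradient energy is
only meaningful when the reference gradients are attainable. With
sub-pixel edges the gradient penalty acquires an irreducible,
noise-masked floor that corrupts dose–quality curves.

What passing tests on these phantoms do *not* show: performance on real
anatomical texture (fine vessel trees, organ parenchyma), beam hardening,
scatter, detector effects, or fan-beam rebinning residuals — the simulator
implements the idealized parallel-beam compound Poisson-Gaussian model
only.

## Problem sizes and study conditions

Training uses 9 reference phantoms of 128×128 (the stable-optimization
regime of 9–12 images), $\lambda_0 = 1.5\times10^5$, $\sigma_n = 5$, $d =
11$, $K = 20$, $\mu = 100$, $\gamma = 10^{-4}$, $\gamma_I = 250$. The
sinogram-domain patch stride is 2 and the image-domain stride 1; stride 1
everywhere is the reference setting (maximal overlap), and stride 2 in the
measurement domain trades a marginal quality loss for a several-fold
smaller training problem — the package exposes both. L-BFGS caps: 100
iterations for stage I and 40 for stage II (the regimes where the two
objectives flatten out on this problem class). The dose-reduction
experiment holds out 2 phantoms, sweeps FBP over dose ratios $2^0 \ldots
2^5$ with the Butterworth cutoff retuned per level, and interpolates the
(log-dose, quality) curve; 3 noise replicates
per level keep the curve jitter below the interpolation step. The
per-level FBP cutoff is tuned on training phantoms and scored on the
held-out ones; tuning on the evaluation image itself would grant FBP an
oracle advantage the learned pipeline is not given.

## Known limitations

- The gradient-penalty term of MSEg is partially masked by reconstruction
  noise (noise *adds* gradient energy), so MSEg comparisons across very
  different noise levels mix resolution and noise effects; the package
  reports SNR and SSIM alongside.
- ATM's trim fraction grows with the local count, so isolated *high*
  outliers in low-count surroundings are smeared rather than trimmed; this
  follows the published parameter formulas.
- The pure-R ATM filter loops over bins and is the slowest baseline at
  full sinogram sizes.
- PWLS semi-converges under weak regularization (iterates first approach,
  then leave, the clean image); its iteration budget is part of its
  effective regularization, as for all early-stopped WLS schemes.
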