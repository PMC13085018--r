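---
title: "Separation bounds for freely rotating dipole emitters: models and numerics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Separation bounds for freely rotating dipole emitters}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the physical model, the numerical choices and
the known limitations of `dipolesep`. It is the place where design
decisions that the reference pages only state are explained.

## 1. The physical setting

A single fluorophore is an oscillating electric dipole. In aqueous
samples it typically tumbles much faster than its fluorescence
lifetime, so each detected photon comes from an effectively random
dipole orientation and the recorded signal is the *incoherent* sum of
the responses to x-, y- and z-oriented dipoles. Because the dipole far
field is vectorial, the response of a high-NA objective must be
computed per polarization component; a scalar (Gaussian/Airy) PSF is
not adequate.

The question the package answers: given two such emitters at separation
$d$ (with angle $\alpha$, centroid $(x_0, y_0)$, $s$ expected signal
photons and background $b$), what is the best achievable standard
deviation $\sigma_d$ of a separation estimate for a given detection
scheme (classical Cramér–Rao bound of the Poisson pixel model), and
what is the best over *all* physically possible measurements (quantum
Cramér–Rao bound of the one-photon state)?

## 2. Vectorial pupil model

### Fields

For an emitter at the sample-medium/coverslip interface, collected by
an aplanatic objective through a medium/coverslip/immersion index stack
$(n_1, n_2, n_3)$, the pupil-plane field components in the local
radial/azimuthal basis are

$$E_R \propto t_p\,(\mu_x \cos\theta_m\cos\phi +
       \mu_y \cos\theta_m\sin\phi - \mu_z \sin\theta_m)\,/\sqrt{\cos\theta_i},$$
$$E_A \propto t_s\,(-\mu_x \sin\phi + \mu_y \cos\phi)\,/\sqrt{\cos\theta_i},$$

where $\theta_m$ and $\theta_i$ are the medium- and immersion-side
polar angles linked by Snell's law, $1/\sqrt{\cos\theta_i}$ is the
Abbe sine-condition apodization in the collection direction, and
$t_p, t_s$ are products of the two interface Fresnel transmission
amplitudes. Beyond the medium's critical angle
($n_3\sin\theta_i > n_1$), $\cos\theta_m$ is continued as
$i\sqrt{\sin^2\theta_m - 1}$ (the $\mathrm{Im} \ge 0$ branch): this is
supercritical-angle fluorescence (SAF), visible as a bright ring in the
pupil between $k = k_0 n_1$ and $k = k_0\,\mathrm{NA}$. The Cartesian
components are $E_H = E_R\cos\phi - E_A\sin\phi$,
$E_V = E_R\sin\phi + E_A\cos\phi$.

The parity structure that drives everything else, exact on the grid:

| orientation | $E_A$ | $E_H, E_V$ |
|---|---|---|
| x, y | odd | even |
| z | $\equiv 0$ | odd |

The azimuthal component is odd for *every* orientation — this is the
mechanism that gives the polarization-sorted interferometric scheme its
perfect null.

### Emitter depth and focus

`emitter_depth` multiplies the pupil by
$\exp(i z k_0 n_1 \cos\theta_m)$. The default is 0 nm (emitter at the
interface, in focus), where SAF is strongest; no separate defocus term
is modeled.

### Normalization

The six fields of one emitter are jointly normalized so that the total
detected intensity per photon is 1 (Parseval, evaluated in the pupil).
The freely rotating average is absorbed into this joint normalization,
so the per-orientation norms equal the orientation's share of the
collected energy (they are close to, but not exactly, 1/3 at finite
NA — the z dipole couples differently from x/y).

### Grids and transforms

* **Pupil**: an odd $N \times N$ grid ($N = 129$ by default) spanning
  the NA disc symmetrically through $k = 0$, so that point inversion is
  an exact index reversal. Null-channel physics is probed down to
  machine precision, and any interpolation in the inversion would
  masquerade as visibility loss; the symmetric grid avoids that
  entirely.
* **Origin sample**: the R/A basis is singular at $k = 0$ ($\phi$
  undefined). The stored R/A components take their azimuthal principal
  value 0 there, while the Cartesian components keep their physical
  on-axis values. Without this choice the single self-inverting grid
  sample injects a spurious $\sim 10^{-4}$ even component into the
  azimuthal field.
* **Image**: the camera grid (150 px per axis, pixel
  $\lambda/(8\,\mathrm{NA})$, well below Nyquist) refined by a 2×2
  subpixel oversampling; pixel values are sums over their subpixel
  samples. Propagation to the image plane uses explicit DFT kernel
  matrices ($E_\mathrm{img} = A E_\mathrm{pup} A^T$) rather than an
  FFT: pupil and image samplings are then independent (the SAF ring is
  finely resolved without padding tricks), emitter offsets enter as
  exact tip-tilt phases, and the image grid is symmetric so the
  image-plane inversion is exact as well.

### Halo truncation

The hard NA edge and the SAF ring give the dipole PSF a slowly decaying
halo. At the default NA 1.45 field of view (150 px ≈ 8.8 µm) about 7%
of the photons fall outside the camera; enlarging the field to 300/450
px recovers only part of it (totals 0.965/0.978). The package keeps the
physical pupil normalization and does **not** renormalize within the
field of view: channel totals are therefore the in-view photon
fraction, identical across methods, and $\sigma_\mathrm{psf}$ is
converged at the default image size (which is the criterion used to fix
it). Exact sum-to-one behavior is available, and tested, with the
scalar Gaussian model, whose pupil and image supports are both
effectively compact.

## 3. Detection methods and channel algebra

With $\omega_{jl}$ the image-plane amplitude of orientation $j$ in
polarization $l$, direct detection measures
$I_l = \sum_j |\omega_{jl}|^2$, and the image-inversion interferometer
outputs

$$I_{\mathrm{sym/asym},l} = \sum_j \Big| \tfrac{1}{2}\big(\omega_{jl}(x,y)
  \pm \omega_{jl}(-x,-y)\big)\Big|^2 ,$$

which conserves energy channel-pair-wise. The five methods are DD;
SLIVER (sym, asym); SLIVER+DD (a 50/50 split: ½ DD, and the
interferometer on half the light); DD(A)+DD(R) (VWP + polarizing
splitter, both ports directly detected); and Polar-SLIVER (radial port
directly detected, azimuthal port into the interferometer). Channel
`weights` attributes record the nominal rational multipliers of these
definitions. Published channel-weight notations differ by where the
$\tfrac12$/$\tfrac1{\sqrt2}$ factors sit; the package fixes the
convention by requiring that each method's channels carry exactly the
emitter's total detected photons, which also makes the five methods
directly comparable.

Interferometer imperfections follow
$E_\pm = \tfrac{1}{\sqrt2}(\sqrt{1-r}\,\omega \pm
\sqrt{r}\,e^{i\Delta\phi}\,\omega_\mathrm{inv})$: split ratio
$r = \tfrac12$ and $\Delta\phi = 0$ recover the ideal case; energy is
conserved for any $(r, \Delta\phi)$. A 1:0.95 split or a 1° phase error
each keep Polar-SLIVER visibility above 0.999.

### Vortex wave plate

The VWP is a half-wave retarder with fast axis $\phi/2$; at retardance
$\delta = \pi$ it maps radial to horizontal and azimuthal to vertical
polarization exactly. The chromatic model uses a nematic liquid-crystal
retardance $\delta(\lambda) = 2\pi \Delta n(\lambda) t / \lambda$ with
Cauchy birefringence $\Delta n = a + b/\lambda^2$
($a = 0.18$, $b = 1.5\times10^4\,\mathrm{nm^2}$ by default, a generic
visible-range nematic LC giving $\Delta n \approx 0.21$ at 680 nm —
the acceptance of this choice is qualitative: visibility falls with
bandwidth, faster toward the blue). The thickness is calibrated so
$\delta = \pi$ at the design wavelength. Detuned operation leaves a
fraction $\cos^2(\delta/2)$ of the light unconverted, with the original
vortex polarization structure; its even part leaks into the
interferometer's null channel. Finite detection bandwidths average
channels over 11 equally spaced, equally weighted wavelengths (a flat
emission spectrum; a real fluorophore spectrum would weight the band
edges differently, which only rescales the effective bandwidth).

## 4. Fisher information: numerics

* **Derivatives**: central finite differences with steps
  $10^{-3}\sigma_\mathrm{psf}$ for lengths and $10^{-3}$ rad for
  $\alpha$; the model is linear in $s$ and $b$, so those derivatives
  are exact. Step-halving changes $\sigma_d$ at the $10^{-6}$ level,
  comfortably inside the quadratic regime.
* **Empty pixels**: for $b = 0$, a floor of $10^{-12}$ counts enters
  the $1/I_q$ factor only. Tests assert the reported bounds move by
  less than 0.1% when the floor is varied by three orders of
  magnitude.
* **Matrix inversion**: the FIM is prescaled by its diagonal before
  inversion (it is badly conditioned at small $d$, where
  $F_{\alpha\alpha} \sim d^4$); directions the data do not constrain
  report `Inf` rather than failing.
* **Background units**: $b$ is photons per $\sigma_\mathrm{psf}^2$,
  converted to per camera pixel and added uniformly to every pixel of
  every channel. Channel-wise allocation of a real background would
  depend on the instrument; the uniform convention treats all methods
  symmetrically.
* **Full vs one-parameter estimation**: under ideal conditions the two
  agree to plotting accuracy; under misalignment the full six-parameter
  bound is substantially larger for Polar-SLIVER (centroid and
  separation information become correlated through the null channel).
  The practical-degradation results (misalignment, background) are
  quoted from full-parameter estimation for this reason.

$\sigma_\mathrm{psf}$ is the geometric mean of the single-emitter DD
centroid bounds at $s = 1$, $b = 0$; isotropy is asserted at 0.5%. At
the study settings (680 nm, NA 1.45, mismatched stack) it is 166.5 nm.
Note that under index mismatch $\sigma_\mathrm{psf}$ is *not* monotone
in NA: beyond $\mathrm{NA} = n_1$ the SAF halo broadens the DD PSF and
costs localization precision (166.5 nm at NA 1.45 vs 141 nm at NA 1.3);
with a matched stack the usual monotone improvement holds.

## 5. Quantum bound: numerics

The one-photon density operator is built from the six generating states
(two emitters × three orientations) and their separation derivatives,
which are exact tip-tilt multiplications in the pupil; the state norms
are separation independent, so no normalization-derivative terms arise.
All twelve generators are orthonormalized through the eigendecomposition
of their Gram matrix, dropping directions below $10^{-10}$ of the
largest singular value (this absorbs the rank collapse at $d = 0$).
Because $\partial_d\rho_1$ lies exactly in that span, the reduced
$\le 12$-dimensional representation is not an approximation: it agrees
with a dense-grid computation of the same quantities on a coarse pupil
to $10^{-6}$ relative (tested). The SLD quantum Fisher information sums
$2|\langle e_i|\partial_d\rho_1|e_j\rangle|^2 / (\lambda_i + \lambda_j)$
over eigenpairs with $\lambda_i + \lambda_j > 10^{-12}\lambda_\max$.

Anchors that validate the machinery end to end: the scalar Gaussian
model reproduces the closed-form QCRB variance $4\sigma_\mathrm{psf}^2$
per photon at every separation (to grid accuracy, $\sim 10^{-5}$); the
pure-state limit reproduces
$4(\langle\partial\psi|\partial\psi\rangle -
|\langle\psi|\partial\psi\rangle|^2)$; the classical information of
every method stays below the QFI at every tested separation; and
Polar-SLIVER's one-parameter classical information reaches 43% of the
QFI at $d = 0.01\sigma_\mathrm{psf}$ (about half, the remainder being
carried by the z-oriented dipole component, which has no azimuthal
field), with its maximum near $d \approx 0.7\sigma_\mathrm{psf}$.

$\sigma_{\infty,\mathrm{QCRB}}$ is evaluated at $d = 16\sigma_\mathrm{psf}$
with a convergence check at $32\sigma_\mathrm{psf}$ (0.5% tolerance,
doubling with a warning if unmet).

**Known limitation.** The computed dipole-model QFI is flat in $d$ to
about 0.3% — the package does not reproduce a visibly *smaller*
$\sigma_{d,\mathrm{QCRB}}$ at $d \to 0$ than at $d \to \infty$. With
exact pupil-space states the orientation cross terms nearly cancel;
whether a genuinely larger effect survives in other constructions of
the one-photon state (e.g. truncated image-space states) is left open.
No package result depends on this, and the bound direction
(CFI ≤ QFI) is unaffected.

## 6. The synthetic-data generator

`sample_images()` draws independent Poisson counts per pixel per
channel from the expected two-emitter images; a fixed seed gives a
bit-identical stack. It emulates shot-noise-limited sCMOS/EMCCD-free
detection: no read noise, no excess noise, no pixel cross-talk, no
drift, and a background that is exactly uniform. Tests built on it
(mean/variance consistency, score-variance agreement with the Fisher
matrix at 3% on an 8×8 toy model with $10^5$ frames) therefore validate
the Poisson model and the information bookkeeping — they say nothing
about camera-specific noise on real data.

Problem sizes: the default study grids are 129×129 pupil samples and
150×150 pixels per channel (the settings behind every number quoted in
this vignette and in the acceptance script); unit tests exercise the
same code paths at 65×65 / 64×64, where all structural properties are
grid independent.

## 7. Parameter defaults at a glance

| parameter | default | meaning |
|---|---|---|
| $\lambda$ | 680 nm | far-red emission |
| NA | 1.45 | oil-immersion objective |
| $n_1/n_2/n_3$ | 1.33/1.516/1.516 | watery sample, glass, oil |
| pixel | $\lambda/(8\,\mathrm{NA})$ ≈ 58.6 nm | far below Nyquist |
| image | 150 px/channel | $\sigma_\mathrm{psf}$-converged FOV |
| oversampling | 2×2 | pixel integration |
| pupil grid | 129×129 (odd) | inversion-exact sampling |
| band sampling | 11 wavelengths, flat | emission-filter model |
| VWP | ideal; LC Cauchy $a=0.18$, $b=1.5\times10^4$ nm² | chromatic option |
| FD steps | $10^{-3}\sigma_\mathrm{psf}$, $10^{-3}$ rad | quadratic regime |
| count floor | $10^{-12}$ | empty-pixel regularization |
| subspace cutoff | $10^{-10}$ (Gram), $10^{-12}$ (eigenpairs) | rank handling |
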