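# dipolesep

How precisely can the distance between two single fluorophores be
measured, and how close does a given microscope come to the quantum
limit? `dipolesep` answers this numerically for the case that matters in
fluorescence microscopy: two **freely rotating dipole emitters**, whose
radiation is a vectorial field (an incoherent mixture over the x, y, z
dipole orientations) rather than the scalar Gaussian beam assumed by
most quantum-metrology treatments of the two-point-source problem.

The package is aimed at researchers in single-molecule localization
microscopy and optical quantum metrology who want to

- model the vectorial PSF of a dipole under a high-NA objective,
  including refractive-index mismatch and supercritical-angle
  fluorescence (SAF);
- compute classical Cramér–Rao bounds (CRB) for separation estimation
  under five detection schemes built from direct detection (DD) and
  image-inversion interferometry (SLIVER), among them **Polar-SLIVER**:
  a vortex wave plate (VWP) and polarizing beam splitter send the
  *azimuthal* component of the dipole radiation — which is odd under
  point inversion for every dipole orientation — into the
  interferometer, while the radial component is directly detected;
- compute the quantum Cramér–Rao bound (QCRB) from the two-emitter
  one-photon density operator;
- quantify practical degradations: chromatic VWP retardance over a
  finite detection bandwidth, fluorescence background, centroid
  misalignment, and interferometer split-ratio/phase errors.

## The model in brief

Expected camera counts for two identical emitters follow

```
I_2em(x, y) = s/2 · I(x − x0 − Δx/2, y − y0 − Δy/2)
            + s/2 · I(x − x0 + Δx/2, y − y0 + Δy/2) + b ,
```

with `(Δx, Δy) = d(cos α, sin α)`, per-channel PSFs `I` from the chosen
detection method, Poisson pixel noise, and parameter vector
θ = (d, α, x0, y0, s, b). The Fisher information matrix

```
F_ij = Σ_q (1/I_q) (∂I_q/∂θ_i)(∂I_q/∂θ_j)
```

gives the CRB `σ_d² = [F⁻¹]_dd` (or `1/F_dd` for one-parameter
estimation). The quantum bound comes from the one-photon state
ρ₁ = ½ Σ_j (|ψ_1j⟩⟨ψ_1j| + |ψ_2j⟩⟨ψ_2j|) over dipole orientations j,
via the symmetric-logarithmic-derivative quantum Fisher information
K_d evaluated in the exact reduced subspace spanned by the states and
their separation derivatives; `σ_d,QCRB = 1/√(s·K_d)`. All lengths are
reported in nm and normalized by `σ_psf`, the single-emitter DD
localization precision at one photon.

## Worked example

Typical far-red superresolution settings: λ = 680 nm, NA 1.45 oil
objective, watery sample (index stack 1.33/1.516/1.516), 150 × 150
pixels per channel at pixel size λ/(8·NA).

```r
library(dipolesep)
cfg <- optical_config(emission_wavelength = 680, numerical_aperture = 1.45,
                      n_medium = 1.33)
sp <- sigma_psf(cfg)                       # 166.5 nm

visibility(detection_model(cfg, "SLIVER"))       # 0.2786
visibility(detection_model(cfg, "PolarSLIVER"))  # 1.0000 (exact null)

s_inf <- sigma_inf_qcrb(cfg)               # 134.0 nm at s = 1
for (m in c("DD", "PolarSLIVER")) {
  mod <- detection_model(cfg, m)
  for (du in c(0.01, 16)) {
    fr <- fisher_matrix(mod, emitter_pair(d = du * sp), params = "d",
                        sigma_psf = sp)
    cat(sprintf("%-12s sigma_d(%5.2f sigma_psf) = %8.1f nm (%5.2f x QCRB_inf)\n",
                m, du, crb(fr)[["d"]], crb(fr)[["d"]] / s_inf))
  }
}
#> DD           sigma_d( 0.01 sigma_psf) =  31642.7 nm (236.15 x QCRB_inf)
#> DD           sigma_d(16.00 sigma_psf) =    335.2 nm ( 2.50 x QCRB_inf)
#> PolarSLIVER  sigma_d( 0.01 sigma_psf) =    203.8 nm ( 1.52 x QCRB_inf)
#> PolarSLIVER  sigma_d(16.00 sigma_psf) =    258.1 nm ( 1.93 x QCRB_inf)
```

Reading the numbers: at high NA the full dipole field mixes even and odd
components, so plain SLIVER interference is poor (visibility 0.28) and
direct detection of two emitters at `d = 0.01 σ_psf` is ~236× worse than
the asymptotic quantum bound. Sorting out the azimuthal polarization
restores a perfect interferometric null (visibility 1), and
Polar-SLIVER keeps `σ_d` within a factor ~1.5–2 of the quantum bound at
*every* separation — the divergence at small `d` is gone.

Parameter sweeps over separation, NA, bandwidth, background and
misalignment are available through `run_sweep(sweep_spec(...))`, which
returns a tidy data frame; Poisson image stacks for estimator studies
come from `sample_images()`. A thin command-line driver with `psf`,
`visibility`, `crb`, `qcrb`, `sweep` and `simulate` subcommands is
installed at `inst/cli/dipolesep.R`.

## Documentation

The methods vignette (`vignettes/separation-bounds.Rmd`) describes the
vectorial pupil model and its conventions, the channel algebra of the
five detection methods, numerical choices (grids, derivative steps,
floors, truncation), and known limitations.
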