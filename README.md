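# kamcorr

Ab initio 3D structure determination from single-particle X-ray
free-electron-laser (XFEL) diffraction snapshots, using high-order angular
correlations instead of per-pattern orientation assignment.

## The problem and the method

In XFEL single-particle imaging, thousands of identical copies of a particle
are exposed one at a time; each snapshot is a central slice of the 3D
diffraction intensity volume `I(k, θ, φ)` at an unknown random orientation.
`kamcorr` reconstructs `I` (and then the real-space density) from the
orientation-averaged statistics of the snapshots:

- **Double correlations** `C(k₁,k₂,ψ) = ⟨I(k₁)·I(k₂)⟩` over point pairs with
  included angle ψ, **triple** `T = ⟨I(k₁)²·I(k₂)⟩` and **quadruple**
  `D = ⟨I(k₁)²·I(k₂)²⟩` correlations, accumulated over all patterns with
  full mask support (partial patterns contribute every valid pair).
- Each ψ-curve is expanded in a **Fourier–Legendre series**
  `C(k₁,k₂,ψ) = Σ_l C_l(k₁,k₂) P_l(cos ψ)` over even degrees (Friedel
  symmetry kills odd l), giving per-degree partial correlation matrices
  related to the spherical-harmonic coefficients of the volume by
  `C_l(k₁,k₂) = (1/4π) Σ_m I_lm(k₁) I*_lm(k₂)`.
- `C_l` is a Gram matrix: its scaled eigenvectors `c_{l,i} u_{l,i}(k)` are
  basis vectors whose unknown unitary mixture `Ũ_l` is the remaining freedom.
  The same construction on `D_l` characterizes the squared volume `S = I²`.
  The triple correlations couple the two: the **constraint matrices**
  `W_l[j,i] = 4π v_j' T_l u_i/(d_j c_i)` must equal the model-side inner
  products `Ũᴴ_l Ṽ_l`. Minimizing the weighted mismatch ε over restricted
  unitary matrices — parameterized by hyperspherical angles,
  `i_max(2l+1) − i_max(i_max+1)/2` per subspace — recovers the volume up to
  a global rotation and mirror.
- **Noise elimination**: with per-pixel measurement variance
  `(1+α)·I_s + β` (Poisson shot noise plus pnCCD-style Fano/electronic
  noise), the estimators
  `T_s = T_d − (1+α)C − β·Ī_s(k₂)` and the analogous quadruple correction
  are exactly unbiased; isotropic Compton/instrument backgrounds are removed
  by a closed-form binomial inversion. This is what makes high-order
  correlations usable at realistic flux.
- **Phase retrieval** (HIO/ER with shrinkwrap) turns the reconstructed
  intensity into a density; agreement is quantified by Fourier shell
  correlation (half-period resolution at the 0.5 crossing) and NRMSE maps
  over shell pairs.

A full synthetic-data simulator (flat-Ewald slicing of |FT(density)|²,
uniform SO(3) orientations, flux scaling, backgrounds, masks, seeded noise)
makes every stage testable end to end.

## Worked example

```r
library(kamcorr)

cfg <- load_config()            # 48^3 blob phantom, 2.5 nm voxels,
cfg$detector_noise <- FALSE     # 80-pixel flat-Ewald detector, 500
cfg$maxiter <- 60L              # patterns at 1e13 photons/um^2/shot
arts <- run_pipeline(cfg)

sapply(arts$recon$trials, function(t) t$epsilon)  # per-trial final errors
arts$validation$intensity_correlation
arts$validation$fsc$resolution
```

On the default configuration this prints (exact trial errors vary only in
the last digits across BLAS builds):

```
[simulate] 2.0s  [correlate] 0.2s  [correct] 0.0s  [fit] 0.0s
[reconstruct] ~4min  [average] 22s  [phase] 41s  [validate] 65s
intensity correlation : 0.979
half-period resolution: 7.13 nm   (FSC 0.5 crossing at 0.070 nm^-1)
```

meaning the aligned reconstructed intensity volume agrees with the phantom's
at 0.98 correlation, and the phased density is resolved past a third of the
2.5 nm-voxel Nyquist frequency from only 500 shot-noise-limited patterns —
the scaled-down analogue of the full-size behavior of the method.

A thin command-line wrapper is installed with the package
(`system.file("cli/kamcorr", package = "kamcorr")`) with `phantom`, `run`
and `validate` subcommands over the same functions.

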