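---
title: "Correlation-based 3D reconstruction: model, corrections, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Correlation-based 3D reconstruction: model, corrections, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(kamcorr)
```

This vignette is the package's own account of the science it implements:
the statistical model, the correction formulas and why they are exact, the
parameterization of the alignment problem, and the numerical and design
choices made where more than one reasonable option existed.

## 1. The forward model

A single-particle XFEL experiment measures, per shot, a central (in the
flat-Ewald limit, planar) slice of the 3D diffraction intensity volume
$I(k,\theta,\phi) = |\mathcal{F}[\rho](\mathbf{k})|^2$ at a uniformly random
orientation. Throughout the package $k$ is spatial frequency in cycles/nm:
a detector pixel at radius $\rho$ maps to $k = (2/\lambda)\sin\theta_s$ with
$2\theta_s = \arctan(\rho/L)$, and a real-space grid with voxel size $a$
supports $k \le 1/(2a)$. The simulator scales the normalized slice to
photons/pixel as `flux * flux_scale`, with `flux_scale` a single
calibration constant (default `2e-10`, i.e. about $2\times10^3$ peak
photons per pixel at $10^{13}$ photons/µm²/shot). Every acceptance property
of the method depends on *relative* flux regimes, so this one constant is a
config value rather than a cross-section model; it is logged with every
dataset.

The volume is expanded in orthonormal complex spherical harmonics with
Condon–Shortley phase, $I(k,\theta,\phi) = \sum_{l,m} I_{lm}(k)
Y_{lm}(\theta,\phi)$. Real volumes satisfy $I_{l,-m} = (-1)^m I_{lm}^*$;
Friedel symmetry $I(\mathbf{k}) = I(-\mathbf{k})$ makes every odd-$l$
coefficient vanish, which is why only even degrees appear anywhere in the
pipeline.

## 2. Correlations and their decomposition

For points at shells $k_1, k_2$ separated by the included angle $\psi$, the
orientation averages
$$C = \langle I_1 I_2\rangle,\quad T = \langle I_1^2 I_2\rangle,\quad
D = \langle I_1^2 I_2^2\rangle$$
decompose per degree through the spherical-harmonic addition theorem:
$$C(k_1,k_2,\psi) = \sum_l C_l(k_1,k_2) P_l(\cos\psi),\qquad
C_l = \frac{1}{4\pi}\sum_m I_{lm}(k_1) I_{lm}^*(k_2),$$
and likewise for $T$ (squared-volume coefficients $S_{lm}$ on the $k_1$
leg) and $D$ (both legs). The $1/4\pi$ prefactor is not taken on trust: a
brute-force Monte-Carlo oracle — $10^5$ uniformly random rotations of a
small band-limited volume — confirms the decomposition within three
standard errors in the test suite, and all downstream scale factors
(`c = sqrt(4π·λ)` basis norms, the $4\pi$ in the constraint projection)
are fixed by round-trip identities rather than by convention.

The accumulator resamples each pattern onto a polar $(k,\phi)$ grid and,
in the flat-Ewald limit where $\psi$ is the folded azimuth difference,
computes all ordered shell-pair correlations by azimuthal FFTs with masks
carried as 0/1 indicator rows (pair counts come from the same transform).
A `direct` engine computes the identical sums by explicit pair enumeration
in canonical order; it is bit-identical to an independently written
quadruple loop and serves as the oracle route at small scale. Accumulation
is associative (chunked/streamed datasets merge exactly), so memory is
bounded by the chunk size, not the number of patterns.

The number of $\psi$ bins defaults to `n_phi/2 + 1` bin centers at the
exact folded azimuth shifts, which makes flat-Ewald binning error-free; a
curved-geometry pairing would bin by nearest center instead. `n_phi = 60`
by default, far above the `l_max/2 + 1` unknowns of the Legendre fit.

## 3. Noise elimination and background subtraction

The measured intensity is $I_d = I_s + \Delta_s + \Delta_d$ with
$\mathbb{E}[\Delta]=0$ and conditional variance
$\mathrm{Var} = (1+\alpha) I_s + \beta$: Poisson shot noise plus detector
noise with a signal-proportional (Fano) part $\alpha$ and an electronic
part $\beta$ (defaults $3\times10^{-4}$ and $1\times10^{-4}$, the order of
magnitude of a pnCCD at 1.24 keV). Only these first two moments matter.
For distinct pixels the noise is independent, and expanding the products
gives the unique unbiased inversions
$$C_s = C_d,\qquad
T_s(k_1,k_2) = T_d - (1+\alpha) C_s - \beta\,\bar I_s(k_2),$$
$$D_s = D_d - (1+\alpha)[T_s(k_1,k_2){+}T_s(k_2,k_1)]
- \beta[\bar S_s(k_1){+}\bar S_s(k_2)] - (1+\alpha)^2 C_s
- (1+\alpha)\beta[\bar I_s(k_1){+}\bar I_s(k_2)] - \beta^2,$$
with $\bar I_s$ the measured angular average and
$\bar S_s = \overline{I_d^2} - (1+\alpha)\bar I_s - \beta$. The derivation
is elementary but easy to get wrong, so the package treats the Monte-Carlo
oracle as the contract: $2\times10^5$ seeded noise realizations of a fixed
tiny pattern must show corrected biases within 3 batch-mean standard
errors of zero (and uncorrected biases beyond 10) before the formulas are
trusted. Nearest-neighbour polar interpolation is required on the noisy
path because any averaging interpolation changes the noise second moment;
the smooth bicubic resampler is reserved for noise-free analyses.

At $\psi = 0$, $k_1 = k_2$ the two points coincide and the noise is
self-correlated; those bins are excluded (`min_psi_bins = 2` by default)
rather than corrected, after which the Legendre systems remain strongly
overdetermined.

Isotropic backgrounds $b(k) = I_\mathrm{Compt} + I_\mathrm{inst}$ shift
$I_s = I + b$ deterministically; every corrected correlation of $I$
follows from the binomial expansion of $\langle (I_1+b_1)^p
(I_2+b_2)^q\rangle$, inverted in the order $C$, then $\overline{I^2}$,
then $T$, then $D$. On noise-free data the inversion is exact to machine
precision (a test asserts $10^{-12}$ relative). The default instrument
background is 5% of the coherent angular-average profile at every radius,
which keeps it isotropic; anisotropic backgrounds are rejected explicitly.

## 4. The alignment problem

Eigen-decomposition of each $C_l$ (symmetrized, negative eigenvalues
clipped and logged; at most $\min(2l+1, k_{\max})$ retained) gives basis
vectors $c_{l,i} u_{l,i}(k)$; the coefficient rows are
$I_{lm}(k) = \sum_i \tilde U_{l,m,i}\, c_{l,i} u_{l,i}(k)$ for some
unitary $\tilde U_l$, and analogously $S_{lm}$ with $\tilde V_l$ from
$D_l$. The triple correlations tie them together: at the true volume
$$W_l[j,i] = \frac{4\pi\, v_{l,j}^\top T_l\, u_{l,i}}{d_{l,j} c_{l,i}}
= (\tilde U_l^\dagger \tilde V_l)^\top[j,i],$$
and the reconstruction minimizes
$\varepsilon = \sum_{l,j,i} \big(c_{l,i}\sqrt{d_{l,j}}\,
|\tilde W_l - W_l|\big)^2$, plus, in subspaces where only one $D$-basis
vector is active, a unit-norm check $d_{l,1}(\lVert\tilde V_{l,1}\rVert-1)$
— without it cylindrically symmetric models collapse.

Only the top-ranked basis vectors (global descending-norm order, ties to
lower degree) are aligned; the D-side count equals the C-side count per
subspace. $\tilde U_l$ blocks are built from angles: hyperspherical unit
vector, branch-free closed-form orthogonal completion (column $j{+}1$ is
the normalized partial derivative of the hyperspherical map — identity at
zero angles, a rotation matrix at $N=2$), recursive right-multiplication
of trailing blocks, then a fixed unitary map pairing $\pm m$ rows so the
conjugate symmetry (hence realness of the volume) holds for *any* angles.
The count $i_\max(2l+1) - i_\max(i_\max+1)/2$ per subspace totals 1176
for full alignment of the even subspaces through $l = 14$. The $l = 0$
factor is a $\pm1$ sign, searched discretely at each schedule stage.

Optimization is progressive: vectors enter one at a time by rank; after
each introduction all active angles are refit by Levenberg–Marquardt least
squares (`minpack.lm::nls.lm`, forward-difference Jacobians, `ftol
= 1e-10`, default 100 iterations per stage) with the previous optimum as
the start. Residual evaluations synthesize the volume on a quadrature grid
sized so that analyzing the *squared* volume at the fitted band limit is
exact (Gauss–Legendre polar nodes $\ge (3 l_{\max}+1)/2 + 1$, azimuthal
nodes $> 3 l_{\max}$), restricted to even-degree harmonics for speed.
Independent trials (20 by default, 4 in the scaled-down tests) start from
seeded random angles; the solution is defined only up to a global rotation
and mirror, so trials are aligned to the lowest-error trial by a seeded
coarse rotation search (Shoemake candidates plus the flip) refined by
Nelder–Mead, then averaged pointwise and re-analyzed. A trial is dropped
as an outlier when its error exceeds three times the best trial's (with a
small floor tied to the constraint scale, so a cluster of near-zero errors
is never split); a best-relative rule was chosen over a median rule
because small trial counts make the median unstable when the error
distribution is bimodal.

Two honest caveats, both visible in the test suite. First, the local
optimizer regularly stops in local minima — the motivation for the
multi-trial average; on an exactly low-rank model the global minimum is
reached in most trials, on richer models in a fraction of them. Second,
with very few basis vectors and a small band limit the *restricted*
constraint set ($j \le j_\max$) can admit spurious exact solutions that
reproduce $C_l$ but not $D_l$; compact, realistically structured particles
at the default scale (`l_max = 12`, top 9) are empirically well pinned,
random coefficient soups at `l_max = 4` are not. The unit tests therefore
assert the guaranteed invariants (ground-truth zero, unitarity, realness,
$C_l$ reproduction), and genuine volume recovery is asserted on phantoms.

## 5. Phasing and validation

The spherical volume is embedded into a Cartesian Fourier grid by
evaluating the even-degree series at each voxel direction with linear
radial interpolation; voxels beyond the measured $k$ range stay
unconstrained. Phasing uses hybrid input–output ($\beta = 0.9$)
interleaved with error-reduction (every 10th iteration and the final 20%),
realness and non-negativity in the object domain, and shrinkwrap support
updates every 30 iterations (Gaussian smoothing annealed from 3 to 1.5
voxels, threshold 5% of the smoothed maximum). Several seeded random
starts are run and the lowest Fourier-residual run is kept. On exact
magnitudes of a compact phantom the recovered density correlates $\ge
0.99$ with the truth after subvoxel translation/inversion alignment
(parabolic peak interpolation on the cross-correlation, applied as a
Fourier phase ramp — integer-only alignment caps the correlation well
below that).

Fourier shell correlation is read out at the 0.5 threshold with linear
interpolation between shells; the half-period resolution is $1/(2 k_c)$
in nm. Note that a deterministic low-pass filter alone cannot move a
shell-normalized FSC (it is invariant under positive per-shell scaling);
the calibration tests therefore engineer the analytic FSC by mixing
shell-power-matched independent noise with a Gaussian transfer, and read
the crossing against its closed form. NRMSE maps divide the RMS deviation
over defined $\psi$ bins by the RMS magnitude of the target curve — the
"magnitude" convention adopted here — and flag all-zero targets as
undefined.

## 6. What the simulator does and does not emulate

It does: uniform random orientations, flat- or curved-Ewald slicing by
trilinear interpolation, flux scaling, Poisson and Gaussian detector noise
with the exact second-moment model above, isotropic Compton/instrument
backgrounds, shared or per-pattern masks, per-pattern reproducible seeds.
It does not: beam-profile structure, sample heterogeneity or multi-particle
hits, detector gain maps, module-correlated noise, charge sharing, or
anisotropic backgrounds. Passing tests therefore demonstrate the
statistical machinery under the stated noise model, not robustness to
real-detector pathologies — the corrections consume the same $\alpha$,
$\beta$ and background profiles the simulator (or a calibration) provides,
and a mis-specified noise model biases $T$ and $D$ in proportion.

## 7. Problem sizes used in the checks

The scaled-down study conditions used throughout the tests were chosen
once as a realistic desk-scale analogue of the full experiment: a 48³
blob phantom with 2.5 nm voxels, an 80-pixel flat-Ewald detector with
0.2 nm⁻¹ edge at $\lambda = 1$ nm (pixel pitch trimmed 4% inside Nyquist
so slices interpolate cleanly), 500 patterns at $10^{13}$
photons/µm²/shot with shot noise, 12 radial shells spanning 15–95% of the
edge, `l_max = 12`, the top 9 basis vectors, 4 optimization trials at 60
LM iterations per stage, and 48³ phasing grids. The Monte-Carlo noise
oracles use $2\times10^5$ realizations of a 2-shell × 8-azimuth pattern;
the orientation-average oracle uses $10^5$ rotations; convergence checks
use 100–1600 patterns. The corner-mask comparison runs a lighter
configuration (32³ phantom, `l_max = 8`, top 6, 2 trials) twice. With
these sizes the whole suite and the end-to-end reconstructions complete on
one CPU core in well under half an hour.

## 8. Known limitations

- The local least-squares optimizer bounds the achievable resolution;
  global schemes (annealing) are out of scope here as they are in the
  method itself.
- Multi-particle (fluctuation-scattering) corrections, orientation
  recovery from the reconstructed model, and fluctuating detector
  parameters are out of scope.
- Artifact files use RDS (and MRC for densities, TSV/JSON for curves and
  reports); there are no HDF5 bindings in the dependency set, so the
  CXI-style HDF5 layout is not emitted.
- The $\psi$-binning is exact only for flat-Ewald geometry; curved-geometry
  accumulation bins by nearest center and is untested against experiment.
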