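---
title: "Methods: model-based optimization of diffuse Raman collagen detection"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: model-based optimization of diffuse Raman collagen detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(DiffuseRaman)
```

# The problem

A subcutaneous implant triggers a foreign body response that deposits a
collagen-rich fibrotic capsule, tens to hundreds of micrometres thick,
around the implant. Monitoring that capsule *in vivo* — without excising
tissue — requires detecting the Raman signature of a thin collagen layer
sitting roughly 1.5 mm below the skin surface, under a hard safety
constraint: the laser power density on skin may not exceed the maximum
permissible exposure (MPE), 3 mW/mm² for continuous 785 nm illumination.
This package implements the full design loop: a photon transport model over
a digital phantom, a shot-noise SNR objective for the collagen band, a
constrained search over excitation/detection geometries, limit-of-detection
estimation, and the spectral calibration pipeline that would be applied to
measured spectra, exercised end to end on synthetic data.

# Phantom geometry

`buildPhantom()` constructs a layered slab: skin (default 0.75 mm) over fat
(0.75 mm) over muscle, at least 20 × 20 × 20 mm so boundary losses are
negligible. A polystyrene disk (radius 4 mm, thickness 2 mm) sits with its
assembly top at `implantTopDepth` (default skin + fat = 1.5 mm, the depth of
a subcutaneous pocket). The collagen layer is a uniform cylindrical slab of
the disk radius occupying `[implantTopDepth, implantTopDepth + t]`; the disk
sits directly below it. `collagenThickness = 0` gives the
"initial-conditions" sample (implant as freshly placed); positive
thicknesses give the "FBR" sample. Membership queries use half-open
intervals, so every point receives exactly one material label and the
labels partition the domain; the geometry is rotationally symmetric about
the implant axis.

`thicknessFromMass()` converts a deposited collagen-solution mass to the
mimicked capsule thickness, t = m·f/(ρ·A), with the fibrotic-capsule
collagen density ρ = 500 µg/mm³ and the disk area A = π·4² mm². With a
1:10 collagen:KOH solution (f = 1/11) this evaluates to ≈ 3.6 mm of
thickness per gram of solution. Reported thickness/mass constants near
6 mm/g are not reproducible from these parameters; the function therefore
exposes every parameter explicitly and no fixed constant is baked in.

# Photon transport

The diffusion approximation is solved on a structured, node-centred grid
(default spacing 0.6 mm) with a 7-point finite-difference stencil:
face conductances use the harmonic mean of the nodal diffusion coefficients
κ = 1/(3(µₐ + µₛ′)), absorption enters as µₐh³ on the diagonal, and the
Robin (partial-current) boundary adds h²/(2A) per exposed face, with the
internal-reflection parameter A computed from the refractive index mismatch
(Egan–Hilgeman fit for the effective reflectance). A collimated beam is
represented as an isotropic point source buried at one transport mean free
path (1/µₛ′) under each pattern point; extended patterns (lines,
rectangles, disks, circle outlines) are uniformly weighted point sets with
total launched power fixed at 1, so geometries are photon-budget comparable
at equal laser power.

The system is symmetric positive definite and is factorized once (sparse
supernodal Cholesky); every excitation and adjoint solve reuses the
factorization, which is what makes the 441-detector sweep cheap (one
triangular solve per detector). Point detectors measure the outward partial
current Φ/(2A) times the 0.1 × 0.1 mm collection area; the adjoint field of
that functional gives, by reciprocity, the detected fraction per
isotropically emitted photon at every node. On a homogeneous semi-infinite
medium the solver agrees with the extrapolated-boundary dipole solution to
within ≈ 2.3 % at 3–10 mm source–detector separations (the tests assert
5 %).

**Optical properties.** The source publications in this area rarely print
the phantom's optical coefficients, and none were available here; the
shipped defaults (`opticalDefaults()`: skin µₐ 0.02 / µₛ′ 1.6 mm⁻¹, fat
0.01/1.0, muscle 0.03/0.7, polystyrene 0.002/2.5, collagen treated as
skin-like, n = 1.4 everywhere) are literature-style NIR values and are
documented assumptions. Consequently every geometric conclusion that
depends on them — the exact argmax offset, absolute SNR values — is treated
as qualitative (symmetry, *nonzero* offset, √2 combination ratios), never
as a number to reproduce.

**Raman emission.** Detected yields use the Born single-conversion model:
yield = Σ Φ_exc·Φ_adj·V over the nodes of a material region, with equal
optical properties in the excitation and emission bands by default. The
absolute scale of an SNR value is then (launched photons) × (Raman
conversion efficiency); `defaultPhotonScale()` fixes the unit convention at
45 mW × 900 s at 785 nm times a nominal 10⁻¹⁶ conversion. Ratios, argmax
locations and LOD *ratios* are independent of this constant.

# The integration sub-grid

The collagen slab (10–200 µm) is far thinner than the 0.6 mm node spacing,
so material-resolved yields are integrated on a refined sub-grid: the base
cells intersecting the slab's depth range are tiled with sub-cells —
spacing/⌈spacing/refined⌉ ≈ 0.075 mm laterally (refined default 0.08 mm)
and 0.01 mm axially — and the smooth fields are evaluated there by
trilinear interpolation. Two numerical points motivated the anisotropy:

* the transport fields vary on the millimetre scale, so 0.075 mm lateral
  sampling is already conservative; but
* membership of a 10–200 µm slab must be resolved *axially*: with 0.01 mm
  bins, every thickness in the calibration design (all multiples of 10 µm)
  is captured exactly, and the collagen yield is linear in thickness with a
  zero-intercept R² ≈ 0.9996 over 0–200 µm — the assumption behind the
  limit-of-detection formula.

Coarse nodes inside the refined region have their cell weight transferred
to the sub-grid, so the coarse + fine point set is an exact partition of
the cell volume: per-material yields always sum to the all-material yield
to machine precision. The residual departure from perfect thickness
linearity (≈ 4 % between t = 200 µm and 2 × t = 100 µm) is the physical
depth decay of the excitation × sensitivity product across the slab, not a
discretization artifact.

# The SNR objective and limits of detection

`computeSNR()` implements the shot-noise SNR of the 910–950 cm⁻¹ band:
signal = n_FBR^Collagen · I_Raman^Collagen; noise = √(Σ n·I_Raw) with the
sum over every material of *both* samples, because the experimental
collagen signal is obtained by subtracting two spectra whose shot noises
add. Band intensities come from `bandIntensities()`: I_Raw is the raw band
total; I_Raman subtracts a local linear baseline through the mean counts of
3-channel anchor windows centred on the channels nearest the band edges
(the anchor width is configurable; 3 channels is a robust minimal default).
Reference intensities for materials with no Raman bands inside the window
can come out marginally negative (band-tail curvature under the chord) and
are floored at zero.

`lodFromSNR()` converts the SNR at a 100 µm reference layer to a thickness
limit of detection, t_LOD = criterion · 100 µm / SNR₁₀₀, with the one-sided
95 % criterion 1.645 (`detectionCriterion()` exposes the standard-normal
quantile; both the criterion and the reference thickness are explicit
parameters). Disjoint detector areas combine by `combineDetectors()`:
signals add, noises add in quadrature, so two symmetric rectangles at SNR
6.7 give 6.7·√2 ≈ 9.5.

# Geometry search

The search space follows the practical constraints: simple shapes (point,
circle, disk, line, rectangle), source and detector disjoint, everything
inside a 10 × 10 mm area centred over the implant, source power density ≤
MPE. Detector positions live on a 21 × 21 grid from −5 to +5 mm (441
points, 0.5 mm pitch). `optimizeGeometry()` sweeps the configured
source/detector candidates (rectangle offsets in 0.5 mm steps), filters by
MPE and disjointness, ranks by SNR with deterministic tie-breaks (smaller
detector area first, then lexicographic), and attaches t_LOD to each row.
A 45 mW point beam (5700 mW/mm²) always fails the MPE filter; spreading
the same power into a 10 × 2 mm line (2.25 mW/mm², or 3 mW/mm² for the
built 10 × 1.5 mm variant) is feasible, and the symmetric dual-rectangle
collection wins by the quadrature factor. The pipeline is fully
deterministic — no seeds are involved on the model side.

`fiberSubsetSNR()` models the realizable fiber-bundle detector: seven
points spanning −0.5 to +0.5 mm (the bundle head spacing) at a lateral
offset, combined in quadrature.

# The synthetic-data generator

The generator emulates exactly the statistical structure the analysis
assumes, and no more:

* material reference spectra as sums of Gaussian/Lorentzian bands over a
  smooth quadratic background, on an 800–1800 cm⁻¹ axis at 2 cm⁻¹ (the
  polystyrene ring-breathing band at 1004 cm⁻¹ dominant; collagen's
  850/930 cm⁻¹ proline/hydroxyproline bands; the usual amide and CH
  regions for skin, fat, muscle). Relative cross-sections of the materials
  are not published, so band heights are documented free parameters;
* composite spectra as weight-sums of the references — the linear mixing
  implicit in the per-material yield model — with initial-conditions
  weights (polystyrene 1, skin 0.8, fat 0.5, muscle 0.3) and a collagen
  weight of 0.002 per µm of thickness, chosen once so that the collagen
  band is a small feature on a dominant background, as in the phantom
  measurements;
* Poisson shot noise per channel (read noise omitted: counts are
  shot-noise dominated), with per-spectrum seeds derived from a master
  seed by a counter, so datasets regenerate byte-identically and extend
  without reshuffling.

`calibrateNoiseToSNR()` rescales the count scale so the *expected* band
SNR of a generated pair at 100 µm hits a target exactly (signal scales
linearly, noise as the square root, so the rescale is (target/current)²).
What the generator does **not** emulate: fluorescence photobleaching
kinetics, instrument line-shape and throughput variation, cosmic rays,
wavelength miscalibration, and biological variation between animals. Tests
passing on this generator therefore validate the analysis chain's
statistical behaviour, not its robustness to those real-data artifacts.

# Calibration pipeline

Each spectrum is min–max normalized over a 990–1020 cm⁻¹ window so the
polystyrene 1004 cm⁻¹ band spans [0, 1] (the normalization target is named
"between 0 and 1" in the field; the window width is configurable). The
normalized initial-conditions spectrum is subtracted channel-wise from its
paired FBR spectrum — axes must match exactly; no resampling is performed —
and the implant's own bands cancel (the residual polystyrene feature around
1004 cm⁻¹ is < 5 % of the collagen band area on noise-free pairs).

`fitPLS()` regresses thickness on the full difference spectra
(mixOmics PLS, unscaled), choosing the component count by minimum
leave-one-out RMSE with a cap of 8 and ties broken towards fewer
components; the cap is further limited by the training-set rank so
noise-free rank-1 designs select one component and recover the structure to
machine precision. The LOO RMSE is the calibration's LOD surrogate. The
default design is the 16-spectrum series (10, 20, 40, 60, 80, 100, 150,
200 µm × 2 replicates). At generator noise calibrated to SNR₁₀₀ = 4.0 the
LOO RMSE lands near 20 µm, consistent with (and slightly better than) the
≈ 25 µm 1σ value implied by t_LOD = 41 µm — the expected gain from using
the whole spectrum rather than one band.

`fitRegressionLOD()` implements the single-band alternative: OLS of
collagen band area against thickness, with t_LOD = criterion·RMSE/|slope|.
Published single-band LODs are sometimes quoted with the criterion absorbed
(i.e. RMSE/|slope| alone), so both variants are reported; neither is
asserted against external values, whose units are ambiguous.
`portableCalibration()` reduces a fitted PLS model to its equivalent linear
map (coefficients + centring), which predicts identically and serializes to
plain JSON.

# Numerical choices and degenerate inputs

* Linear solver: sparse Cholesky (CHOLMOD), deterministic assembly order;
  solutions are reproducible to the 10⁻¹⁰ level across factorization reuse.
* Grid convention: nodes per axis = ⌊extent/spacing⌋ + 1, x/y centred on
  the implant axis, z from 0 (surface) downwards; boundary cells carry
  half-weights so cell volumes tile the domain exactly.
* Band integration requires ≥ 4 channels in the band and errors outside
  the axis; flat normalization windows, zero total counts (undefined
  noise), zero regression slopes, unpaired series entries, axis mismatches
  and unknown materials all raise descriptive errors rather than returning
  NaN.
* Display: LODs and predictions are reported to whole micrometres;
  internal values keep double precision.

# Problem sizes

The shipped defaults (also used by the test-suite and the acceptance
script) are: 34³ ≈ 39 000 transport nodes at 0.6 mm for the 20 mm phantom
(51 × 51 × 34 for the 30 mm oracle domain), 441 detector positions, a
≈ 0.2 million-point integration sub-grid around the collagen slab,
16-spectrum calibration sets, and 5–20 generator seeds for Monte-Carlo
consistency checks. These sizes keep a full geometry sweep around ten
seconds on one core while leaving discretization error well inside the
tolerances asserted by the tests.

# Known limitations

* The diffusion approximation is inaccurate within ~1 transport mean free
  path of sources; the 3–10 mm validation range avoids that regime, and
  sub-millimetre offsets should be read qualitatively.
* Optical properties and Raman cross-sections are assumptions; absolute
  SNR values are unit-convention dependent, and only their ratios,
  symmetries and trends are meaningful.
* The collagen slab is modelled as uniform and purely on the implant's top
  face; real capsules envelop the implant and vary in density.
* Time-domain/frequency-domain transport, Monte-Carlo solvers,
  fluorescence, and multi-wavelength excitation are out of scope.
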