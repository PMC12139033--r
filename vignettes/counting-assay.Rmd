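---
title: "Single-particle counting and carboxyl quantification: models, parameters and design choices"
author: "npquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Single-particle counting and carboxyl quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `npquant`, the tunable parameters
that matter, what the synthetic-data generator does and does not emulate,
and the design decisions that were genuinely open.

## The measurement model

The package combines two independent concentration measurements into a
mole ratio:

1. **Particle concentration by counting.** A dispersion is cast into an
   agarose microlayer of pre-collapse thickness $h$ (default 38 µm) which
   dries by collapsing only vertically.  A micrograph of field width $w$
   therefore images every particle contained in the cast volume
   $h \cdot w^2$.  With $N$ detected spots per micrograph, aggregate
   correction factor $R$, and dilution $D$,
   $$c_\mathrm{stock} = \frac{N \, R \, D}{h \, w^2 \, N_A}
     \times 10^{-3}\ \mathrm{mol\,L^{-1}},$$
   the $10^{-3}$ converting mol·m⁻³ to mol·L⁻¹.  With $h$, $w$ in metres,
   1344 spots, $R = 1.66$ and $D = 1$ this gives $1.08\times10^{-12}$
   mol/L — the unit test `test-concentration.R` pins this arithmetic,
   including the m³→L factor, against hand-computed values.

2. **Carboxyl concentration by titration.** The NaOH endpoint volume of the
   acid-washed particle suspension, minus the blank endpoint scaled by the
   HCl volume ratio, times the NaOH concentration, divided by the stock
   volume titrated.  The titrant itself is standardized against diprotic
   oxalic acid.  Detection and quantification limits are 3 and 10 standard
   deviations of the blank endpoint volume, converted to groups per
   particle; their ratio is exactly 10/3.

The ratio of the two concentrations is the average number of carboxyl
groups per particle.  Its standard uncertainty is propagated by Monte
Carlo: independent normal draws for numerator and denominator (the GUM
default when only a mean and standard uncertainty are stated), sample SD of
the element-wise ratio, 5×10⁶ samples by default.  The propagation requires
the denominator mean to exceed five times its uncertainty, otherwise the
moments of the ratio are not well behaved and the function refuses to
proceed.  At relative uncertainties below ~5% the Monte Carlo SD agrees
with the first-order delta method within a few percent; at the 8% level of
a typical counting budget the second-order terms already contribute ~2%,
which is why the Monte Carlo route is the reported one.

## What the simulator emulates

`simulateScene()` renders the study conditions, not an arbitrary
microscope:

| parameter | default | rationale |
|---|---|---|
| `h` | 38 µm | pre-collapse layer thickness set by the casting spacers |
| `w` | 300 µm | photon-upconversion field of view |
| `pixels` | 1024 | EM-CCD sensor side |
| `concentration` | 1.0825 pmol/L | places ~2231 particles in the field |
| `multiplicityFractions` | 0.52/0.30/0.18 | monomer/dimer/trimer mix with mean multiplicity 1.66 and decreasing histogram maxima |
| `psfSigma` | 1.3 px | diffraction-limited spot sampled near Nyquist |
| `monomerMean`, `monomerCV` | 2000 counts, 0.25 | bright spots with realistic mode overlap |
| `backgroundLevel` | 100 (upconversion) / 400 (fluorescence) counts | flat vs high background |
| `readoutSigma` | 3 counts | camera read noise |

The emitter count is Poisson with mean
$c \cdot 10^3 h w^2 N_A / \bar{k}$ ($\bar{k}$ the mean aggregate size);
positions are uniform; each spot is a pixel-integrated isotropic Gaussian;
Poisson shot noise is applied to signal plus background, then Gaussian read
noise, then rounding to integer counts.  Fluorescence mode adds a smooth
random field (white noise blurred at a configurable correlation length) to
emulate illumination irregularities.  All randomness flows from a single
integer seed; identical seeds give bit-identical scenes.

**Deliberately not modelled:** vector PSFs, EM-gain excess noise,
gel-drying physics, sub-resolution offsets within an aggregate (aggregates
render as one emitter), detector nonlinearity, multi-channel imaging.
Passing tests on this simulator therefore show that the *analysis chain* is
correct and unbiased under these assumptions — they cannot certify
performance on real micrographs with, e.g., structured backgrounds beyond
the smooth-field model or strongly non-Gaussian PSFs.

### Aggregate brightness: a design decision

An aggregate of $k$ particles is rendered with integrated intensity equal
to the **sum of $k$ independent monomer brightness draws**, so the $k$-th
histogram mode has mean $k\mu_1$ and width growing like $\sqrt{k}$.  The
monomer brightness family is configurable: a zero-truncated normal
(default) or a lognormal.  The default is symmetric on purpose: the
decomposition the assay prescribes fits *Gaussian* curves to the histogram,
and with strongly right-skewed modes (lognormal, CV 0.25) that estimator
acquires an intrinsic upward bias in the recovered aggregate fractions of
order +0.1 in $R$ — the skewed tails of each mode leak into the next
component.  A generator whose brightness model makes the assay's own
estimator inconsistent would misrepresent data that the assay demonstrably
fits well; the symmetric default reproduces the observed behaviour
(overlapping, near-Gaussian modes) while the lognormal option remains
available for sensitivity studies.

## Spot detection

The default detector is deterministic: difference-of-Gaussians band-pass at
(`psfSigma`, 3·`psfSigma`) with replicate padding (the FFT blur is circular
and would wrap bright border spots to the opposite edge), local maxima with
minimum separation 2·`psfSigma`, a threshold of `thresholdK` (default 5)
robust spreads (MAD) above the median response, and intensity-weighted
centroids in a window of half-width 2·`psfSigma`.  On noiseless spots the
centroid is accurate to well under 0.1 px.

The learned detector is a compact two-layer fully convolutional pixel
classifier — a trainable bank of 9×9 kernels, ReLU, and a 1×1 logistic
output — trained with Adam on simulator patches against unit-peak Gaussian
blob targets, with per-image (median, MAD) input normalization.  It is
intentionally the smallest architecture adequate for blob segmentation: it
trains on a single CPU in seconds, is fully deterministic under a fixed
seed, and serializes to a plain list of weights.  It is *not* a replica of
any particular published network; the classical detector remains the
default and the reference that the learned path must agree with (spot
counts within 10% on in-distribution scenes).

## Photometry

Spot intensity is the pixel sum in a circular aperture of radius
3·`psfSigma` (≈99% of a Gaussian spot's flux), minus a background level
times the aperture's pixel area.  Two background estimators mirror the two
imaging modes:

- **global** (upconversion, flat background): mean over 100 aperture-sized
  discs at random sites at least 4 aperture radii from every detected spot.
  Sites may overlap one another — their mean is unaffected — so the
  crowding guard requires ten times `nSites` admissible *centres*, not
  disjoint disc area; with ~1300 spots per field the Poisson voids still
  leave ample admissible area.
- **local** (fluorescence, varying background): per-spot median of an
  annulus between 1 and 2 aperture radii, robust to a neighbour covering
  part of the annulus.

Spots closer than `minSeparation` (default 2 aperture radii) are flagged
`excludedOverlap` — symmetrically, both members of a close pair — and spots
whose aperture or annulus touches the border are flagged `borderExcluded`.
Excluded spots contribute no intensity to the histogram **but still count
toward $N$**: exclusion protects the intensity statistics, not the count.

## Mixture decomposition and the correction factor

The corrected-intensity histogram (Freedman–Diaconis bins) is fitted with
$\sum_k A_k \cdot \Delta \cdot \mathcal{N}(x;\mu_k,\sigma_k)$ by bounded
Levenberg–Marquardt least squares with Poisson weights
$1/\sqrt{\max(n_i,1)}$, so $A_k$ is directly the spot count of component
$k$.  Initialization: $\mu_1$ at the histogram's first mode,
$\mu_k = k\mu_1$, $\sigma_k = 0.25\mu_1$, areas from the counts near each
harmonic mean.  The optional constrained mode pins $\mu_k = k\mu_1$ and
$\sigma_k = \sigma_1\sqrt{k}$ — exactly the structure of summed independent
brightnesses — and is useful when modes overlap heavily; the default is
unconstrained, as a histogram with well-resolved maxima needs no
constraint.  `selectComponents()` picks $K$ by an AIC-style criterion on
the weighted residuals with $3K$ parameters, resolving near-ties toward
smaller $K$.

$R = \sum_k k A_k / \sum_k A_k \ge 1$, with equality iff $K = 1$.  Two
subtleties surfaced during validation and are worth knowing:

- At ~1300 spots per 1024 px field, chance overlaps closer than the PSF
  merge ~3–5% of spot pairs into single detections.  These merged spots
  carry the summed brightness of their members, so they enter the histogram
  as genuine higher-multiplicity components — the correction factor then
  converts detected spots back to particles almost exactly.  This requires
  giving the fit room for the merged tail: at the default density a fourth
  component ($K=4$) captures double-dimer and trimer-monomer merges; with
  $K=3$ forced, the third Gaussian stretches over that tail and $R$
  overshoots by a few percent.  The recovery tests run at $K=4$ for this
  reason; for sparser fields $K=3$ is appropriate.
- At $n$ spots the multinomial sampling of the multiplicities alone gives
  the realized mean multiplicity a SD of about $0.77/\sqrt{n}$ (0.017 at
  $n=2000$), which bounds how tightly any estimator can match the
  *configured* $R$; the recovery tests therefore use 6000-spot samples
  where that noise is comfortably inside the ±0.05 recovery band.

## Titration details

The blank endpoint is scaled by `VHClSample / VHClBlank` before
subtraction, because the blank titrates a different HCl volume than the one
the pellet is resuspended in; the unscaled variant is available via
`scaleBlank = FALSE`.  The ~3% of carboxyls left deprotonated at the pH set
by 1 mmol/L HCl (pK$_a$ ≈ 4.5) is *reported* by `deprotonatedFraction()`
but never corrected — it is well inside the measurement uncertainty, and
correcting it would misstate what the endpoint actually measures.
Indicator chemistry is not modelled; endpoints are numeric inputs.

Structural interpretation uses the hydrodynamic diameter as the sphere
diameter (66 nm UCNP, 83 nm polystyrene presets), which overstates the
core surface slightly; densities and doped-unit masses for the
upconversion lattice (4.21 g/cm³, 204.7 g/mol) are package defaults for a
β-phase NaYF₄ host with 18% Yb / 2% Tm and are config entries, not
measured quantities.  Rounding (3 s.f. concentrations, nearest thousand
for group counts, 2 s.f. densities) happens only in the `reported` strings
of `runReport()`; all computations keep full precision.

## Numerical choices and degenerate inputs

- Mixture fits require ≥100 intensities; fewer is a hard error, not a
  silent fit.
- Non-convergence or a non-positive fitted area returns a `MixtureFit` with
  `converged = FALSE` carrying the last parameters as diagnostics.
- Exact response ties on plateaus (a spot centred between pixels) are
  deduplicated before centroiding.
- The Monte Carlo ratio rejects `denMean <= 5 * denU` rather than
  truncating distributions.
- Pixel coordinates are 0-based and pixel-centred throughout
  (physical $x = (i + 0.5)\,w/\mathrm{pixels}$); micrographs are stored as
  matrices indexed `[y+1, x+1]`.

## Problem sizes in the test suite

The suite exercises full-scale scenes (1024 px, ~1300 spots) where density
effects matter — the end-to-end concentration recovery runs ten microlayer
sets of three such micrographs — and 64–256 px scenes elsewhere, chosen so
each test isolates one property.  Detector scoring uses greedy
nearest-neighbour matching within 2 px, each truth spot matched at most
once.

## Known limitations

- Detection efficiency is not modelled out: particles dimmer than the
  threshold are lost and no correction is applied (the assay's premise is
  that spots are bright and well above background).
- $D$ (dilution to stock) is user input; the package does not estimate it
  from pipetting records.
- The learned detector is trained per imaging condition; a model trained on
  upconversion-like scenes is not expected to transfer to fluorescence
  scenes without retraining.
- Between-preparation SD is computed from as few as two preparations, as in
  typical practice; it is a repeatability indicator, not a full uncertainty
  budget, which is why the type B counting component (default 8% relative)
  enters the quadrature separately.
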