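---
title: "Models and methods behind nanodomain"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind nanodomain}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(nanodomain)
```

# Scientific setting

Glycosphingolipids such as GM1 organize into nanoscale domains in the outer
leaflet of the plasma membrane, and the acyl-chain structure of the lipid
(fully saturated C16:0 vs. singly unsaturated C16:1) controls whether these
domains form, how they couple across the bilayer, and how they respond to
clustering by the pentameric cholera toxin B-subunit (CTxB). Three
quantitative readouts probe this organization at different scales, and this
package implements the analysis machinery for all three, together with
forward simulators that generate every input with known ground truth.

# Homo-FRET anisotropy imaging

## Model

Polarized excitation photoselects fluorophores whose absorption dipole is
aligned with the field; their emission is partially polarized, quantified by
the steady-state anisotropy

$$r = \frac{I_{pa} - g\,I_{pe}}{I_{pa} + 2 g\,I_{pe}}, \qquad
  I_{tot} = I_{pa} + 2 g\,I_{pe},$$

where $g$ corrects the unequal detection efficiency of the two cameras.
Homo-FRET between like fluorophores within the Förster radius randomizes the
emitting dipole and depolarizes the signal. Two regimes matter:

* **Active clustering** — a fixed small number of molecules per nanocluster.
  Depolarization is set by the cluster geometry, not by how many clusters
  exist, so anisotropy is *low and independent of total intensity*.
* **Random proximity (bystander) FRET** — randomly distributed monomers come
  within transfer range only by chance, so depolarization *grows with
  surface density*: anisotropy falls as intensity rises.

CTxB binding adds a third signature: its five binding sites scaffold GM1 and
rotationally restrict the bound fluorophores, *raising* anisotropy above the
unbound clustered level even though the molecules remain clustered.

## Estimators and design choices

* **G-factor** (`estimate_g_factor`): median of the background-subtracted
  per-pixel $I_{pa}/I_{pe}$ ratio over a foreground mask of an isotropic dye
  reference. The median is robust to hot pixels; the reference's anisotropy
  is zero after fast rotational averaging, so the ratio estimates $g$
  directly. An empty mask or nonpositive perpendicular intensities raise an
  invalid-reference error.
* **Background**: constant per-channel offsets subtracted, then clipped at
  zero. Pixels with $I_{tot} \le 0$ are masked invalid rather than dropped
  or raised as errors — noisy background pixels are expected.
* **Binning** (`bin_intensity_anisotropy`): pixels pooled over ROIs, sorted
  by total intensity and split into equal-count (quantile) bins, default
  20. Equal-count bins stabilize the per-bin SD at low intensity where
  equal-width bins would be sparsely populated. `pool_intensity_anisotropy`
  pools pixels across acquisitions before binning, the analogue of pooling
  ROIs across cells.
* **Classification** (`classify_clustering_signature`): weighted least
  squares of anisotropy against $\log_{10}$ intensity with weights
  $1/\mathrm{SD}^2$ (falling back to equal weights when any bin SD is zero).
  The regression axis is logarithmic because the signatures span decades of
  intensity. Defaults: `flat_threshold = 0.01` anisotropy units per decade
  and `low_fraction = 0.8` of the monomer reference. The quantitative
  criterion separating the regimes is usually judged visually; these
  thresholds formalize it and were validated against the forward simulator
  (100% correct over seeded replicates of both regimes at the default
  simulation conditions). Fewer than 3 bins yields `indeterminate` with a
  diagnostic rather than an error.

## Forward model

The simulator implements a deliberately minimal one-step transfer
approximation: emitter $i$ keeps its own emission with weight

$$w_i = \frac{1}{1 + \sum_{j \ne i} (R_0/d_{ij})^6},$$

and its effective anisotropy is $r_i = w_i\,r_{base} + (1 - w_i)\,r_{et}$.
Defaults: $R_0 = 5$ nm, monomer anisotropy $r_{mono} = 0.35$, post-transfer
anisotropy $r_{et} = 0$, bound-state anisotropy $r_{mono,bound} = 0.45$.
These are conventional values for a membrane dye, chosen once; the effective
Förster radius and monomeric anisotropy of any particular dye-lipid
conjugate are not measured quantities here. Multi-step transfer chains and
explicit dipole orientations are out of scope; the one-step model is the
simplest that reproduces the three observed regimes (flat-low,
density-dependent, bound-elevated). Pairs beyond $8 R_0$ are neglected
(per-pair rate $< 4 \times 10^{-6}$) so the computation scales to the
$10^4$–$10^5$ emitters of the density-ramp conditions via a cell list.

Clusters are modeled as rings: `cluster_size` (default 5) emitters on a
3 nm-radius ring, matching the footprint of the five binding sites of one
pentamer. The bound and unbound cluster modes share this geometry and
differ only in $r_{base}$, so comparisons are at matched FRET geometry and
matched intensity.

The camera model applies, in order: photon budget $B_i \sim
\mathrm{Poisson}$(mean), channel split $B_i(1+2r_i)/3$ and
$B_i(1-r_i)/(3g)$, pixel deposition, Gaussian PSF convolution (default
$\sigma = 150$ nm; photons leaving the field of view are lost), Poisson shot
noise, gain, Gaussian read noise, offset, and 16-bit quantization. With
noise disabled the expected signal is returned, which makes the sparse-limit
identity exact: analyzing the output at the generator's $g$ returns $r_i$.

# SMLM spatial statistics

## Ripley's K and the clustering length

The estimator is

$$\hat K(r) = \frac{A}{n(n-1)} \sum_i \sum_{j \ne i} w_{ij}\,
  \mathbf{1}(d_{ij} \le r),$$

with $L = \sqrt{K/\pi}$ and $H = L - r$. Edge corrections for rectangular
windows: Ripley's isotropic correction (the reciprocal of the fraction of
the circle of radius $d_{ij}$ centred on point $i$ that lies inside the
window, computed in closed form for a rectangle), a translation correction,
or none. Isotropic is the default — standard practice and analytic for
rectangles. The $r$ grid defaults to 5–500 nm in 5 nm steps, covering the
90–225 nm range where GM1 clustering lengths are reported; the grid must not
exceed half the shorter window side, where the closed-form correction is
valid.

`estimate_rmax` locates the maximum of $H(r)$ — the clustering-length
normalization — refined by a parabola through the three grid points around
the discrete argmax, with ties broken toward smaller $r$ and a boundary flag
when the maximum sits at a grid end. Individual windows give noisy $H$ at
large $r$ (the variance of $\hat K$ grows with $r$), so `pool_ripley`
averages $K$ over tiles or replicate windows before locating the maximum,
the analogue of averaging the K-function over many cells before reading off
a clustering length. Pooled over 10 replicate simulations of a Thomas
process, the recovered $r_{max}$ is within ~2% of the analytic argmax across
cluster spreads of 20–60 nm, and is monotone in the spread.

## Cross-correlation

$\hat C(r)$ divides observed A–B pair counts per annulus by the count
expected for independent uniform points at the same intensities. The
expectation is computed analytically from the isotropized set covariance of
the rectangle ($\bar\gamma(r) = ab - 2r(a+b)/\pi + r^2/\pi$ for
$r \le \min(a,b)$), integrated over each annulus — equivalent to the
window-mask autocorrelation normalization but exact. Annuli with zero
expected pairs are reported as missing, not zero. Default bin width 10 nm.
An independent toroidal brute-force pair-counting implementation serves as
the test oracle.

## Blinking

A single fluorophore is typically localized several times across consecutive
frames, which inflates $\hat K$ at short range. The default analysis is
as-recorded (no merging), matching common practice for these comparisons.
`merge_blinking` optionally collapses localizations within a linking radius
across consecutive frames (greedy chaining, mean position); the test suite
shows that blinking with ~4 localizations per molecule inflates
$\hat K(100\,\mathrm{nm})$ well above the CSR level and that merging restores
the CSR calibration within 10%.

## Pattern generators

CSR is a homogeneous Poisson process; the Thomas process draws Poisson
parents (intensity $\kappa$), Poisson($\mu$) offspring per parent,
isotropic Gaussian displacements (SD $\sigma$), wrapped toroidally, and has
the closed form $K(r) = \pi r^2 + (1 - e^{-r^2/4\sigma^2})/\kappa$ used for
calibration. The default study condition ($\kappa = 50\,\mu m^{-2}$,
$\mu = 20$, $\sigma = 30$ nm in 3 × 3 µm windows) produces ~9,000
localizations per window, a realistic SMLM density. Two-channel patterns
share parents (co-clustered) or use independent parent sets (the null).
An expected-count cap (default $10^6$) guards against runaway inputs.

# Bilayer coordinate metrics

These are post-hoc analyses of coordinate snapshots; the package runs no
molecular dynamics, and the reported reference values from microsecond
all-atom trajectories (interdigitation 0.43/0.45/0.47/0.25, area-per-lipid
changes of +3.3/+0.7 Å², 2–4× sigma-theta contrasts) are not reproduced
here — the synthetic generator's planted truths are the acceptance surface.

* **sigma-theta**: per (lipid, headgroup vector), the sample SD over frames
  of the angle to the bilayer normal (+z), averaged within the bound and
  unbound groups; the unbound/bound ratio is the restraint readout. Which
  three atoms define the headgroup vectors is a species-schema input (the
  exact sugar-ring atom pairs are not prescribed); bound/unbound membership
  is likewise an input list, since toxin-structure handling is out of scope.
* **Interdigitation**: the time-averaged fraction of a chain's carbons lying
  past the bilayer midplane into the opposing leaflet. Reported
  interdigitation indices in the literature are not always accompanied by a
  formula; this fraction-past-midplane definition is one plausible reading —
  bounded in [0, 1] and monotone in penetration depth — and is stated as
  such. The midplane is the per-frame z center of mass of all terminal
  chain carbons, robust to leaflet asymmetry (unlike the fixed box center).
  With mirror-symmetric leaflets and a deterministic planted crossing
  fraction the midplane sits exactly at z = 0 and the planted value is
  recovered exactly; with species-specific crossing the midplane shifts and
  recovery is approximate.
* **Trans-bilayer contacts**: inter-leaflet heavy-atom chain-chain pairs
  within a cutoff (default 0.4 nm, a conventional contact criterion) under
  minimum-image distances, normalized per upper-leaflet lipid.
* **Area per lipid**: periodic 2-D Voronoi tessellation of anchor-atom
  (x, y) positions, built by half-plane clipping against all generators and
  their eight periodic replicas. The central cells tile the box, so areas
  must sum to the box area; this conservation is asserted on every call.
  Coincident anchors are perturbed by $10^{-6}$ nm with a warning.
* **S_CD**: hydrogens are reconstructed from heavy-atom geometry (ideal
  tetrahedral construction from three consecutive carbons — a documented
  approximation), and $S_{CD}(k) = \langle (3\cos^2\theta_{CH} - 1)/2
  \rangle$ over frames, lipids and both methylene hydrogens. The profile
  covers carbons $2 \ldots L-1$. An all-trans chain along the normal gives
  exactly $-0.5$; isotropic orientations give 0.

## Bilayer generator

Anchors sit on a jittered lattice with 0.8 nm spacing (~64 Å² per lipid, a
realistic fluid-phase value); chains are all-trans zig-zags along the normal
with a 0.127 nm rise per carbon; headgroup vectors are drawn per frame with
planted per-group angular SDs (defaults 3° bound / 9° unbound, the 3×
contrast of the restrained regime, drawn about a 30° mean); crossing counts
follow the planted distribution; an isotropic-orientation mode rigidly
rotates each lipid's chains per frame for orientation-sensitive null tests.
The default composition (18 GM1 + phospholipids, 5 bound lipids) mirrors a
one-pentamer asymmetric patch. What the generator does **not** emulate:
thermal chain conformations, realistic sterol packing, headgroup-chain
coupling, or any force-field physics — so passing tests demonstrate correct
estimators, not biological realism of the inputs.

# Numerical choices and problem sizes

* Pairwise kernels (neighbor counts, Ripley sums, cross-channel pair
  histograms, contact counts, FRET rates) are C++ (Rcpp); every one is
  checked against an independent vectorized-R brute-force oracle, exactly
  for integer counts and at $10^{-9}$ relative tolerance for weighted sums
  (double summation order differs between the two paths).
* The test suite and acceptance script use: 50-seed CSR (n = 5000) and
  Thomas calibrations, 10–20 seed cross-correlation and r_max runs,
  40 classification replicates, $10^4$-frame sigma-theta ensembles and
  ~$10^5$-sample isotropic S_CD checks. These sizes put Monte-Carlo error
  well below the property tolerances while keeping the whole suite in
  minutes on one core.
* Degenerate inputs: empty localization tables return empty results with a
  warning; coincident emitters transfer fully ($w \to 0$); coincident
  Voronoi generators are perturbed; collinear carbon triplets make the
  hydrogen reconstruction undefined and raise an error.

# Known limitations

* No image registration or drift correction: polarization channels are
  assumed registered (dual-camera acquisition) and localization tables
  drift-corrected upstream.
* No time-resolved anisotropy or lifetime analysis; no 3-D spatial
  statistics; no raw-movie localization fitting.
* The spatial statistics assume a homogeneous window; strong intensity
  gradients (cell edges) should be handled by tiling (`tile_windows`) into
  approximately homogeneous regions first.
* Absolute anisotropy values from the forward model depend on the assumed
  $r_{mono}$, $r_{et}$ and $R_0$; only relative and qualitative behavior
  (flatness, slopes, orderings) transfers to real dyes.
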