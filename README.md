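# nanodomain

Quantitative analysis of glycosphingolipid (GSL) nanodomain organization in
cell membranes, built around three experimental readouts and one simulated
one:

1. **Homo-FRET fluorescence anisotropy imaging.** Energy transfer between
   identical fluorophores depolarizes emission. From registered parallel- and
   perpendicular-emission images the package computes, per pixel,

   ```
   I_tot = I_pa + 2 g I_pe
   r     = (I_pa - g I_pe) / (I_pa + 2 g I_pe)
   ```

   with the G-factor `g` calibrated on an isotropic dye reference. Pixels are
   pooled over ROIs, sorted by total intensity and binned into equal-count
   bins; the shape of anisotropy vs. log10(intensity) separates *active
   clustering* (low, concentration-independent anisotropy from fixed-size
   nanoclusters) from *random-proximity / bystander FRET* (anisotropy falling
   with surface density).

2. **SMLM point-pattern statistics.** For single-molecule localization tables:
   neighbor-density analysis (counts within a 100 nm radius), Ripley's
   K/L/H functions with isotropic or translation edge correction for
   rectangular windows (`K(r) = pi r^2` under complete spatial randomness,
   `L = sqrt(K/pi)`, `H = L - r`), the characteristic clustering length
   `r_max = argmax H(r)` with parabolic refinement, tiling into 3 x 3 um
   analysis windows, and the two-channel pair cross-correlation `C(r)`
   (1 under independence; > 1 at short range for co-clustered channels),
   normalized analytically by the isotropized set covariance of the window.

3. **Bilayer coordinate metrics.** Post-hoc analysis of membrane snapshots
   (GRO/PDB): headgroup-vector angular fluctuation sigma-theta for
   toxin-bound vs. unbound lipids, chain interdigitation past the bilayer
   midplane, trans-bilayer chain contacts (e.g. GM1-POPS vs. GM1-POPE),
   periodic Voronoi area per lipid, and the C-H bond order parameter
   `S_CD(k) = <(3 cos^2 theta - 1)/2>` per chain carbon.

4. **Synthetic data with embedded ground truth.** Forward simulators for all
   inputs: CSR and Thomas cluster point patterns (with optional blinking),
   two-channel co-clustered or independent patterns, polarization-resolved
   image pairs under a one-step homo-FRET transfer model
   (`w_i = 1 / (1 + sum_j (R0/d_ij)^6)`), and bilayer ensembles with planted
   angular fluctuations, interdigitation fractions and contacts. Every
   generated object carries its full parameter record and seed, so
   analysis-vs-truth comparisons are automated in the test suite.

## Worked example

```r
library(nanodomain)

## clustered localization pattern -> Ripley analysis
win   <- analysis_window(3000)                       # 3 x 3 um window, nm units
truth <- pattern_truth("thomas", kappa_um2 = 50, mu = 20, sigma_nm = 30)
locs  <- simulate_point_pattern(truth, win, seed = 42)
rip   <- ripley_k(locs, win, r_grid = seq(5, 500, 5))
attr(rip, "r_max")
#> [1] 73.7                    # nm; clustering length of the simulated domains
mean(neighbor_density(locs, win, radius = 100)$per_point_counts)
#> [1] 53.1                    # mean neighbors within 100 nm

## homo-FRET forward simulation -> clustering signature
field <- simulate_emitter_field(analysis_window(6400), "clustered",
                                cluster_density_um2 = 10, seed = 1)
pair  <- simulate_polarized_image_pair(field, shape = c(64, 64),
                                       photons_mean = 1e4, seed = 2)
maps  <- compute_anisotropy_maps(pair, g = 1)
curve <- bin_intensity_anisotropy(maps, list(maps$total_intensity > 1000),
                                  n_bins = 10)
classify_clustering_signature(curve, monomer_reference = 0.35)
#> clustering signature: active_clustered
#>   slope -0.0012 per decade (95% CI -0.0037 .. 0.0013), mean r 0.0194 (monomer 0.3500)
```

The flat, low anisotropy curve (slope indistinguishable from zero, mean
anisotropy far below the 0.35 monomer reference) is the fixed-cluster-size
signature; a random-monomer density ramp instead produces a strongly negative
slope and is labeled `random_proximity`.

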