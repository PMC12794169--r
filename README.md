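# polyionics

Analysis toolkit for linear **polyanion models** — polynucleotides, acidic
polypeptides, glycosaminoglycans, mucin glycoforms, inorganic
polyphosphate and similar polyelectrolytes — sampled as coordinate
trajectories. It is aimed at molecular-modelling and structural-biology
groups who want the standard descriptors of such chains computed
reproducibly and tested against exact ground truth, without rerunning the
underlying simulations.

## What it computes

**Charge-density decomposition.** The charge distribution is split into a
linear density along the backbone and a radial density about the backbone
axis:

    lambda_x  = q_tot / (N * dx) = q_tot / Lc            [e/nm]
    lambda_yz = ( sum_i |q_i| / d_i ) / N                [e/nm]

where `q_tot` is the total charge magnitude, `dx` the monomer length, `Lc`
the contour length of the fully extended chain, and `d_i` the
perpendicular distance of charge *i* from the main axis of the extended
reference conformation.

**Compactness and shape.** Per-frame end-to-end distance `Ree`, radius of
gyration `Rg`, the contour-normalized `Ree/Lc`, and the ensemble size
ratio `<Ree^2>/<Rg^2>` (≈ 12 rigid rod, ≈ 6 ideal coil, < 4 collapsed
globule).

**Backbone flexibility.** Essential-dynamics PCA of backbone anchor
atoms: pooled replicates, two-pass least-squares superposition, covariance
eigendecomposition, PC1/PC2 projections and variance fraction.

**Counterion organization.** Site–cation radial distribution function
(3 nm / 200 bins), bound-cation counts (0.5 nm cutoff), charge
neutralization and cation-bridging fractions, residence times from a
Kaplan–Meier survival curve fitted as a single exponential (0.75 nm
proximity cutoff), and per-coordination-shell hydration numbers (0.38 nm
water cutoff).

**Synthetic ground truth.** A bead-chain generator plants chain regimes
(rod / freely-jointed / collapsed globule), ion-binding shells,
exponential dwell kinetics and water shells with exactly known answers,
so every estimator in the package is validated against closed forms or
planted truth.

## Worked example

A 30-monomer rigid-rod polyanion with peptide-like monomer length
(0.38 nm), one −1 charge per monomer at 0.25 nm radial offset, and a
planted ion field (60 monovalent + 30 divalent cations, exponential
dwell times of mean 2 ns) sampled for 15 ns at 10 ps/frame:

```r
library(polyionics)

spec <- synthetic_spec(model = "rod", n_monomers = 30, bond_length = 0.38,
                       charge_radial_offset = 0.25, box = 25,
                       n_frames = 1500, frame_time = 10,
                       ion_model = "planted_bound",
                       n_monovalent = 60, n_divalent = 30, seed = 2024)
sys <- generate_system(spec)

charge_density(sys$topology)
#> charge density: lambda_x = 2.632 e/nm, lambda_yz = 4.000 e/nm
#>   q_tot = 30 e over Lc = 11.400 nm

series <- conformation_series(sys$trajectory, sys$topology)
c(size_ratio = series$size_ratio, mean_ree_norm = mean(series$ree_normalized))
#> size ratio: 11.21   mean Ree/Lc: 0.967

ion_interaction_series(sys$trajectory, sys$topology)[
  c("mean_bound", "mean_neutralized", "mean_bridged")]
#> bound cations: 39.5 +/- 9.0   neutralized: 0.92   bridged: 0.98

residence_time(sys$trajectory, sys$topology)
#> residence_fit: tau = 1.828 ns from 333 events (50 censored)
```

Reading the output: `lambda_x = 30/11.4 = 2.63` e/nm is exactly the
charge count over the contour length, and `lambda_yz = 4` e/nm is
`|q|/offset` for the uniform 0.25 nm geometry. The size ratio 11.21
matches the rigid-rod closed form `12(N−1)/(N+1) = 11.23` to sampling
error, and `Ree/Lc ≈ 0.97` says the rod is essentially fully extended.
With 90 cations competing for 30 sites, ~40 are bound at a time, 92% of
sites are neutralized and nearly all neutralized sites share a cation
with a neighbour. The fitted residence time (1.83 ns from 333 completed
events) recovers the planted 2 ns dwell to within sampling error of this
short window.

Multi-system runs are driven by a configuration object or YAML file
(`run_config()` / `run_pipeline()`), producing per-system CSV/JSON
outputs plus a combined summary table and a provenance record; see the
vignette in `vignettes/polyanion-analysis.Rmd`.

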