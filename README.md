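# tubemech

Mechanics of tubulin intra- and inter-dimer interfaces from structures
and coordinate trajectories.

Microtubules grow and shrink by adding and losing αβ-tubulin dimers at
the ends of their 13 protofilaments, and the mechanics of the two
longitudinal contacts in a protofilament — the intra-dimer (α–β) and
inter-dimer (β–α) interfaces — are central to how GTP hydrolysis
destabilizes the lattice. `tubemech` implements the analysis toolchain
for this problem for structural biophysicists working with cryo-EM/X-ray
tubulin models and MD-style coordinate trajectories:

* **Bend/twist decomposition.** The relative orientation of adjacent
  monomers is expressed in a microtubule-bound frame (x radial, y
  tangential, z axial) and decomposed into bend magnitude
  θ = arccos(z·Z), signed bend direction φ (φ = 0 for strictly outward
  radial bending), and twist δ about the tilted axis, with the sign of
  δ from the triple product of {x′, X, Z}.
* **Equipartition stiffness.** κ = k\_BT/σ² from the pooled variance of
  an angle over the equilibrated window, in kBT/rad², with block
  bootstrap uncertainty and four-block convergence diagnostics.
* **Essential dynamics.** Cα + coarse-grained nucleotide bead models,
  Kabsch frame alignment, covariance PCA
  C\_ij = ⟨(x\_i−⟨x\_i⟩)(x\_j−⟨x\_j⟩)⟩, projections and mode overlaps.
* **Heterogeneous elastic networks.** Springs below R\_cutoff = 0.8 nm,
  constants fitted to pair-distance fluctuations (Boltzmann inversion +
  iterative refinement), normal modes ω\_n = √λ\_n, mode classification
  against ideal beam fields, and beam-theory rigidities
  K\_bend = ρ\_l ω²/k⁴, K\_twist = ρ\_v I ω²/k².
* **Contacts & compaction.** Strict 8 Å Cα contact counts with rupture
  detection, and ribose-ring center-of-mass compaction distances.
* **Synthetic ground truth.** Idealized 13-protofilament walls, bent
  protofilaments, harmonic rigid-interface trajectories and Gaussian
  ENM ensembles, all seeded and returning their ground truth — every
  analysis stage has a generate → analyze → recover closure test.

## Worked example

Generate a harmonic interface trajectory at a known stiffness, decompose
every frame, and recover the stiffness by equipartition:

```r
library(tubemech)

wall <- generate_wall_fragment()                      # idealized 13-pf wall
truth <- interface_ground_truth(theta0 = 9.1, phi0 = -73, delta0 = 7.7,
                                kappa_theta = 350, kappa_delta = 410)
tr <- generate_interface_trajectory(truth, n_frames = 2e4, seed = 1001)

iface <- list(label = "gtp_inter", class = "inter-dimer",
              lower_sel = tr$subunits[[1]], upper_sel = tr$subunits[[2]],
              lower_site = "A", upper_site = "B")
s <- angle_series(tr$trajectory, iface, wall$lattice)
win <- equilibrated_window(s)                          # second half of the run
kappa <- harmonic_stiffness(pooled_variance(win$theta_deg, n_boot = 0)$variance,
                            label = "gtp_inter", kind = "bend")
print(kappa)
```

```
stiffness_report [gtp_inter] bend: kappa = 358.2 kBT/rad^2 (sigma^2 = 0.00279 rad^2)
```

The recovered 358 kBT/rad² matches the generating stiffness (350)
within the sampling error of a 10⁴-frame variance; σ² = 0.00279 rad²
corresponds to a 3.0° bend-angle SD about θ₀ = 9.1°. The same loop over
all four study conditions is `analysis/03_stiffness_equipartition.R`,
which prints:

```
gtp_inter  bend  kappa =    358 kBT/rad^2 (true   350,  +2.3%), drift 0.028
gdp_intra  bend  kappa =    908 kBT/rad^2 (true   930,  -2.4%), drift 0.016
gtp_intra  bend  kappa =   1074 kBT/rad^2 (true  1100,  -2.4%), drift 0.028
gdp_inter  bend  kappa =   1283 kBT/rad^2 (true  1290,  -0.6%), drift 0.047
```

i.e. the soft inter-dimer condition is ~3–4× more flexible than the
intra-dimer ones, and the block drift statistic confirms stationarity
of each windowed series.

## Analysis workflow

The numbered scripts under `analysis/` run the whole synthetic study
and write tables under `results/`:

| script | what it does | output |
| --- | --- | --- |
| `01_simulate_interfaces.R` | defines the four stiffness conditions, generates trajectories | `01_interface_conditions.csv` |
| `02_interface_angles.R` | per-frame (φ, θ, δ) + unit-vector projections | `02_*_stride50.csv` |
| `03_stiffness_equipartition.R` | windowed pooled variances → κ, convergence | `03_stiffness.csv` |
| `04_essential_dynamics.R` | ENM ensemble → PCA, overlaps with normal modes | `04_pca_summary.csv` |
| `05_enm_beam_stiffness.R` | heterogeneous spring recovery; rod → K_bend/K_twist | `05_*.csv` |
| `06_contacts_compaction.R` | splaying contact series with rupture; compaction distance | `06_*.csv` |

Each script is a thin driver over exported package functions; run them
in order with `Rscript analysis/01_simulate_interfaces.R` etc.

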