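# ringstack

Simulation and analysis of concentrated solutions of semiflexible
polyelectrolyte **ring polymers** (DNA mini-circle like) with explicit
counterions.

Such rings — stiff enough that the contour length is only ~8 persistence
lengths — assemble into nanoscopic **cylindrical stacks** whose morphology
and dynamics are steered by the counterion valence: trivalent ions condense
onto the rings (Manning parameter ξ ≈ 6 ≫ 1), neutralise them and glue
stacks together, while with monovalent ions (ξ ≈ 2) the free-ion osmotic
pressure can collapse the rings and dissolve the stacks at high density.
`ringstack` provides, in one R package:

* a charged Kremer–Grest bead–spring **Langevin dynamics engine** (Rcpp):
  WCA excluded volume with Lorentz–Berthelot mixing, FENE bonds, harmonic
  cosine bending U(φ) = (K/2)(1−cos φ)², and Coulomb electrostatics via
  Ewald summation (plus Debye–Hückel and charge-off modes), with the
  lattice-initialisation / stepwise-compression preparation protocol;
* the **analysis pipeline**: gyration-tensor shape descriptors (radius of
  gyration, prolateness p ∈ [−1/4, 2], director), geometric stack-cluster
  identification (|d̂_i·d̂_j| ≥ 1−Δω, axial ≤ v∥, lateral ≤ v⊥ → connected
  components), static structure factors and coherent/incoherent
  intermediate scattering functions between ring centres of mass, g(r) and
  counterion-condensation diagnostics, and **minimal-surface threading
  analysis** (area-minimising triangulated disk per ring; bond–triangle
  piercings define active/passive threading partners and threading depths);
* **planted-truth synthetic scenes** (stack columns, prolate rods, ion
  clouds) so every analysis stage is testable without MD;
* plain-text trajectory I/O (extended XYZ, LAMMPS dump dialect, native
  format) and a small CLI/pipeline driver.

Reduced units: σ = 1 nm (one bead ≈ 3 nt of ssDNA, charge −3e), k_BT = 1,
m = 1; Bjerrum length l_B = 0.71 nm.

## Worked example

Simulate a small trivalent-counterion system and analyse it:

```r
library(ringstack)
ff <- forcefield()              # the DNA mini-ring parametrisation
manning_parameters(ff)
#> $line_charge_e_per_lB  2.13
#> $xi_mono               2.13
#> $xi_tri                6.39

proto <- run_protocol(M_rings = 8, N_monomers = 50,
                      ion_scenario = "tri_only", target_density = 0.2,
                      compress_block = 4, equil_time = 20,
                      production_time = 20, dump_interval = 4, seed = 1)
traj <- simulate_protocol(proto, ff, electro_mode = "explicit",
                          compress_electro_mode = "debye_huckel")

g <- pair_correlation(traj, "monomer", "ion_tri", bin_width = 0.05)
g$r[which.max(g$g)]
#> [1] 0.725        # first peak at the monomer-ion contact ~0.7 nm
condensed_fraction(traj$frames[[length(traj$frames)]], shell = 1.0325)
#> ion_tri
#>  0.9575          # effectively all trivalent ions condensed
```

The g(r) contact peak at ≈ 0.7 nm = (σ_mon + σ_ion)/2 and the ~96%
condensed trivalent fraction are the microscopic signature of the strong
Manning condensation that drives ring stacking in this system.

Analysis on a synthetic scene with planted truth:

```r
sc <- make_stack_scene(n_stacks = 4, sizes = c(20, 5, 3, 8),
                       tilt_max = 0.2, jitter = 0.3, n_dangling = 3,
                       seed = 3)
part <- build_partition(shape_frame(sc$config, sc$topology))
part
#> Stack partition: 39 rings in 7 clusters, Nw = 12.85, dangling W(1) = 0.08
all(part$labels == sc$truth$cluster_labels)   # exact recovery
#> [1] TRUE
```

## CLI

```sh
Rscript -e 'ringstack::ringstack_cli()' generate --n_stacks 2 --sizes 5,5 \
    --out_dir out
Rscript -e 'ringstack::ringstack_cli()' simulate --M_rings 8 \
    --target_density 0.2 --ion_scenario tri_only --out_dir out
```

Every run writes a JSON manifest (config, seeds, per-stage provenance);
fixed seeds reproduce runs end-to-end.

See `vignettes/ringstack-methods.Rmd` for the model, the numerical choices
(Ewald accuracy targets, minimal-surface convergence rule, criterion
tie-breaks), what the synthetic generators do and do not emulate, and known
limitations.
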