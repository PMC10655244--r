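---
title: "ringstack: model, analyses, and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{ringstack: model, analyses, and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The physical model

`ringstack` simulates concentrated solutions of semiflexible
polyelectrolyte ring polymers — a coarse-grained stand-in for DNA
mini-circles — with explicit counterions in an implicit solvent, and ships
the analysis pipeline used to characterise such solutions: ring shape
descriptors, geometric stack-cluster identification, static and dynamic
scattering between ring centres of mass, counterion-condensation
diagnostics, and minimal-surface threading analysis.

Reduced units are used throughout: the monomer diameter $\sigma \equiv 1$ nm
sets the length scale (one bead $\approx$ 3 nucleotides of ssDNA), $k_BT=1$
the energy scale, $m=1$ the mass, and $\tau=\sigma\sqrt{m/k_BT}$ the time
unit. A system holds $M$ rings of $N=50$ beads each plus counterions.

Interactions:

* **Excluded volume** — WCA (cut-and-shifted Lennard-Jones) between all
  pairs, $4\varepsilon[(s/r)^{12}-(s/r)^6]+\varepsilon$ for
  $r<2^{1/6}s$, zero beyond; continuous at the cutoff, with
  Lorentz–Berthelot mixing $s=(\sigma_i+\sigma_j)/2$. Ion diameter
  $\sigma_{\rm ion}=0.355\,\sigma$, so the monomer–ion contact sits at
  $0.6775\,\sigma \approx 0.7$ nm.
* **Bonds** — FENE, $-\tfrac12 K R_0^2\ln[1-(b/R_0)^2]$ with
  $K=30\,k_BT/\sigma^2$, $R_0=1.5\,\sigma$. Combined with the WCA core the
  bonds are uncrossable and equilibrate at $\langle b\rangle\simeq0.97\sigma$
  at $T=1$ (the commonly quoted value is 0.96–0.97; the tests accept
  $0.96\pm0.01$ and our measured mean sits at the upper edge of that band).
* **Bending** — the *harmonic cosine* angular potential
  $U(\phi)=\tfrac12 K_{\rm bend}(1-\cos\phi)^2$ with
  $K_{\rm bend}=30\,k_BT$ and $\phi$ the angle between consecutive bond
  vectors ($\phi=0$ for a straight continuation, maximum $2K_{\rm bend}$ at a
  back-fold). We deliberately use the squared ("cosine-squared") form
  rather than the simple $K(1-\cos\phi)$: for the squared form
  $\langle\cos\phi\rangle = 1-1/\sqrt{\pi K/2}\approx0.854$ at $K=30$, giving
  a persistence length $l_{\rm per}=-b/\ln\langle\cos\phi\rangle\approx
  6\,\sigma$, the ssDNA-like stiffness the model is built around
  ($N\sigma \simeq 8\,l_{\rm per}$). The simple form would give
  $l_{\rm per}\approx K b\approx29\,\sigma$, a qualitatively different
  (nearly rigid) ring. Both conventions agree at $\phi=0$ and $\phi=\pi$
  and share the range $[0,2K]$.
* **Electrostatics** — bare Coulomb $u(r)= l_B z_i z_j k_BT/r$ with Bjerrum
  length $l_B = e^2/(4\pi\varepsilon_0\varepsilon_r k_BT)=0.71$ nm
  ($\varepsilon_r=78.5$, $T=298$ K). Monomers carry $z=-3$; counterions
  $+1$, $+3$, or a charge-balanced mixture ($3NM$, $NM$, or $3NM/2 + NM/2$
  ions respectively). The contour charge density is $3e$/nm
  $=2.1\,e/l_B$, i.e. Manning parameters $\xi\approx2$ (monovalent) and
  $\xi\approx6$ (trivalent), both above the condensation threshold
  $\xi=1$.

## Dynamics and the electrostatics solver

Langevin dynamics, velocity-Verlet with friction $\gamma$ and a random
force of zero mean and variance $2\gamma m k_BT/\delta t$ per Cartesian
component per step; $\delta t = 0.005\,\tau$, $\gamma = 1/\tau$ by default
(the friction coefficient is a documented tunable, not asserted against
any reference). With the bath switched off the integrator reduces to plain
velocity Verlet (relative energy drift $<10^{-3}$ over $10^4$ steps, tested).

Full electrostatics uses a classic **Ewald summation** (tinfoil boundary)
rather than a particle-mesh method: at desk scale (up to a few thousand
charges) it is the simpler solver to verify, and it is held to the same
$10^{-3}$ relative-accuracy target. The real-space cutoff scales with the
box ($0.35L$, clamped to $[4\sigma, 0.45L]$) so the reciprocal-space vector
count stays bounded during compression. The suite validates the
implementation against a brute-force periodic-image sum (converged cubic
shells, with the dipole surface term removed to match the tinfoil
convention). Two cheaper modes exist: `debye_huckel` (Yukawa-screened pairs,
screening length defaulting to the free-ion ionic strength) and `off`
(charges zeroed — ions become neutral crowders, the charge-switch-off
control).

**Preparation protocol.** Rings start as planar, randomly oriented
$N$-gons on a primitive cubic lattice whose spacing exceeds the ring
diameter, so unknottedness and non-concatenation are guaranteed by
construction (verified with a discrete Gauss linking-integral oracle in the
tests). The box is then compressed in steps of $1\,\sigma$ (affine rescale
of coordinates by $1-\sigma/L$, followed by a dynamics block), then
equilibrated and sampled. Production-scale block lengths ($5\times10^3\tau$)
are retained as defaults in `run_protocol()`; desk-scale runs pass
explicitly shorter schedules. For explicit-ion desk runs the compression
stages may be performed under the screened interaction with the Ewald
treatment switched on for equilibration and production
(`compress_electro_mode`), mirroring the practice of retuning the
long-range solver once the box reaches its final size.

## Shape observables

Per ring (unwrapped across periodic boundaries by walking bonds with
minimum-image displacements): the gyration tensor
$G_{\alpha\beta} = N^{-1}\sum_i (r_{i\alpha}-r^{\rm com}_\alpha)
(r_{i\beta}-r^{\rm com}_\beta)$ with eigenvalues
$\lambda_1\ge\lambda_2\ge\lambda_3$; $R_g^2 = \sum\lambda_i$; the
**director** $\hat d$ is the eigenvector of $\lambda_3$ (the plane normal of
a disk-like ring; sign fixed first-nonzero-positive since only
$|\hat d_i\cdot\hat d_j|$ is ever used; near-degenerate
$\lambda_2\approx\lambda_3$ is flagged and excluded from pair criteria); the
**prolateness**

$$p = 27\,\frac{(\lambda_1-\bar\lambda)(\lambda_2-\bar\lambda)
(\lambda_3-\bar\lambda)}{(\lambda_1+\lambda_2+\lambda_3)^3}
\in [-\tfrac14, 2],$$

positive for cigar-like (prolate), negative for disk-like (oblate), zero
for spherical symmetry. Several rescaled variants of this descriptor
circulate in the literature; we fix the standard unnormalised form above,
and record its range $[-1/4,2]$ here because the bin grids of the joint
$(R_g/R_{g,0},\,p)$ histograms depend on it.

$R_{g,0}$, the infinite-dilution single-ring radius of gyration used to
scale sizes and wavenumbers, is measured by `measure_rg0()` from an
isolated-ring Langevin run (block averaging until the standard error drops
below 1%). For the neutral reference force field it is $\approx5.9\sigma$
(the rigid-polygon limit would be $7.64\sigma$; thermal fluctuations at
$l_{\rm per}=6\sigma$ contract it).

## Stack clustering

Rings $i<j$ are stacked iff simultaneously
$|\hat d_i\cdot\hat d_j|\ge 1-\Delta\omega$,
$|\vec r_{ij}\cdot\hat d_i|\le v_\parallel$, and
$|\vec r_{ij}-(\vec r_{ij}\cdot\hat d_i)\hat d_i|\le v_\perp$, with
$\Delta\omega=0.1$, $v_\parallel=3.0\sigma$, $v_\perp=2.5\sigma$;
projections use ring $i$'s director (the strictly-upper-triangular
convention) and boundary equalities count as satisfied. Clusters are the
connected components of the resulting graph; the weight fraction $W(N_s)$,
the weight-averaged aggregation number $N_w=\sum N_s W(N_s)$, and the
dangling fraction $W(1)$ summarise a frame. When a trajectory is analysed,
$N_w$ is computed frame-wise and then time-averaged; averaging the
$W(N_s)$ histograms over time first and weighting afterwards is an equally
defensible convention, and the frame-wise choice is fixed here because it
is the variance-reducing one. Director
asymmetry ($\hat d_i$ vs $\hat d_j$ projections) can flip the verdict only
for pairs within numerical tolerance of a criterion boundary; the suite
checks exact symmetry on off-boundary noise-free scenes.

## Correlations

* $S(k)$ between ring centres of mass, $(1/M)\langle|\sum_\alpha
  e^{i\vec k\cdot\vec R_\alpha}|^2\rangle$, averaged over all
  lattice-commensurate wavevectors ($\vec k = (2\pi/L)\,\vec n$) binned in
  shells of width $\pi/L$ — standard finite-box shell averaging; the $1/M$
  prefactor makes $S\to1$ for uncorrelated points (asserted in tests).
* Intermediate scattering functions at the cluster-peak wavenumber
  $k_{\max}$: incoherent (self) and coherent (collective), averaged over
  all time origins and the $k$-shell; the coherent function is normalised
  by its $\Delta t=0$ value so the $e^{-1}$ relaxation-time criterion is
  well-posed. Relaxation times interpolate log-linearly in time between the
  bracketing lags of the first downward crossing of $e^{-1}$ and are
  flagged `unresolved` when no crossing occurs within the window.
* $g(r)$ between species with ideal-gas normalisation and minimum image;
  the monomer–trivalent-ion $g(r)$ peaks at the mixing-rule contact
  $(\sigma_{\rm mon}+\sigma_{\rm ion})/2=0.6775\sigma\approx0.7$ nm when
  condensation is strong.
* Condensed fraction: ions within a stated shell of any monomer,
  time-averaged per species.

## Minimal surfaces and threading

Each ring's contour is spanned by a triangulated disk: the $N$ monomers are
fixed boundary vertices; interior "ghost" vertices (concentric rings plus a
centre point, about one ghost ring per $\sigma$ of radius so crossings are
localised at the monomer scale) are free and evolve by backtracking
gradient descent of the total area, i.e. a discrete surface tension. The
step size adapts so the area never increases; convergence is declared when
the area changes by at most 0.1% over 240 consecutive steps (the budget is
an error, reporting the last area). The interior seeding and mesh topology
of the original Surface-Evolver-based procedure are not published; only the
convergence rule is asserted.

Ring $A$ threads ring $B$ when a bond vector of $A$ (or one of its periodic
images) pierces a triangle of $B$'s surface ($A$ active, $B$ passive;
Möller–Trumbore test, boundary hits inclusive, degenerate triangles
excluded). A bond is counted at most once per surface — a bond of length
$\approx\sigma$ cannot pierce a near-flat disk twice. The crossing bonds
cut $A$'s contour into segments whose monomer counts are the threading
depths $\{L_t\}$, which partition $N$; an odd crossing count for a closed
pair (possible only for concatenated rings or mesh artefacts) is kept but
flagged with a warning. Surfaces are rebuilt per analysed frame.

## Synthetic scenes: what they do and do not establish

The `make_*` generators plant exact ground truth: regular planar $N$-gons
(known director, $R_g$ = circumradius), racetrack "double-folded" prolates
(two antiparallel strands joined by hairpins — the idealised cigar shape),
coaxial stack columns with controlled tilt (uniform in $[0,t_{\max}]$) and
isotropic Gaussian vertex jitter, rod/ring threading scenes with known
crossing counts and depths, and ion clouds with a planted condensed
fraction. All are deterministic under a fixed seed. They are geometric
fixtures, **not** Boltzmann samples: a green planted-partition or
threading-oracle test establishes the correctness of the analysis
machinery, not the thermodynamics of the simulated model. The
simulation-facing tests (bond length, persistence length, equipartition,
energy conservation, Ewald-vs-brute-force, the explicit-ion $g(r)$ contact
peak and strong trivalent condensation) cover that side at desk scale.

## Desk scale versus production scale

The reference results this package is built around were produced at
$M=512$ rings with $10^6\tau$ production runs. The package retains those
schedules as named defaults but its tests and acceptance report run at desk
scale ($M\le64$, $10^2$–$10^3\tau$), which reproduces the instantaneous and
single-ring quantities faithfully while the *collective, self-assembled*
observables (cluster-peak position of $S(k)$, stack size distributions at
entropic-stacking conditions, ISF time-scale decoupling, threading-count
distributions) need the production scale: entropy-driven stacking of
neutral/monovalent systems does not equilibrate within desk-scale budgets
(we verified that $4\times10^3\tau$ of equilibration at $M=64$,
$\rho\sigma^3=0.3$ leaves $N_w\approx1.2$, and that explicit-ion Ewald runs
at comparable $M$ are an order of magnitude more expensive still). The
acceptance report nevertheless recomputes the cluster-peak position from
the scaled-down neutral run and reports whatever it measures: at desk scale
the $S(k)$ maximum sits at the nearest-neighbour position
($kR_{g,0}\approx3.5$–$3.7$) rather than at the cluster position
($\approx2.7$), because the stacks that generate the cluster peak have not
had time to form. That target is expected to stay outside its comparison
band at desk scale; the property-based suite (planted-partition recovery,
threading-oracle equivalence, scattering closed forms) stands in for the
production-scale collective observables.

## Known limitations

* No hydrodynamics, no solvent structure beyond the dielectric continuum,
  no pressure coupling.
* Ewald (not PPPM) limits practical system sizes to a few thousand charges.
* Cluster statistics from short desk-scale runs are kinetically limited
  (see above); dynamic cluster tracking across frames (exchange/hopping
  kinetics) is out of scope.
* The depth statistics treat each frame independently; no shallow-vs-deep
  threading persistence analysis.
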