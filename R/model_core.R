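#' Pairwise and bonded interaction potentials
#'
#' Scalar (vectorised) forms of the four interaction terms of the model.
#' `wca_energy` is the purely repulsive cut-and-shifted Lennard-Jones
#' (Weeks-Chandler-Andersen) potential: 4 eps ((s/r)^12 - (s/r)^6) + eps for
#' r < 2^(1/6) s and exactly 0 beyond (Heaviside cutoff, continuous at the
#' cutoff). `fene_energy` is the finitely extensible nonlinear elastic bond
#' -K R0^2/2 log(1 - (b/R0)^2), diverging at b = R0. `bend_energy` is the
#' harmonic cosine bending term (K/2)(1 - cos phi)^2 with phi the angle
#' between consecutive bond vectors, zero for a straight continuation and
#' maximal (2K) at a full back-fold; with K = 30 k_B T and mean bond 0.96
#' sigma it yields a persistence length of about 6 sigma. `coulomb_energy`
#' is the unscreened pair term l_B z_i z_j / r in k_B T units.
#'
#' @param r interparticle distance (sigma); must be > 0.
#' @param sigma_pair pair interaction diameter (sigma).
#' @param epsilon energy scale (k_B T).
#' @return energy in k_B T, same length as the longest argument.
#' @export
#' @examples
#' wca_energy(2^(1 / 6))     # 0 at the cutoff
#' fene_energy(0.96)
#' bend_energy(pi / 2)
#' coulomb_energy(0.71, -3, 3)
wca_energy <- function(r, sigma_pair = 1, epsilon = 1) {
  if (any(r <= 0)) stop("invalid geometry: r must be > 0")
  sr6 <- (sigma_pair / r)^6
  ifelse(r < 2^(1 / 6) * sigma_pair, 4 * epsilon * (sr6^2 - sr6) + epsilon, 0)
}

#' @rdname wca_energy
#' @param b bond length (sigma); must satisfy 0 <= b < R0.
#' @param K FENE spring constant (k_B T / sigma^2).
#' @param R0 maximum bond extension (sigma).
#' @export
fene_energy <- function(b, K = 30, R0 = 1.5) {
  if (any(b < 0)) stop("invalid geometry: b must be >= 0")
  if (any(b >= R0)) stop("overstretched bond: b >= R0")
  -0.5 * K * R0^2 * log(1 - (b / R0)^2)
}

#' @rdname wca_energy
#' @param phi angle between consecutive bond vectors (radians, in [0, pi]).
#' @param K_bend bending constant (k_B T).
#' @export
bend_energy <- function(phi, K_bend = 30) {
  phi <- pmin(pmax(phi, 0), pi)
  0.5 * K_bend * (1 - cos(phi))^2
}

#' @rdname wca_energy
#' @param z_i,z_j charge numbers.
#' @param bjerrum Bjerrum length (sigma).
#' @export
coulomb_energy <- function(r, z_i, z_j, bjerrum = 0.71) {
  if (any(r <= 0)) stop("invalid geometry: r must be > 0")
  bjerrum * z_i * z_j / r
}

#' Single-snapshot particle configuration
#'
#' Positions are kept unwrapped; the cubic periodic box is `[0, box_length)^3`
#' and minimum-image convention is applied by all pair computations. Species
#' labels are `"monomer"`, `"ion_mono"`, `"ion_tri"`.
#'
#' @param positions n x 3 numeric matrix (sigma units).
#' @param species character vector of per-particle species labels.
#' @param charges numeric vector of per-particle charge numbers.
#' @param box_length cubic box edge (sigma).
#' @param time simulation time stamp (tau).
#' @return object of class `ringstack_configuration`.
#' @export
configuration <- function(positions, species, charges, box_length, time = 0) {
  positions <- as.matrix(positions)
  stopifnot(ncol(positions) == 3, nrow(positions) == length(species),
            nrow(positions) == length(charges), box_length > 0)
  bad <- setdiff(unique(species), c("monomer", "ion_mono", "ion_tri"))
  if (length(bad)) stop("unknown species: ", paste(bad, collapse = ", "))
  if (any(species != "monomer") && abs(sum(charges)) > 1e-9)
    stop("total charge must be 0 when ions are present")
  structure(list(positions = positions, species = species, charges = charges,
                 box_length = box_length, time = time),
            class = "ringstack_configuration")
}

#' @export
print.ringstack_configuration <- function(x, ...) {
  cat(sprintf("Configuration: %d particles (%s), box %.3f sigma, t = %g tau\n",
              nrow(x$positions),
              paste(sprintf("%d %s", table(x$species)[unique(x$species)],
                            unique(x$species)), collapse = ", "),
              x$box_length, x$time))
  invisible(x)
}

#' Ring topology: which particles form each closed ring
#'
#' @param rings list of integer index vectors, each giving one ring's
#'   monomers in cyclic order (consecutive entries, and the last-first pair,
#'   are bonded).
#' @param closed logical (recycled): `FALSE` marks an open chain (no
#'   last-first bond), used by synthetic threading scenes with rods.
#' @return object of class `ringstack_topology` with fields `rings`, `M`, `N`.
#' @export
ring_topology <- function(rings, closed = TRUE) {
  stopifnot(is.list(rings), length(rings) >= 1)
  closed <- rep_len(closed, length(rings))
  Ns <- lengths(rings)
  if (length(unique(Ns[closed])) > 1)
    stop("all closed rings must have the same length N")
  idx <- unlist(rings)
  if (anyDuplicated(idx)) stop("ring index lists must be disjoint")
  rings <- unname(lapply(rings, as.integer))
  structure(list(rings = rings, M = length(rings),
                 N = if (any(closed)) Ns[closed][[1]] else Ns[[1]],
                 closed = closed),
            class = "ringstack_topology")
}

#' @export
print.ringstack_topology <- function(x, ...) {
  cat(sprintf("Ring topology: M = %d rings of N = %d monomers\n", x$M, x$N))
  invisible(x)
}

# bonds (2-col) and angle triplets (3-col), 0-based, for the C++ core
topology_bonds <- function(topo) {
  closed <- if (!is.null(topo$closed)) topo$closed else rep(TRUE, topo$M)
  bonds <- do.call(rbind, lapply(seq_along(topo$rings), function(m) {
    r <- topo$rings[[m]]
    if (length(r) < 2) return(matrix(integer(0), 0, 2))
    if (closed[m]) cbind(r, c(r[-1], r[1])) else cbind(r[-length(r)], r[-1])
  }))
  angles <- do.call(rbind, lapply(seq_along(topo$rings), function(m) {
    r <- topo$rings[[m]]
    n <- length(r)
    if (n < 3) return(matrix(integer(0), 0, 3))
    if (closed[m]) cbind(r, c(r[-1], r[1]), c(r[-(1:2)], r[1], r[2]))
    else cbind(r[seq_len(n - 2)], r[2:(n - 1)], r[3:n])
  }))
  if (is.null(bonds)) bonds <- matrix(integer(0), 0, 2)
  if (is.null(angles)) angles <- matrix(integer(0), 0, 3)
  list(bonds = matrix(as.integer(bonds - 1), ncol = 2),
       angles = matrix(as.integer(angles - 1), ncol = 3))
}

species_sigma <- function(species, ff) {
  unname(c(monomer = ff$sigma_mon, ion_mono = ff$sigma_ion,
           ion_tri = ff$sigma_ion)[species])
}

#' Default charge numbers for a species vector
#' @param species character vector of species labels.
#' @param ff a [forcefield()].
#' @return numeric charge numbers.
#' @export
species_charges <- function(species, ff = forcefield()) {
  unname(c(monomer = ff$z_mon, ion_mono = ff$z_ion_mono,
           ion_tri = ff$z_ion_tri)[species])
}

electro_code <- function(mode) {
  switch(match.arg(mode, c("explicit", "debye_huckel", "off")),
         off = 0L, explicit = 1L, debye_huckel = 2L)
}

cpp_params <- function(ff, electro_mode = "off", kappa = 1,
                       rcut_elec = 4, accuracy = 1e-3) {
  list(epsilon = ff$epsilon, K_fene = ff$K_fene, R0 = ff$R0,
       K_bend = ff$K_bend, bjerrum = ff$bjerrum,
       electro = electro_code(electro_mode), kappa = kappa,
       rcut_elec = rcut_elec, accuracy = accuracy)
}

#' Total potential energy breakdown and forces
#'
#' Assembles the WCA, FENE, bending, and electrostatic terms for a
#' configuration. Excluded volume acts between all pairs (bonded included,
#' Kremer-Grest style) with Lorentz-Berthelot mixing of the per-species
#' diameters; FENE and bending act only along each ring's cyclic bonds;
#' electrostatics is Ewald-summed (`"explicit"`, tinfoil boundary),
#' Yukawa-screened (`"debye_huckel"`), or absent (`"off"`, the
#' neutral-crowders mode). All pair terms use the minimum-image convention.
#'
#' @param config a [configuration()].
#' @param topo a [ring_topology()].
#' @param ff a [forcefield()].
#' @param electro_mode one of `"explicit"`, `"debye_huckel"`, `"off"`.
#' @param kappa inverse screening length for `"debye_huckel"` (1/sigma).
#' @param rcut_elec electrostatic real-space cutoff (sigma).
#' @param accuracy Ewald relative accuracy target.
#' @return `total_energy`: named list with the four energy terms and their
#'   sum `total` (k_B T). `forces`: n x 3 matrix of forces (k_B T / sigma).
#' @export
total_energy <- function(config, topo, ff = forcefield(),
                         electro_mode = c("off", "explicit", "debye_huckel"),
                         kappa = 1, rcut_elec = 4, accuracy = 1e-3) {
  electro_mode <- match.arg(electro_mode)
  tb <- topology_bonds(topo)
  res <- rs_energy_forces(config$positions, species_sigma(config$species, ff),
                          config$charges, tb$bonds, tb$angles,
                          config$box_length,
                          cpp_params(ff, electro_mode, kappa, rcut_elec,
                                     accuracy))
  list(wca = res$wca, fene = res$fene, bend = res$bend,
       electrostatic = res$electrostatic,
       total = res$wca + res$fene + res$bend + res$electrostatic)
}

#' @rdname total_energy
#' @export
forces <- function(config, topo, ff = forcefield(),
                   electro_mode = c("off", "explicit", "debye_huckel"),
                   kappa = 1, rcut_elec = 4, accuracy = 1e-3) {
  electro_mode <- match.arg(electro_mode)
  tb <- topology_bonds(topo)
  rs_energy_forces(config$positions, species_sigma(config$species, ff),
                   config$charges, tb$bonds, tb$angles, config$box_length,
                   cpp_params(ff, electro_mode, kappa, rcut_elec,
                              accuracy))$forces
}
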