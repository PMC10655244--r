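#' Counterion counts for an ion scenario
#'
#' Electroneutrality with monomer charge -3: `mono_only` uses 3NM monovalent
#' ions, `tri_only` NM trivalent ions, `mixed` splits the compensating charge
#' evenly between the species (3NM/2 monovalent + NM/2 trivalent), `none`
#' has no ions (neutral reference system).
#'
#' @param M number of rings.
#' @param N monomers per ring.
#' @param scenario one of `"mono_only"`, `"tri_only"`, `"mixed"`, `"none"`.
#' @return named integer vector `c(n_mono =, n_tri =)`.
#' @export
#' @examples
#' ion_counts(512, 50, "mixed")
ion_counts <- function(M, N, scenario = c("mono_only", "tri_only", "mixed",
                                          "none")) {
  scenario <- match.arg(scenario)
  stopifnot(M > 0, N > 0)
  nm <- M * N
  counts <- switch(scenario,
    mono_only = c(3 * nm, 0),
    tri_only = c(0, nm),
    mixed = {
      if (nm %% 2 != 0)
        stop("indivisibility: mixed scenario needs N*M even")
      c(3 * nm / 2, nm / 2)
    },
    none = c(0, 0))
  c(n_mono = as.integer(counts[1]), n_tri = as.integer(counts[2]))
}

#' Box length for a target reduced monomer density
#'
#' Only monomeric units count towards the reduced density rho sigma^3;
#' counterions are excluded. L = (N M / rho)^(1/3).
#'
#' @inheritParams ion_counts
#' @param density reduced monomer density rho sigma^3.
#' @return box edge length in sigma.
#' @export
#' @examples
#' density_to_box(512, 50, 0.05)  # 80 sigma
density_to_box <- function(M, N, density) {
  stopifnot(density > 0)
  (M * N / density)^(1 / 3)
}

#' Simulation run protocol
#'
#' Defaults follow the production schedule (compression blocks of 5e3 tau);
#' desk-scale runs pass much shorter blocks and durations. `dump_interval`
#' must divide `production_time`.
#'
#' @param M_rings,N_monomers system size.
#' @param ion_scenario counterion composition, see [ion_counts()].
#' @param target_density reduced monomer density rho sigma^3.
#' @param initial_box initial box edge L0 (sigma); `NULL` picks the smallest
#'   lattice-safe box whose difference from the target box is an integer
#'   number of sigma, so the compression protocol lands exactly.
#' @param compress_block dynamics time after each 1-sigma box rescale (tau).
#' @param equil_time,production_time run schedule (tau).
#' @param dump_interval snapshot interval during production (tau).
#' @param seed integer RNG seed.
#' @return object of class `ringstack_protocol`.
#' @export
run_protocol <- function(M_rings, N_monomers = 50,
                         ion_scenario = c("mono_only", "tri_only", "mixed",
                                          "none"),
                         target_density, initial_box = NULL,
                         compress_block = 5e3, equil_time = 3e5,
                         production_time = 1e6, dump_interval = 1e3,
                         seed = 1L) {
  ion_scenario <- match.arg(ion_scenario)
  stopifnot(target_density > 0, compress_block >= 0, equil_time >= 0,
            production_time > 0, dump_interval > 0)
  if (abs(production_time / dump_interval -
          round(production_time / dump_interval)) > 1e-9)
    stop("dump_interval must divide production_time")
  ion_counts(M_rings, N_monomers, ion_scenario)  # validates divisibility
  structure(list(M_rings = M_rings, N_monomers = N_monomers,
                 ion_scenario = ion_scenario, target_density = target_density,
                 initial_box = initial_box, compress_block = compress_block,
                 equil_time = equil_time, production_time = production_time,
                 dump_interval = dump_interval, seed = as.integer(seed)),
            class = "ringstack_protocol")
}

#' Place rings on a primitive cubic lattice with random orientations
#'
#' Each ring starts as a planar regular N-gon of bond length `bond_length`
#' (circumradius b / (2 sin(pi/N))) centred on a lattice site, randomly
#' oriented. The lattice spacing must exceed the ring diameter plus a margin
#' so the initial state is guaranteed unknotted and non-concatenated;
#' otherwise the function refuses. Counterions are inserted uniformly at
#' random, rejecting hard overlaps.
#'
#' @inheritParams ion_counts
#' @param box box edge length (sigma).
#' @param ion_scenario counterion composition.
#' @param ff a [forcefield()].
#' @param seed integer seed.
#' @param bond_length initial bond length (sigma).
#' @return list with `config` ([configuration()]) and `topology`
#'   ([ring_topology()]).
#' @export
initialize_lattice <- function(M, N, box,
                               ion_scenario = c("mono_only", "tri_only",
                                                "mixed", "none"),
                               ff = forcefield(), seed = 1L,
                               bond_length = 0.96) {
  ion_scenario <- match.arg(ion_scenario)
  set.seed(seed)
  n_side <- ceiling(M^(1 / 3))
  spacing <- box / n_side
  radius <- bond_length / (2 * sin(pi / N))
  if (spacing < 2 * radius + ff$sigma_mon)
    stop(sprintf(paste("box too small: lattice spacing %.2f sigma <",
                       "ring diameter + margin %.2f sigma;",
                       "cannot guarantee non-concatenation"),
                 spacing, 2 * radius + ff$sigma_mon))
  ring0 <- make_planar_ring(N, bond_length)
  sites <- as.matrix(expand.grid(x = seq_len(n_side), y = seq_len(n_side),
                                 z = seq_len(n_side)))[seq_len(M), , drop = FALSE]
  centers <- (sites - 0.5) * spacing
  pos <- vector("list", M)
  for (m in seq_len(M)) {
    R <- random_rotation()
    pos[[m]] <- sweep(ring0 %*% t(R), 2, centers[m, ], `+`)
  }
  monomers <- do.call(rbind, pos)
  topo <- ring_topology(split(seq_len(M * N), rep(seq_len(M), each = N)))

  ions <- ion_counts(M, N, ion_scenario)
  n_ions <- sum(ions)
  ion_pos <- matrix(numeric(0), 0, 3)
  if (n_ions > 0) {
    contact <- 0.9 * (ff$sigma_mon + ff$sigma_ion) / 2
    placed <- 0
    ion_pos <- matrix(0, n_ions, 3)
    guard <- 0
    while (placed < n_ions) {
      guard <- guard + 1
      if (guard > 200 * n_ions) stop("could not place ions without overlap")
      cand <- runif(3, 0, box)
      d2 <- colSums((t(monomers) - cand)^2)
      if (min(d2) < contact^2) next
      if (placed > 0) {
        di <- colSums((t(ion_pos[seq_len(placed), , drop = FALSE]) - cand)^2)
        if (min(di) < (0.9 * ff$sigma_ion)^2) next
      }
      placed <- placed + 1
      ion_pos[placed, ] <- cand
    }
  }
  species <- c(rep("monomer", M * N),
               rep("ion_mono", ions["n_mono"]), rep("ion_tri", ions["n_tri"]))
  charges <- species_charges(species, ff)
  if (ion_scenario == "none") charges[] <- 0
  config <- configuration(rbind(monomers, ion_pos), species, charges, box)
  list(config = config, topology = topo)
}

random_rotation <- function() {
  # uniform random rotation from a normalised quaternion
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  a <- q[1]; b <- q[2]; c <- q[3]; d <- q[4]
  matrix(c(a^2 + b^2 - c^2 - d^2, 2 * (b * c - a * d), 2 * (b * d + a * c),
           2 * (b * c + a * d), a^2 - b^2 + c^2 - d^2, 2 * (c * d - a * b),
           2 * (b * d - a * c), 2 * (c * d + a * b), a^2 - b^2 - c^2 + d^2),
         3, 3, byrow = TRUE)
}

#' Langevin dynamics run
#'
#' Velocity-Verlet integration with Langevin friction and a random force of
#' zero mean and variance 2 gamma m k_B T / dt per Cartesian component per
#' step. Electrostatics modes: `"explicit"` (Ewald summation, tinfoil
#' boundary, desk-scale stand-in for particle-mesh methods at the same 1e-3
#' relative accuracy target), `"debye_huckel"` (Yukawa-screened pair term
#' with screening length `screening_length`, by default matched to the ionic
#' strength of the free counterions), or `"off"` (charges zeroed; ions act
#' as neutral crowders).
#'
#' @param config a [configuration()] (starting state; positions unwrapped).
#' @param topo a [ring_topology()].
#' @param ff a [forcefield()].
#' @param duration run length in tau.
#' @param seed integer seed for the thermal noise.
#' @param electro_mode `"explicit"`, `"debye_huckel"` or `"off"`.
#' @param dump_interval snapshot spacing in tau (0 = final snapshot only).
#' @param temperature thermostat temperature (k_B T; 0 switches noise off).
#' @param gamma friction override (default: `ff$gamma`).
#' @param screening_length Debye length in sigma for `"debye_huckel"`.
#' @param rcut_elec electrostatic real-space cutoff (sigma); default scales
#'   with the box (0.35 L, at least 4 sigma, at most 0.45 L) to balance the
#'   real- and reciprocal-space Ewald cost.
#' @param velocities optional n x 3 starting velocities (default: drawn from
#'   the Maxwell distribution at `temperature`).
#' @return object of class `ringstack_trajectory`: list of `frames` (each a
#'   [configuration()]), plus `topology`, `final_velocities`,
#'   `kinetic_per_dof` trace.
#' @export
run_langevin <- function(config, topo, ff = forcefield(), duration,
                         seed = 1L,
                         electro_mode = c("off", "explicit", "debye_huckel"),
                         dump_interval = 0, temperature = 1, gamma = NULL,
                         screening_length = NULL, rcut_elec = NULL,
                         velocities = NULL) {
  electro_mode <- match.arg(electro_mode)
  if (is.null(gamma)) gamma <- ff$gamma
  if (is.null(rcut_elec))
    rcut_elec <- min(0.45 * config$box_length,
                     max(4, 0.35 * config$box_length))
  n <- nrow(config$positions)
  dt <- ff$dt
  nsteps <- max(1L, as.integer(round(duration / dt)))
  dump_every <- if (dump_interval > 0)
    max(1L, as.integer(round(dump_interval / dt))) else 0L
  if (is.null(velocities)) {
    set.seed(seed)
    velocities <- matrix(rnorm(3 * n, sd = sqrt(max(temperature, 0) / ff$mass)),
                         n, 3)
  }
  kappa <- 1
  charges <- config$charges
  if (electro_mode == "debye_huckel") {
    if (is.null(screening_length))
      screening_length <- debye_length(config, ff)
    kappa <- 1 / screening_length
  }
  if (electro_mode == "off") charges <- rep(0, n)
  tb <- topology_bonds(topo)
  res <- rs_run_langevin(config$positions, velocities,
                         species_sigma(config$species, ff), charges,
                         tb$bonds, tb$angles, config$box_length,
                         cpp_params(ff, electro_mode, kappa, rcut_elec),
                         nsteps, dt, gamma, temperature, ff$mass,
                         as.numeric(seed) %% 2^31, dump_every)
  frames <- list()
  if (dump_every > 0) {
    frames <- lapply(seq_along(res$snapshots), function(i) {
      configuration(res$snapshots[[i]], config$species, config$charges,
                    config$box_length,
                    time = config$time + res$snap_steps[i] * dt)
    })
  }
  final <- configuration(res$positions, config$species, config$charges,
                         config$box_length, time = config$time + nsteps * dt)
  if (length(frames) == 0 || tail(res$snap_steps, 1) != nsteps)
    frames <- c(frames, list(final))
  structure(list(frames = frames, topology = topo,
                 final_velocities = res$velocities,
                 kinetic_per_dof = res$kinetic / (3 * n),
                 protocol = NULL),
            class = "ringstack_trajectory")
}

#' @export
print.ringstack_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames, %d rings x %d monomers, box %.2f sigma\n",
              length(x$frames), x$topology$M, x$topology$N,
              x$frames[[1]]$box_length))
  invisible(x)
}

#' Debye screening length from the free-counterion ionic strength
#'
#' kappa^2 = 4 pi l_B sum_i rho_i z_i^2 over the ion species of the
#' configuration; returns 1/kappa in sigma.
#'
#' @param config a [configuration()] with ions.
#' @param ff a [forcefield()].
#' @return screening length (sigma).
#' @export
debye_length <- function(config, ff = forcefield()) {
  V <- config$box_length^3
  ion <- config$species != "monomer"
  if (!any(ion)) stop("no ions in configuration")
  k2 <- 4 * pi * ff$bjerrum * sum(config$charges[ion]^2) / V
  1 / sqrt(k2)
}

#' One compression step of the preparation protocol
#'
#' Shrinks the box by 1 sigma, rescales all coordinates affinely by
#' 1 - sigma/L, then runs dynamics for `block_time`. An overstretched bond
#' after rescaling signals too-aggressive compression and raises an error.
#'
#' @inheritParams run_langevin
#' @param block_time dynamics time after the rescale (tau).
#' @return the final [configuration()] of the block.
#' @export
compress_step <- function(config, topo, ff = forcefield(), block_time = 50,
                          seed = 1L,
                          electro_mode = c("off", "explicit", "debye_huckel"),
                          temperature = 1, screening_length = NULL,
                          rcut_elec = NULL) {
  electro_mode <- match.arg(electro_mode)
  L <- config$box_length
  scl <- 1 - ff$sigma_mon / L
  cfg <- configuration(config$positions * scl, config$species, config$charges,
                       L - ff$sigma_mon, time = config$time)
  if (block_time <= 0) return(cfg)
  traj <- run_langevin(cfg, topo, ff, duration = block_time, seed = seed,
                       electro_mode = electro_mode, temperature = temperature,
                       screening_length = screening_length,
                       rcut_elec = rcut_elec)
  tail(traj$frames, 1)[[1]]
}

#' Run the full preparation + production protocol
#'
#' Lattice initialisation, stepwise 1-sigma compression to the target
#' density, equilibration, then production with snapshots every
#' `dump_interval`. Desk-scale wrapper around [run_langevin()].
#'
#' @param protocol a [run_protocol()].
#' @param ff a [forcefield()].
#' @param electro_mode electrostatics mode, see [run_langevin()].
#' @param compress_electro_mode electrostatics during the settle/compression
#'   stages only (default: same as `electro_mode`). Desk-scale explicit-ion
#'   runs can compress under the cheap screened interaction and switch to
#'   the full Ewald treatment for equilibration and production, mirroring
#'   the retuning of the long-range solver after the box reaches its final
#'   size.
#' @param temperature thermostat temperature.
#' @param verbose print per-stage progress.
#' @return a `ringstack_trajectory` of the production frames.
#' @export
simulate_protocol <- function(protocol, ff = forcefield(),
                              electro_mode = c("off", "explicit",
                                               "debye_huckel"),
                              compress_electro_mode = NULL,
                              temperature = 1, verbose = FALSE) {
  electro_mode <- match.arg(electro_mode)
  if (is.null(compress_electro_mode)) compress_electro_mode <- electro_mode
  p <- protocol
  target_L <- density_to_box(p$M_rings, p$N_monomers, p$target_density)
  n_side <- ceiling(p$M_rings^(1 / 3))
  radius <- 0.96 / (2 * sin(pi / p$N_monomers))
  min_L0 <- n_side * (2 * radius + 2 * ff$sigma_mon)
  L0 <- p$initial_box
  if (is.null(L0)) L0 <- target_L + max(0, ceiling(min_L0 - target_L))
  if (L0 < target_L) stop("initial box smaller than target box")
  if (abs((L0 - target_L) %% 1) > 1e-9 &&
      abs((L0 - target_L) %% 1 - 1) > 1e-9)
    stop("initial_box - target box must be an integer number of sigma")
  st <- initialize_lattice(p$M_rings, p$N_monomers, L0, p$ion_scenario, ff,
                           seed = p$seed)
  config <- st$config
  topo <- st$topology
  # short settle at L0
  config <- tail(run_langevin(config, topo, ff, duration = p$compress_block,
                              seed = p$seed,
                              electro_mode = compress_electro_mode,
                              temperature = temperature)$frames, 1)[[1]]
  nsteps_compress <- round(L0 - target_L)
  for (i in seq_len(nsteps_compress)) {
    if (verbose)
      message(sprintf("compress %d/%d: L = %.2f", i, nsteps_compress,
                      config$box_length - 1))
    config <- compress_step(config, topo, ff, block_time = p$compress_block,
                            seed = p$seed + i,
                            electro_mode = compress_electro_mode,
                            temperature = temperature)
  }
  if (p$equil_time > 0)
    config <- tail(run_langevin(config, topo, ff, duration = p$equil_time,
                                seed = p$seed + 10000L,
                                electro_mode = electro_mode,
                                temperature = temperature)$frames, 1)[[1]]
  traj <- run_langevin(config, topo, ff, duration = p$production_time,
                       seed = p$seed + 20000L, electro_mode = electro_mode,
                       dump_interval = p$dump_interval,
                       temperature = temperature)
  traj$protocol <- p
  traj
}
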