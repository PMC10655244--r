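test_that("ion counts follow electroneutrality for every scenario", {
  expect_equal(ion_counts(512, 50, "mono_only"),
               c(n_mono = 76800L, n_tri = 0L))
  expect_equal(ion_counts(512, 50, "tri_only"), c(n_mono = 0L, n_tri = 25600L))
  expect_equal(ion_counts(512, 50, "mixed"),
               c(n_mono = 38400L, n_tri = 12800L))
  expect_equal(ion_counts(2, 50, "none"), c(n_mono = 0L, n_tri = 0L))
  # total counterion charge balances -3 per monomer
  for (sc in c("mono_only", "tri_only", "mixed")) {
    ic <- ion_counts(4, 50, sc)
    expect_equal(ic[["n_mono"]] + 3 * ic[["n_tri"]], 3 * 4 * 50)
  }
  expect_error(ion_counts(1, 3, "mixed"), "indivisibility")
})

test_that("box length from reduced monomer density", {
  expect_equal(density_to_box(512, 50, 0.05), 80)
  expect_equal(density_to_box(512, 50, 0.5), 37.13, tolerance = 1e-3)
  expect_equal(density_to_box(1, 1, 1), 1)
})

test_that("lattice initialisation is non-concatenated (Gauss linking oracle)", {
  # oracle self-check on a Hopf link
  th <- 2 * pi * (0:39) / 40
  c1 <- cbind(cos(th), sin(th), 0)
  c2 <- cbind(1 + cos(th), 0, sin(th))
  expect_equal(abs(gauss_linking(c1, c2)), 1, tolerance = 0.01)
  expect_equal(gauss_linking(c1, sweep(c2, 2, c(5, 0, 0), `+`)), 0,
               tolerance = 0.01)

  N <- 16
  st <- initialize_lattice(8, N, 16, "none", seed = 3)
  expect_equal(nrow(st$config$positions), 8 * N)
  for (i in 1:7) for (j in (i + 1):8) {
    lk <- gauss_linking(st$config$positions[st$topology$rings[[i]], ],
                        st$config$positions[st$topology$rings[[j]], ])
    expect_lt(abs(lk), 0.05)
  }
  # single ring is a regular polygon of the stated circumradius
  st1 <- initialize_lattice(1, 50, 20, "none", seed = 1)
  r <- sqrt(rowSums(sweep(st1$config$positions, 2,
                          colMeans(st1$config$positions))^2))
  expect_equal(unname(r), rep(0.96 / (2 * sin(pi / 50)), 50),
               tolerance = 1e-10)
  expect_error(initialize_lattice(8, 50, 16, "none"), "box too small")
  # ions are placed and the system is neutral
  sti <- initialize_lattice(2, 10, 18, "tri_only", seed = 5)
  expect_equal(sum(sti$config$charges), 0)
  expect_equal(sum(sti$config$species == "ion_tri"), 20)
})

test_that("trajectories are bit-reproducible under a fixed seed", {
  ff <- forcefield()
  st <- initialize_lattice(2, 12, 14, "tri_only", seed = 2)
  t1 <- run_langevin(st$config, st$topology, ff, 2, seed = 7,
                     electro_mode = "explicit", dump_interval = 1)
  t2 <- run_langevin(st$config, st$topology, ff, 2, seed = 7,
                     electro_mode = "explicit", dump_interval = 1)
  expect_identical(t1$frames[[2]]$positions, t2$frames[[2]]$positions)
  t3 <- run_langevin(st$config, st$topology, ff, 2, seed = 8,
                     electro_mode = "explicit", dump_interval = 1)
  expect_false(identical(t1$frames[[2]]$positions, t3$frames[[2]]$positions))
})

test_that("zero-temperature, zero-force dynamics keeps positions fixed", {
  ff <- forcefield()
  cfg <- configuration(matrix(c(5, 5, 5), 1, 3), "monomer", 0, 10)
  topo <- ring_topology(list(1L), closed = FALSE)
  tr <- run_langevin(cfg, topo, ff, 5, temperature = 0, gamma = 0,
                     velocities = matrix(0, 1, 3))
  expect_equal(tail(tr$frames, 1)[[1]]$positions, cfg$positions)
})

test_that("equipartition: free particle at gamma=1, T=1 over 1e4 steps", {
  ff <- forcefield()
  cfg <- configuration(matrix(5, 1, 3), "monomer", 0, 10)
  topo <- ring_topology(list(1L), closed = FALSE)
  tr <- run_langevin(cfg, topo, ff, 50, seed = 12, dump_interval = 0.25)
  ke <- tr$kinetic_per_dof[-(1:20)]
  se <- sd(ke) / sqrt(length(ke))   # snapshots ~ uncorrelated (dt >> 1/gamma... conservative)
  expect_lt(abs(mean(ke) - 0.5), 3 * max(se, 0.01))
})

test_that("symplectic core: energy drift < 1e-3 over 1e4 steps without bath", {
  ff <- forcefield()
  N <- 20
  ring <- make_planar_ring(N, 0.98, c(10, 10, 10))
  cfg <- configuration(ring, rep("monomer", N), rep(0, N), 20)
  topo <- ring_topology(list(1:N))
  warm <- run_langevin(cfg, topo, ff, 10, seed = 3)
  tr <- run_langevin(tail(warm$frames, 1)[[1]], topo, ff, 50,
                     temperature = 0, gamma = 0,
                     velocities = warm$final_velocities, dump_interval = 1)
  etot <- vapply(seq_along(tr$frames), function(i) {
    total_energy(tr$frames[[i]], topo, ff)$total +
      tr$kinetic_per_dof[i] * 3 * N
  }, numeric(1))
  expect_lt((max(etot) - min(etot)) / abs(mean(etot)), 1e-3)
})

test_that("Ewald agrees with the brute-force periodic image sum", {
  ff <- forcefield()
  set.seed(31)
  n <- 20
  L <- 5
  repeat {
    pos <- matrix(runif(3 * n, 0, L), n, 3)
    if (min(dist(pos)) > 0.45) break
  }
  q <- rep(c(1, -1), n / 2)
  e_ewald <- ringstack:::rs_energy_forces(
    pos, rep(1e-4, n), q, matrix(integer(0), 0, 2),
    matrix(integer(0), 0, 3), L,
    ringstack:::cpp_params(ff, "explicit", 1, rcut_elec = 2.4,
                           accuracy = 1e-4))$electrostatic
  e_brute <- brute_coulomb(pos, q, L, ff$bjerrum, shells = 3)
  expect_lt(abs(e_ewald - e_brute) / abs(e_brute), 1e-3)
})

test_that("Debye length matches the free-ion ionic strength formula", {
  ff <- forcefield()
  st <- initialize_lattice(2, 10, 18, "tri_only", seed = 1)
  ld <- debye_length(st$config, ff)
  rho_i <- 20 / 18^3
  expect_equal(ld, 1 / sqrt(4 * pi * ff$bjerrum * rho_i * 9))
})

test_that("compression rescales box and coordinates affinely", {
  ff <- forcefield()
  st <- initialize_lattice(1, 30, 80, "none", seed = 2)
  cfg2 <- compress_step(st$config, st$topology, ff, block_time = 0)
  expect_equal(cfg2$box_length, 79)
  expect_equal(cfg2$positions, st$config$positions * (1 - 1 / 80))
  # all pair distances scale by exactly 1 - sigma/L
  d0 <- dist(st$config$positions[1:10, ])
  d1 <- dist(cfg2$positions[1:10, ])
  expect_equal(as.numeric(d1 / d0), rep(1 - 1 / 80, length(d0)))
  # 80 -> 37 takes 43 steps of one sigma
  expect_equal(80 - 37, 43)
  L <- 80
  cfg <- st$config
  for (i in 1:3) cfg <- compress_step(cfg, st$topology, ff, block_time = 0)
  expect_equal(cfg$box_length, 77)
})

test_that("run_protocol validates schedule invariants", {
  expect_error(run_protocol(8, 50, "none", target_density = 0.2,
                            production_time = 10, dump_interval = 3),
               "divide")
  p <- run_protocol(8, 50, "mixed", target_density = 0.2)
  expect_s3_class(p, "ringstack_protocol")
  expect_error(run_protocol(1, 3, "mixed", target_density = 0.1),
               "indivisibility")
})
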