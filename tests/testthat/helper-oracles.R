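# Independent oracles used across the suite. These deliberately avoid the
# package's own computational paths.

# central finite-difference gradient of the total energy wrt one coordinate
fd_force <- function(config, topo, ff, mode, i, a, h = 1e-5) {
  p <- config$positions
  p[i, a] <- p[i, a] + h
  ep <- total_energy(configuration(p, config$species, config$charges,
                                   config$box_length), topo, ff, mode)$total
  p[i, a] <- p[i, a] - 2 * h
  em <- total_energy(configuration(p, config$species, config$charges,
                                   config$box_length), topo, ff, mode)$total
  -(ep - em) / (2 * h)
}

# discrete Gauss linking integral between two closed polygons
gauss_linking <- function(c1, c2) {
  n1 <- nrow(c1); n2 <- nrow(c2)
  d1 <- c1[c(2:n1, 1), ] - c1
  d2 <- c2[c(2:n2, 1), ] - c2
  m1 <- (c1 + c1[c(2:n1, 1), ]) / 2
  m2 <- (c2 + c2[c(2:n2, 1), ]) / 2
  acc <- 0
  for (i in seq_len(n1)) {
    r <- sweep(m2, 2, m1[i, ], `-`) * -1   # m1 - m2
    cr <- cbind(d1[i, 2] * d2[, 3] - d1[i, 3] * d2[, 2],
                d1[i, 3] * d2[, 1] - d1[i, 1] * d2[, 3],
                d1[i, 1] * d2[, 2] - d1[i, 2] * d2[, 1])
    acc <- acc + sum(rowSums(r * cr) / rowSums(r^2)^1.5)
  }
  acc / (4 * pi)
}

# adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sij <- sum(comb2(tab))
  si <- sum(comb2(rowSums(tab)))
  sj <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- si * sj / n2
  maxi <- (si + sj) / 2
  if (maxi == expected) return(1)
  (sij - expected) / (maxi - expected)
}

# brute-force periodic Coulomb energy (cubic image shells, vacuum boundary)
# with the dipole term removed so it matches tinfoil Ewald
brute_coulomb <- function(pos, q, L, lB, shells = 3) {
  n <- nrow(pos)
  e <- 0
  for (sx in -shells:shells) for (sy in -shells:shells)
    for (sz in -shells:shells) {
      sh <- c(sx, sy, sz) * L
      for (i in seq_len(n)) for (j in seq_len(n)) {
        if (all(sh == 0) && i >= j) next
        r <- sqrt(sum((pos[i, ] - pos[j, ] + sh)^2))
        fac <- if (all(sh == 0)) 1 else 0.5
        e <- e + fac * lB * q[i] * q[j] / r
      }
    }
  M <- colSums(q * pos)
  e - 2 * pi * lB / (3 * L^3) * sum(M^2)
}

# sign-of-volume segment-triangle intersection oracle
orient3d <- function(a, b, c, d) {
  det(rbind(b - a, c - a, d - a))
}
seg_tri_oracle <- function(p, q, tri, eps = 1e-10) {
  a <- tri[1, ]; b <- tri[2, ]; c <- tri[3, ]
  vp <- orient3d(a, b, c, p)
  vq <- orient3d(a, b, c, q)
  if (vp * vq > eps) return(FALSE)          # same strict side
  # segment endpoints straddle (or touch) the plane; check the three
  # wedge volumes have a consistent sign
  s1 <- orient3d(p, q, a, b)
  s2 <- orient3d(p, q, b, c)
  s3 <- orient3d(p, q, c, a)
  (s1 >= -eps & s2 >= -eps & s3 >= -eps) ||
    (s1 <= eps & s2 <= eps & s3 <= eps)
}

# small thermalised two-ring + ions fixture used by force tests
make_test_system <- function(seed = 1, box = 8) {
  set.seed(seed)
  ff <- forcefield()
  r1 <- make_planar_ring(6, 0.96, c(3, 3, 3), c(0, 0, 1))
  r2 <- make_planar_ring(6, 0.96, c(3, 3, 5.2), c(0, 1, 2))
  mon <- rbind(r1, r2) + matrix(rnorm(36, sd = 0.03), 12, 3)
  n_ion <- 12
  repeat {
    ion <- matrix(runif(3 * n_ion, 0, box), n_ion, 3)
    dmin <- min(as.matrix(ringstack:::rs_min_dists(ion, mon, box)))
    dii <- min(dist(ion))
    if (dmin > 0.75 && dii > 0.5) break
  }
  species <- c(rep("monomer", 12), rep("ion_tri", n_ion))
  charges <- species_charges(species, ff)
  list(config = configuration(rbind(mon, ion), species, charges, box),
       topo = ring_topology(list(1:6, 7:12)), ff = ff)
}
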