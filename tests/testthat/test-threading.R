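test_that("minimal surface: planar polygon area, descent, saddle", {
  N <- 50
  ring <- make_planar_ring(N, 0.96)
  surf <- build_minimal_surface(ring)
  R <- 0.96 / (2 * sin(pi / N))
  exact <- 0.5 * N * R^2 * sin(2 * pi / N)
  expect_lt(abs(surf$area - exact) / exact, 0.02)
  # area is non-increasing throughout the evolution
  expect_true(all(diff(surf$area_trace) <= 1e-12))
  # boundary vertices stay fixed at the monomer positions
  expect_equal(surf$vertices[1:N, ], unname(ring))

  # saddle-shaped contour: converged area strictly below the initial mesh
  saddle <- ring
  ang <- atan2(ring[, 2], ring[, 1])
  saddle[, 3] <- 0.8 * sin(2 * ang)
  s2 <- build_minimal_surface(saddle)
  expect_lt(s2$area, s2$initial_area)
  expect_error(build_minimal_surface(saddle, max_steps = 3),
               "did not converge")
})

test_that("segment-triangle test agrees with the sign-of-volume oracle", {
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0))
  # perpendicular through the centroid
  hit <- segment_triangle_intersect(c(0.3, 0.3, -1), c(0.3, 0.3, 1), tri)
  expect_true(hit$hit)
  expect_equal(hit$point, c(0.3, 0.3, 0))
  # coplanar but offset outside
  expect_false(segment_triangle_intersect(c(2, 2, 0), c(3, 2, 0), tri)$hit)
  expect_true(segment_triangle_intersect(c(0, 0, -1), c(0, 0, 1),
                                         tri)$hit)   # vertex hit inclusive
  expect_true(segment_triangle_intersect(c(0.5, 0.5, -1), c(0.5, 0.5, 1),
                                         tri)$hit)   # edge hit inclusive
  # degenerate triangle excluded
  deg <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_true(segment_triangle_intersect(c(0, 0, -1), c(0, 0, 1),
                                         deg)$degenerate)

  set.seed(17)
  n_agree <- 0
  for (i in 1:2000) {
    tri <- matrix(rnorm(9), 3, 3)
    p <- rnorm(3); q <- rnorm(3)
    got <- segment_triangle_intersect(p, q, tri)$hit
    want <- seg_tri_oracle(p, q, tri)
    if (identical(got, want)) n_agree <- n_agree + 1
  }
  expect_equal(n_agree, 2000)
})

test_that("threading depths partition the active contour", {
  rc <- make_threading_scene("ring_chain")
  rec <- detect_threadings(rc$config, rc$topology)
  expect_equal(sum(unlist(rec$depths)), 50)
  # crossing bonds are antipodal for the planted construction
  bonds <- sort(unlist(rec$bonds))
  expect_equal(diff(bonds), 25)
})

test_that("threading statistics: counts, marginals, bookkeeping identity", {
  # one prolate rod threading a 6-ring column (all oblates)
  sizes <- 6
  sc <- make_stack_scene(1, sizes, spacing = 1.2, seed = 3, box = 40,
                         axis = c(0, 0, 1))
  axis_ctr <- colMeans(sc$config$positions[unlist(sc$topology$rings), ])
  rod <- make_prolate_ring(50, 0.96, axis_ctr, c(0, 0, 1))
  pos <- rbind(sc$config$positions, rod)
  topo <- ring_topology(c(sc$topology$rings, list(6 * 50 + 1:50)))
  cfg <- configuration(pos, rep("monomer", nrow(pos)), rep(0, nrow(pos)), 40)
  rec <- detect_threadings(cfg, topo)
  shapes <- shape_frame(cfg, topo)
  st <- threading_statistics(rec, shapes)
  expect_equal(st$per_ring$active[7], 6)          # rod threads all oblates
  expect_true(all(st$per_ring$passive[1:6] >= 1))
  expect_equal(sum(st$per_ring$active), nrow(rec))  # bookkeeping identity
  expect_equal(sum(st$P_passive), 1, tolerance = 1e-12)
  expect_equal(sum(st$P_active), 1, tolerance = 1e-12)
  expect_equal(sum(st$joint_passive), 1, tolerance = 1e-12)
  expect_equal(sum(st$joint_active), 1, tolerance = 1e-12)

  # isolated rings: all mass at count zero
  un <- make_threading_scene("unlinked")
  st0 <- threading_statistics(detect_threadings(un$config, un$topology),
                              shape_frame(un$config, un$topology))
  expect_equal(st0$P_passive, c("0" = 1))
  expect_equal(st0$P_active, c("0" = 1))
})

test_that("detect_threadings agrees with a brute-force oracle on random scenes", {
  # small random two-ring scenes in a large box (no image ambiguity);
  # oracle: all bonds of A against all triangles of B's surface using the
  # sign-of-volume test
  set.seed(23)
  N <- 14
  n_mismatch <- 0
  for (rep in 1:100) {
    box <- 200
    ctr <- c(100, 100, 100)
    c1 <- make_planar_ring(N, 0.96, ctr, rnorm(3))
    off <- rnorm(3) * 2
    c2 <- make_planar_ring(N, 0.96, ctr + off, rnorm(3)) +
      matrix(rnorm(3 * N, sd = 0.1), N, 3)
    cfg <- configuration(rbind(c1, c2), rep("monomer", 2 * N),
                         rep(0, 2 * N), box)
    topo <- ring_topology(list(1:N, N + 1:N))
    surfs <- lapply(list(c1, c2), build_minimal_surface)
    rec <- suppressWarnings(detect_threadings(cfg, topo, surfaces = surfs))
    for (A in 1:2) {
      B <- 3 - A
      ringA <- if (A == 1) c1 else c2
      sB <- surfs[[B]]
      bonds_oracle <- integer(0)
      for (bo in 1:N) {
        p <- ringA[bo, ]
        q <- ringA[if (bo == N) 1 else bo + 1, ]
        hit <- FALSE
        for (t in seq_len(nrow(sB$triangles))) {
          tri <- sB$vertices[sB$triangles[t, ], ]
          if (seg_tri_oracle(p, q, tri)) { hit <- TRUE; break }
        }
        if (hit) bonds_oracle <- c(bonds_oracle, bo)
      }
      got <- rec[rec$active == A & rec$passive == B, ]
      got_bonds <- if (nrow(got)) sort(unlist(got$bonds)) else integer(0)
      if (!identical(got_bonds, bonds_oracle)) n_mismatch <- n_mismatch + 1
    }
  }
  expect_equal(n_mismatch, 0)
})
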