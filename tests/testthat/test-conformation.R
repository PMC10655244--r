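test_that("gyration tensor basics and unwrapping", {
  # coincident points: zero tensor
  expect_equal(gyration_tensor(matrix(1, 5, 3)), matrix(0, 3, 3))
  # trace = mean squared distance from the centre of mass
  set.seed(1)
  pts <- matrix(rnorm(30), 10, 3)
  G <- gyration_tensor(pts)
  ctr <- sweep(pts, 2, colMeans(pts))
  expect_equal(sum(diag(G)), mean(rowSums(ctr^2)))
  expect_true(all(eigen(G, symmetric = TRUE)$values >= -1e-12))
  # rg^2 equals the eigenvalue sum exactly
  sh <- ring_shape(pts)
  expect_equal(sh$rg^2, sum(sh$gyration_eigenvalues))

  # ring wrapped across a periodic boundary
  box <- 10
  ring <- make_planar_ring(20, 0.96, c(0.2, 5, 5))   # straddles x = 0
  wrapped <- ring %% box
  expect_error(gyration_tensor(wrapped, box, auto_unwrap = FALSE), "wrapped")
  expect_equal(gyration_tensor(wrapped, box), gyration_tensor(ring))
})

test_that("director: normals, equivariance, degeneracy flag", {
  ring <- make_planar_ring(40, 1)
  d <- director(gyration_tensor(ring))
  expect_equal(abs(d[3]), 1, tolerance = 1e-12)
  # rotating the ring rotates the director identically
  set.seed(3)
  q <- rnorm(4); q <- q / sqrt(sum(q^2))
  R <- ringstack:::random_rotation()
  d2 <- director(gyration_tensor(ring %*% t(R)))
  expect_equal(abs(sum(d2 * (R %*% d))), 1, tolerance = 1e-10)
  # random planar polygon: director perpendicular to the best-fit plane
  set.seed(7)
  th <- sort(runif(25, 0, 2 * pi))
  poly <- cbind(3 * cos(th), 2 * sin(th), 0) %*% t(R)
  dsv <- svd(sweep(poly, 2, colMeans(poly)))$v[, 3]   # plane-fit oracle
  expect_equal(abs(sum(director(gyration_tensor(poly)) * dsv)), 1,
               tolerance = 1e-6)
  # sign convention: first nonzero component positive
  expect_gt(d[which(abs(d) > 1e-12)[1]], 0)
  # degenerate lambda2 ~ lambda3 flagged
  rod <- cbind(seq(0, 10, length.out = 30), 0, 0)
  expect_true(isTRUE(attr(director(gyration_tensor(rod)), "degenerate")))
})

test_that("prolateness: sign contract, extremes, invariances", {
  expect_equal(prolateness(diag(c(2, 2, 2))), 0)
  expect_equal(prolateness(c(1, 0, 0)), 2)          # thin rod: maximum
  expect_equal(prolateness(c(1, 1, 0)), -0.25)      # thin disk: minimum
  set.seed(11)
  for (i in 1:50) {
    lam <- sort(runif(3), decreasing = TRUE)
    p <- prolateness(lam)
    expect_true(p >= -0.25 - 1e-12 && p <= 2 + 1e-12)
    expect_equal(prolateness(7.3 * lam), p)          # scale invariance
  }
  # rotation invariance via similarity transform
  G <- diag(c(3, 2, 0.5))
  R <- ringstack:::random_rotation()
  expect_equal(prolateness(R %*% G %*% t(R)), prolateness(G))
  expect_error(prolateness(diag(0, 3)), "undefined shape")
})

test_that("shape observables are invariant under rigid motions", {
  set.seed(21)
  ring <- make_planar_ring(30, 0.96) + matrix(rnorm(90, sd = 0.3), 30, 3)
  s0 <- ring_shape(ring)
  for (i in 1:5) {
    R <- ringstack:::random_rotation()
    moved <- sweep(ring %*% t(R), 2, rnorm(3, sd = 5), `+`)
    s1 <- ring_shape(moved)
    expect_equal(s1$rg, s0$rg, tolerance = 1e-10)
    expect_equal(s1$prolateness, s0$prolateness, tolerance = 1e-8)
  }
})

test_that("shape histogram normalises to unit mass", {
  sc <- make_stack_scene(2, c(5, 5), jitter = 0.2, seed = 3)
  traj <- ringstack:::make_read_trajectory(list(sc$config), sc$topology)
  st <- shape_table(traj)
  h <- shape_histogram(st, rg0 = 7.6)
  expect_equal(sum(h$mass), 1, tolerance = 1e-12)
  # planar rings are oblate: all mass at negative prolateness
  expect_lt(max(st$prolateness), 0)
  # identical frames occupy a single bin per ring value
  one <- shape_histogram(st[rep(1, 10), ], rg0 = 7.6)
  expect_equal(sum(one$mass > 0), 1)
  expect_error(shape_histogram(st[0, ], 7.6), "empty")
})

test_that("persistence length and rg0 measurements behave physically", {
  ff <- forcefield()
  # stiffness monotonicity at modest cost: rg0 of a floppy ring is smaller
  rg_stiff <- measure_rg0(ff, seed = 2, N = 16, chunk_time = 100,
                          burn_in = 100)
  rg_floppy <- measure_rg0(forcefield(K_bend = 0), seed = 2, N = 16,
                           chunk_time = 100, burn_in = 100)
  expect_gt(rg_stiff$rg0, rg_floppy$rg0)
  # two seeds agree within 3 combined standard errors
  rg_b <- measure_rg0(ff, seed = 9, N = 16, chunk_time = 100, burn_in = 100)
  expect_lt(abs(rg_stiff$rg0 - rg_b$rg0),
            3 * sqrt(rg_stiff$se^2 + rg_b$se^2) + 0.02)
})
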