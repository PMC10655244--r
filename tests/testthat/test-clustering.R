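shape_stub <- function(com, dir) {
  structure(list(director = dir / sqrt(sum(dir^2)), com = com,
                 degenerate = FALSE, rg = 1, prolateness = -0.2),
            class = "ringstack_shape")
}

test_that("pair_stacked applies the three criteria with inclusive bounds", {
  cr <- stack_criteria()
  z <- c(0, 0, 1)
  a <- shape_stub(c(0, 0, 0), z)
  expect_true(pair_stacked(a, shape_stub(c(0, 0, 1), z), cr))
  # perpendicular directors fail the alignment criterion
  expect_false(pair_stacked(a, shape_stub(c(0, 0, 1), c(1, 0, 0)), cr))
  # axial separation beyond v_parallel fails; exactly at the bound passes
  expect_false(pair_stacked(a, shape_stub(c(0, 0, 3.001), z), cr))
  expect_true(pair_stacked(a, shape_stub(c(0, 0, 3), z), cr))
  # lateral offset beyond v_perpendicular fails; at the bound passes
  expect_false(pair_stacked(a, shape_stub(c(3, 0, 1), z), cr))
  expect_true(pair_stacked(a, shape_stub(c(2.5, 0, 0), z), cr))
  # alignment exactly at 1 - delta_omega passes
  th <- acos(0.9)
  tilted <- shape_stub(c(0, 0, 1), c(sin(th), 0, cos(th)))
  expect_true(pair_stacked(a, tilted, cr))
  # degenerate director excludes the pair
  d <- shape_stub(c(0, 0, 1), z)
  d$degenerate <- TRUE
  expect_true(is.na(pair_stacked(a, d, cr)))
  # minimum image: neighbour across the boundary
  expect_true(pair_stacked(shape_stub(c(0, 0, 0.2), z),
                           shape_stub(c(0, 0, 9.8), z), cr, box = 10))
})

test_that("pair_stacked is near-symmetric: exact on noise-free scenes", {
  cr <- stack_criteria()
  count_dis <- function(sc) {
    shapes <- shape_frame(sc$config, sc$topology)
    box <- sc$config$box_length
    dis <- 0
    M <- length(shapes)
    for (i in seq_len(M - 1)) for (j in (i + 1):M) {
      if (!identical(pair_stacked(shapes[[i]], shapes[[j]], cr, box),
                     pair_stacked(shapes[[j]], shapes[[i]], cr, box)))
        dis <- dis + 1
    }
    c(dis, M * (M - 1) / 2)
  }
  # noise-free (spacing 0.9 keeps every pair off the criterion boundary):
  # strictly zero asymmetric disagreements
  expect_equal(count_dis(make_stack_scene(2, c(6, 6), spacing = 0.9,
                                          seed = 4))[1], 0)
  # mildly perturbed columns away from criterion boundaries: rate < 1%
  tot <- c(0, 0)
  for (sd_ in 1:8)
    tot <- tot + count_dis(make_stack_scene(2, c(4, 4), spacing = 0.9,
                                            tilt_max = 0.08, jitter = 0.05,
                                            seed = sd_))
  expect_lt(tot[1] / tot[2], 0.01)
})

test_that("build_partition: component semantics and W statistics", {
  z <- c(0, 0, 1)
  # chain A-B-C where A-C alone would fail the axial cut: one cluster
  shapes <- list(shape_stub(c(0, 0, 0), z), shape_stub(c(0, 0, 2.5), z),
                 shape_stub(c(0, 0, 5), z), shape_stub(c(20, 20, 20), z))
  part <- build_partition(shapes, box = 50)
  expect_equal(length(unique(part$labels[1:3])), 1)
  expect_equal(sort(part$sizes), c(1, 3))
  expect_equal(part$W, c("1" = 0.25, "3" = 0.75))
  expect_equal(part$Nw, 2.5)
  expect_equal(part$dangling_fraction, 0.25)
  expect_equal(sum(part$sizes), 4)
  expect_equal(sum(part$W), 1)
})

test_that("partition invariant under relabeling and rigid motion", {
  sc <- make_stack_scene(3, c(8, 4, 2), tilt_max = 0.05, jitter = 0.1,
                         n_dangling = 1, seed = 6)
  shapes <- shape_frame(sc$config, sc$topology)
  p0 <- build_partition(shapes)
  # rigid motion of the whole box
  R <- ringstack:::random_rotation()
  moved <- lapply(shapes, function(s) {
    s$com <- as.numeric(R %*% s$com + c(1, 2, 3))
    s$director <- as.numeric(R %*% s$director)
    s
  })
  p1 <- build_partition(moved, box = Inf)
  expect_equal(adjusted_rand(p0$labels, p1$labels), 1)
  # ring relabeling permutes labels consistently
  perm <- sample(length(shapes))
  p2 <- build_partition(shapes[perm], box = attr(shapes, "box"))
  expect_equal(adjusted_rand(p2$labels, p0$labels[perm]), 1)
})

test_that("Nw is monotone non-decreasing under merging two clusters", {
  set.seed(8)
  for (rep in 1:20) {
    sizes <- sample(1:10, sample(3:6, 1), replace = TRUE)
    M <- sum(sizes)
    nw <- sum(sizes^2) / M
    i <- sample(length(sizes), 2)
    merged <- c(sizes[-i], sum(sizes[i]))
    expect_gte(sum(merged^2) / M, nw)
  }
})

test_that("alignment distribution: column, isotropic, and empty cases", {
  sc <- make_stack_scene(1, 12, spacing = 1, seed = 2)
  shapes <- shape_frame(sc$config, sc$topology)
  ad <- alignment_distribution(shapes, rg0 = 7.64, nbins = 10)
  expect_false(ad$empty)
  expect_equal(sum(ad$density) * 0.1, 1, tolerance = 1e-12)
  expect_equal(which.max(ad$density), 10)     # all mass in the top bin

  # isotropic directors at close range: uniform in |dot|
  set.seed(4)
  iso <- lapply(1:300, function(i) {
    shape_stub(runif(3, 0, 0.5), rnorm(3))
  })
  adi <- alignment_distribution(iso, rg0 = 10, box = 100, nbins = 5)
  expect_lt(max(abs(adi$density - 1)), 0.15)

  far <- list(shape_stub(c(0, 0, 0), c(0, 0, 1)),
              shape_stub(c(50, 0, 0), c(0, 0, 1)))
  expect_true(alignment_distribution(far, rg0 = 5, box = 200)$empty)
})
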