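test_that("structure factor: single ring, Poisson gas, two-point crystal", {
  L <- 20
  # M = 1: S(k) = 1 identically
  sk1 <- structure_factor(lapply(1:3, function(i) matrix(runif(3, 0, L), 1)),
                          box = L, kmax = 2.5)
  expect_true(all(abs(sk1$S - 1) < 1e-12))

  # Poisson-random centres: S = 1 within 3/sqrt(samples per bin)
  set.seed(5)
  M <- 150
  coms <- lapply(1:25, function(i) matrix(runif(3 * M, 0, L), ncol = 3))
  sk <- structure_factor(coms, box = L, kmax = 3)
  tol <- 3 / sqrt(sk$n_vectors * 25)
  expect_gt(mean(abs(sk$S - 1) < pmax(tol, 0.15)), 0.95)
  expect_true(all(sk$S >= 0))
  expect_true(all(sk$k >= 2 * pi / L - 1e-9))   # sub-box modes excluded

  # two-point crystal: closed form S(k) = 1 + cos(k . d) per wavevector
  d <- c(4, 0, 0)
  pair <- rbind(c(3, 3, 3), c(3, 3, 3) + d)
  sk2 <- structure_factor(list(pair), box = L, kmax = 2.5)
  kv <- ringstack:::legal_kvectors(L, 2.5)
  pred <- 1 + cos(kv$K %*% d)
  bin <- floor(kv$knorm / (pi / L) + 0.5)
  pred_binned <- tapply(pred, bin, mean)
  expect_equal(sk2$S, as.numeric(pred_binned), tolerance = 1e-10)
})

test_that("ISF: frozen configurations, Brownian closed form, M = 1", {
  L <- 20
  set.seed(9)
  com0 <- matrix(runif(3 * 40, 0, L), ncol = 3)
  frozen <- lapply(1:8, function(i) com0)
  for (mode in c("incoherent", "coherent")) {
    fi <- isf(frozen, k_max = 1, mode = mode, box = L, times = 0:7)
    expect_true(all(abs(fi$F - 1) < 1e-12))
    expect_true(all(abs(fi$F) <= 1 + 1e-9))
  }
  expect_equal(isf(frozen, 1, "incoherent", box = L, times = 0:7)$F[1], 1)

  # independent Brownian walkers: F_inc = exp(-k^2 D dt)
  D <- 0.1
  M <- 300
  nf <- 40
  walk <- vector("list", nf)
  walk[[1]] <- matrix(runif(3 * M, 0, L), ncol = 3)
  for (t in 2:nf)
    walk[[t]] <- walk[[t - 1]] + matrix(rnorm(3 * M, sd = sqrt(2 * D)), M, 3)
  fi <- isf(walk, k_max = 1, mode = "incoherent", box = L, times = 0:(nf - 1))
  expect_lt(max(abs(fi$F - exp(-1^2 * D * fi$lag))), 0.05)

  # M = 1: coherent equals incoherent identically
  w1 <- lapply(walk, function(m) m[1, , drop = FALSE])
  f1i <- isf(w1, 1, "incoherent", box = L, times = 0:(nf - 1))
  f1c <- isf(w1, 1, "coherent", box = L, times = 0:(nf - 1))
  expect_equal(f1i$F, f1c$F)
})

test_that("relaxation time: exact crossing, floor, two-exponential refinement", {
  lag <- exp(seq(log(0.05), log(80), length.out = 25))
  expect_equal(relaxation_time(data.frame(lag = lag, F = exp(-lag / 7))), 7,
               tolerance = 0.01)
  floor_series <- data.frame(lag = 1:10, F = seq(0.9, 0.6, length.out = 10))
  tr <- relaxation_time(floor_series)
  expect_true(is.na(tr) && isTRUE(attr(tr, "unresolved")))
  # two-exponential: sparse interpolation matches dense sampling
  f2 <- function(t) 0.6 * exp(-t) + 0.4 * exp(-t / 12)
  sparse <- data.frame(lag = lag, F = f2(lag))
  dense_lag <- exp(seq(log(0.05), log(80), length.out = 4000))
  dense <- data.frame(lag = dense_lag, F = f2(dense_lag))
  expect_equal(relaxation_time(sparse), relaxation_time(dense),
               tolerance = 0.02)
})

test_that("pair correlation: ideal gas, planted shell, count identity", {
  L <- 15
  set.seed(2)
  n <- 400
  pos <- matrix(runif(3 * n, 0, L), ncol = 3)
  cfg <- configuration(pos, rep("ion_mono", n), rep(0, n), L)
  g <- pair_correlation(list(cfg, cfg), "ion_mono", "ion_mono",
                        bin_width = 0.5)
  expect_equal(mean(g$g), 1, tolerance = 0.05)
  # g -> 1 at large r
  expect_equal(mean(g$g[g$r > 5]), 1, tolerance = 0.05)

  # histogram counts recover the total pair count within r_max
  h <- ringstack:::rs_pair_histogram(pos, pos, TRUE, L, 3, 10)
  # brute periodic pair count
  cnt <- 0
  for (i in 1:(n - 1)) {
    d <- t(pos[(i + 1):n, , drop = FALSE]) - pos[i, ]
    d <- d - L * round(d / L)
    cnt <- cnt + sum(colSums(d^2) < 9)
  }
  expect_equal(sum(h), cnt)

  # planted condensed shell peaks in the contact bin
  ring <- make_planar_ring(50, 0.96, c(7.5, 7.5, 7.5))
  cl <- make_ion_cloud(ring, 1, 0.05, L, 120, seed = 3)
  cfg2 <- configuration(rbind(ring, cl$positions),
                        c(rep("monomer", 50), rep("ion_tri", 120)),
                        rep(0, 170), L)
  g2 <- pair_correlation(cfg2, "monomer", "ion_tri", bin_width = 0.05)
  expect_lt(abs(g2$r[which.max(g2$g)] - 0.6775), 0.06)
  expect_warning(pair_correlation(cfg2, "monomer", "ion_tri", r_max = 10),
                 "truncating")
  expect_error(pair_correlation(cfg2, "monomer", "ion_mono"), "species")
})

test_that("condensed fraction trivials", {
  ring <- make_planar_ring(30, 0.96, c(10, 10, 10))
  cl <- make_ion_cloud(ring, 1, 0.3, 20, 60, seed = 1)
  cfg <- configuration(rbind(ring, cl$positions),
                       c(rep("monomer", 30), rep("ion_tri", 60)),
                       rep(0, 90), 20)
  expect_equal(condensed_fraction(cfg, shell = 1.1)[["ion_tri"]], 1)
  # vanishing shell: fraction -> 0 (no ion can sit closer than
  # contact - neighbour spacing ~ 0.28 sigma from any monomer)
  expect_equal(condensed_fraction(cfg, shell = 0.1)[["ion_tri"]], 0)
})
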