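#' Unwrap a ring across periodic boundaries
#'
#' Reconstructs a contiguous contour by walking the bonds and accumulating
#' minimum-image displacements from the first monomer. Shape observables
#' assume contiguous coordinates.
#'
#' @param coords N x 3 matrix of one ring's monomer positions in cyclic
#'   order.
#' @param box cubic box edge (sigma).
#' @return N x 3 matrix of unwrapped coordinates.
#' @export
unwrap_ring <- function(coords, box) {
  d <- diff(coords)
  d <- d - box * round(d / box)
  rbind(coords[1, , drop = FALSE],
        sweep(apply(d, 2, cumsum), 2, coords[1, ], `+`))
}

#' Gyration tensor of a set of coordinates
#'
#' G_ab = (1/N) sum_i (r_ia - rcom_a)(r_ib - rcom_b); symmetric positive
#' semidefinite, trace = mean squared distance from the centre of mass
#' (= Rg^2).
#'
#' @param coords N x 3 coordinate matrix.
#' @param box optional box edge; when given, the ring is unwrapped first
#'   (`auto_unwrap = TRUE`) or an error is raised if the contour is
#'   discontinuous.
#' @param auto_unwrap reconstruct contiguous coordinates before analysis.
#' @return 3 x 3 symmetric matrix.
#' @export
gyration_tensor <- function(coords, box = NULL, auto_unwrap = TRUE) {
  coords <- as.matrix(coords)
  if (!is.null(box)) {
    jumps <- abs(diff(coords)) > box / 2
    if (any(jumps)) {
      if (!auto_unwrap)
        stop("ring wrapped across periodic boundary; enable auto_unwrap")
      coords <- unwrap_ring(coords, box)
    }
  }
  centred <- sweep(coords, 2, colMeans(coords))
  crossprod(centred) / nrow(coords)
}

#' Director of a ring conformation
#'
#' Unit eigenvector of the gyration tensor associated with the smallest
#' eigenvalue; for a planar ring it is the plane normal. The sign is fixed
#' deterministically (first nonzero component positive) since only
#' |d_i . d_j| is ever used. If the two smallest eigenvalues coincide within
#' `tol` (relative), the result carries attribute `degenerate = TRUE`.
#'
#' @param G 3 x 3 gyration tensor (or an object from [ring_shape()]).
#' @param tol relative degeneracy tolerance on lambda2 - lambda3.
#' @return unit 3-vector, possibly with attribute `degenerate`.
#' @export
director <- function(G, tol = 1e-8) {
  e <- eigen(G, symmetric = TRUE)
  d <- e$vectors[, 3]
  nz <- which(abs(d) > 1e-12)[1]
  if (!is.na(nz) && d[nz] < 0) d <- -d
  lam <- e$values
  if ((lam[2] - lam[3]) <= tol * max(lam[1], .Machine$double.eps))
    attr(d, "degenerate") <- TRUE
  d
}

#' Prolateness of a gyration tensor
#'
#' p = 27 (l1 - lbar)(l2 - lbar)(l3 - lbar) / (l1 + l2 + l3)^3 with lbar the
#' eigenvalue mean; dimensionless and invariant under rotation and uniform
#' scaling. Range `[-1/4, 2]`: +2 for an ideal thin rod (prolate), -1/4 for
#' an ideal thin disk (oblate), 0 for spherical symmetry.
#'
#' @param G 3 x 3 gyration tensor or its eigenvalue vector.
#' @return scalar prolateness.
#' @export
prolateness <- function(G) {
  lam <- if (is.matrix(G)) eigen(G, symmetric = TRUE, only.values = TRUE)$values
         else sort(G, decreasing = TRUE)
  tr <- sum(lam)
  if (tr <= 0) stop("undefined shape: zero gyration tensor")
  27 * prod(lam - tr / 3) / tr^3
}

#' Shape observables of one ring
#'
#' @param coords N x 3 ring coordinates (cyclic order).
#' @param box optional box edge for unwrapping.
#' @return object of class `ringstack_shape`: gyration eigenvalues
#'   (decreasing), `rg`, `prolateness`, `director`, `com`, `degenerate`.
#' @export
ring_shape <- function(coords, box = NULL) {
  if (!is.null(box)) {
    jumps <- abs(diff(coords)) > box / 2
    if (any(jumps)) coords <- unwrap_ring(coords, box)
  }
  G <- gyration_tensor(coords)
  lam <- eigen(G, symmetric = TRUE, only.values = TRUE)$values
  d <- director(G)
  structure(list(gyration_eigenvalues = lam, rg = sqrt(sum(lam)),
                 prolateness = prolateness(lam), director = as.numeric(d),
                 com = colMeans(coords),
                 degenerate = isTRUE(attr(d, "degenerate"))),
            class = "ringstack_shape")
}

#' Per-ring shapes for one configuration
#'
#' @param config a [configuration()].
#' @param topo a [ring_topology()].
#' @return list of [ring_shape()] objects, one per ring, with attribute
#'   `box`.
#' @export
shape_frame <- function(config, topo) {
  shapes <- lapply(topo$rings, function(idx) {
    ring_shape(config$positions[idx, , drop = FALSE], config$box_length)
  })
  attr(shapes, "box") <- config$box_length
  shapes
}

#' Shape table across a trajectory
#'
#' @param traj a `ringstack_trajectory`.
#' @return data.frame with columns frame, ring_id, rg, prolateness,
#'   dx, dy, dz (director), suitable for delimited-text export.
#' @export
shape_table <- function(traj) {
  do.call(rbind, lapply(seq_along(traj$frames), function(f) {
    shapes <- shape_frame(traj$frames[[f]], traj$topology)
    do.call(rbind, lapply(seq_along(shapes), function(i) {
      s <- shapes[[i]]
      data.frame(frame = f, ring_id = i, rg = s$rg,
                 prolateness = s$prolateness, dx = s$director[1],
                 dy = s$director[2], dz = s$director[3])
    }))
  }))
}

#' Joint histogram of scaled ring size and prolateness
#'
#' Normalised 2-D probability mass over (rg/rg0, prolateness) bins; the
#' masses sum to 1 (a `density` matrix dividing by bin areas is also
#' returned).
#'
#' @param shapes output of [shape_table()] (or any data.frame with `rg` and
#'   `prolateness` columns).
#' @param rg0 infinite-dilution single-ring radius of gyration (sigma).
#' @param rg_breaks,p_breaks bin edges.
#' @return list with `rg_breaks`, `p_breaks`, `mass`, `density`.
#' @export
shape_histogram <- function(shapes, rg0,
                            rg_breaks = seq(0, 2, by = 0.05),
                            p_breaks = seq(-0.3, 2, by = 0.05)) {
  if (nrow(shapes) == 0) stop("empty trajectory")
  x <- shapes$rg / rg0
  y <- shapes$prolateness
  ix <- cut(x, rg_breaks, include.lowest = TRUE)
  iy <- cut(y, p_breaks, include.lowest = TRUE)
  keep <- !is.na(ix) & !is.na(iy)
  h <- table(ix[keep], iy[keep])
  mass <- h / sum(h)
  areas <- outer(diff(rg_breaks), diff(p_breaks))
  list(rg_breaks = rg_breaks, p_breaks = p_breaks,
       mass = unclass(mass), density = unclass(mass) / areas)
}

#' Persistence length of the model backbone
#'
#' Simulates an isolated linear chain with the same bonded potentials as the
#' rings and fits an exponential to the tangent (bond-vector) correlation
#' C(s) = <t_i . t_(i+s)> over the short-separation window s = 0..`s_fit`
#' where the bending term dominates; the self-avoidance swelling of the
#' chain contaminates larger separations and their statistics converge
#' slowly (global chain conformations decorrelate over hundreds of tau), so
#' a short window is both less biased and markedly less noisy.
#' l_per = -<b> / slope of log C(s).
#'
#' @param ff a [forcefield()].
#' @param seed integer seed.
#' @param N chain length.
#' @param duration total run (tau); the first half is discarded as burn-in.
#' @param s_fit largest bond separation entering the fit.
#' @return list with `l_per` (sigma), `corr` (C(s) for s = 1..12),
#'   `mean_bond`.
#' @export
measure_persistence_length <- function(ff = forcefield(), seed = 1L, N = 50,
                                       duration = 3000, s_fit = 3) {
  box <- 3 * N
  chain <- cbind(seq(0, by = 0.96, length.out = N), box / 2, box / 2)
  set.seed(seed)
  chain <- chain + matrix(rnorm(3 * N, sd = 0.01), N, 3)
  cfg <- configuration(chain, rep("monomer", N), rep(0, N), box)
  topo <- ring_topology(list(seq_len(N)), closed = FALSE)
  traj <- run_langevin(cfg, topo, ff, duration, seed = seed,
                       dump_interval = 10)
  frames <- traj$frames[-seq_len(length(traj$frames) %/% 2)]
  smax <- min(12, N - 2)
  acc <- matrix(0, length(frames), smax)
  bl <- numeric(length(frames))
  for (f in seq_along(frames)) {
    b <- diff(frames[[f]]$positions)
    bl[f] <- mean(sqrt(rowSums(b^2)))
    b <- b / sqrt(rowSums(b^2))
    nb <- nrow(b)
    acc[f, ] <- vapply(seq_len(smax), function(s) {
      mean(rowSums(b[seq_len(nb - s), , drop = FALSE] *
                   b[(1 + s):nb, , drop = FALSE]))
    }, numeric(1))
  }
  corr <- colMeans(acc)
  s <- 0:s_fit
  fit <- lm(log(c(1, corr[seq_len(s_fit)])) ~ s)
  list(l_per = -mean(bl) / coef(fit)[[2]], corr = corr, mean_bond = mean(bl))
}

#' Infinite-dilution radius of gyration of a single ring
#'
#' Langevin run of one isolated ring in a large box; rg is sampled at fixed
#' intervals after a burn-in and averaged until the standard error of block
#' means drops below `rel_se` (relative), otherwise an error is raised.
#'
#' @param ff a [forcefield()].
#' @param seed integer seed.
#' @param N ring length.
#' @param electro_mode electrostatics for the isolated ring (default off:
#'   neutral reference).
#' @param burn_in,chunk_time time per stage (tau).
#' @param max_chunks convergence budget.
#' @param rel_se convergence criterion on the relative standard error.
#' @return list with `rg0`, `se`, `n_samples`.
#' @export
measure_rg0 <- function(ff = forcefield(), seed = 1L, N = 50,
                        electro_mode = "off", burn_in = 200,
                        chunk_time = 200, max_chunks = 40, rel_se = 0.01) {
  box <- 20 * N * 0.02 + 30
  ring <- make_planar_ring(N, 0.96, rep(box / 2, 3))
  species <- rep("monomer", N)
  charges <- if (electro_mode == "off") rep(0, N) else
    species_charges(species, ff)
  config <- configuration(ring, species, charges, box)
  topo <- ring_topology(list(seq_len(N)))
  state <- tail(run_langevin(config, topo, ff, burn_in, seed = seed,
                             electro_mode = electro_mode)$frames, 1)[[1]]
  block_means <- numeric(0)
  vel <- NULL
  for (chunk in seq_len(max_chunks)) {
    traj <- run_langevin(state, topo, ff, chunk_time, seed = seed + chunk,
                         electro_mode = electro_mode, dump_interval = 5)
    rgs <- vapply(traj$frames, function(fr) {
      ring_shape(fr$positions, fr$box_length)$rg
    }, numeric(1))
    block_means <- c(block_means, mean(rgs))
    state <- tail(traj$frames, 1)[[1]]
    if (length(block_means) >= 5) {
      se <- sd(block_means) / sqrt(length(block_means))
      if (se < rel_se * mean(block_means))
        return(list(rg0 = mean(block_means), se = se,
                    n_samples = length(block_means)))
    }
  }
  stop("measure_rg0 did not converge within budget")
}
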