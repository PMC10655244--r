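#' Planted-truth synthetic scenes
#'
#' Generators of idealised configurations with exactly known ground truth
#' (cluster labels, directors, threading records, condensed ion fractions),
#' used to test every analysis stage without molecular dynamics. Scenes are
#' unit-test fixtures, not Boltzmann-weighted samples.
#'
#' @name synthetic_scenes
NULL

rotation_from_z <- function(normal) {
  n <- normal / sqrt(sum(normal^2))
  z <- c(0, 0, 1)
  v <- c(z[2] * n[3] - z[3] * n[2], z[3] * n[1] - z[1] * n[3],
         z[1] * n[2] - z[2] * n[1])
  s <- sqrt(sum(v^2))
  c0 <- sum(z * n)
  if (s < 1e-12) {
    if (c0 > 0) return(diag(3))
    return(diag(c(1, -1, -1)))  # flip about x
  }
  vx <- matrix(c(0, -v[3], v[2], v[3], 0, -v[1], -v[2], v[1], 0), 3, 3,
               byrow = TRUE)
  diag(3) + vx + vx %*% vx * ((1 - c0) / s^2)
}

#' Regular planar ring
#'
#' Vertices of a regular N-gon of bond length `bond_length` (circumradius
#' b / (2 sin(pi/N))) in the plane perpendicular to `normal`.
#'
#' @param N number of monomers (>= 3).
#' @param bond_length edge length (sigma).
#' @param center 3-vector centre.
#' @param normal plane normal (any nonzero 3-vector).
#' @return N x 3 coordinate matrix.
#' @export
#' @examples
#' ring <- make_planar_ring(50)
#' sqrt(sum((ring[1, ] - ring[2, ])^2))  # 0.96
make_planar_ring <- function(N, bond_length = 0.96, center = c(0, 0, 0),
                             normal = c(0, 0, 1)) {
  stopifnot(N >= 3)
  R <- bond_length / (2 * sin(pi / N))
  th <- 2 * pi * (seq_len(N) - 1) / N
  xy <- cbind(R * cos(th), R * sin(th), 0)
  sweep(xy %*% t(rotation_from_z(normal)), 2, center, `+`)
}

#' Prolate (double-folded) ring
#'
#' Idealisation of the cigar-like collapsed conformations: N vertices
#' equally spaced along a racetrack curve (two antiparallel straight strands
#' joined by semicircular hairpins of radius `hairpin_radius`), elongated
#' along `axis`.
#'
#' @inheritParams make_planar_ring
#' @param hairpin_radius radius of the end caps (sigma).
#' @param axis direction of the long axis.
#' @return N x 3 coordinate matrix.
#' @export
make_prolate_ring <- function(N, bond_length = 0.96, center = c(0, 0, 0),
                              axis = c(0, 0, 1), hairpin_radius = 0.8) {
  stopifnot(N >= 8)
  per <- N * bond_length
  straight <- (per - 2 * pi * hairpin_radius) / 2
  if (straight <= 0) stop("hairpin_radius too large for ring length")
  s <- per * (seq_len(N) - 1) / N
  pts <- t(vapply(s, function(si) {
    if (si < straight) {                       # strand 1 at y = +rho
      c(hairpin_radius, si - straight / 2, 0)
    } else if (si < straight + pi * hairpin_radius) {  # far cap
      a <- (si - straight) / hairpin_radius
      c(hairpin_radius * cos(a), straight / 2 + hairpin_radius * sin(a), 0)
    } else if (si < 2 * straight + pi * hairpin_radius) {  # strand 2
      c(-hairpin_radius,
        straight / 2 - (si - straight - pi * hairpin_radius), 0)
    } else {                                   # near cap
      a <- (si - 2 * straight - pi * hairpin_radius) / hairpin_radius
      c(-hairpin_radius * cos(a), -straight / 2 - hairpin_radius * sin(a), 0)
    }
  }, numeric(3)))
  # long axis currently y; rotate y -> axis
  Rz <- rotation_from_z(axis)
  Ry <- matrix(c(1, 0, 0, 0, 0, 1, 0, -1, 0), 3, 3, byrow = TRUE)  # y -> z
  sweep(pts %*% t(Ry) %*% t(Rz), 2, center, `+`)
}

scene_truth <- function(cluster_labels = integer(), director_truth = NULL,
                        threading_truth = NULL,
                        condensed_fraction_truth = NA_real_) {
  structure(list(cluster_labels = cluster_labels,
                 director_truth = director_truth,
                 threading_truth = threading_truth,
                 condensed_fraction_truth = condensed_fraction_truth),
            class = "ringstack_scene_truth")
}

scene_config <- function(coord_list, box, time = 0) {
  pos <- do.call(rbind, coord_list)
  configuration(pos, rep("monomer", nrow(pos)), rep(0, nrow(pos)), box, time)
}

#' Cylindrical stack scene with planted cluster labels
#'
#' Builds `n_stacks` coaxial ring columns (plus optional dangling rings) with
#' controlled per-ring tilt and Gaussian vertex jitter. Stack axes are drawn
#' at random; column base positions are laid out on a grid and the function
#' refuses if the requested stacks cannot be placed without overlap.
#'
#' @param n_stacks number of columns.
#' @param sizes integer vector (length `n_stacks`) of rings per column.
#' @param spacing axial ring spacing within a column (sigma).
#' @param tilt_max per-ring tilt drawn uniformly from `[0, tilt_max]` (rad).
#' @param jitter standard deviation of isotropic Gaussian vertex noise
#'   (sigma).
#' @param box cubic box edge (sigma).
#' @param N monomers per ring.
#' @param bond_length bond length (sigma).
#' @param n_dangling isolated far-away rings, each its own planted cluster.
#' @param seed integer seed.
#' @param axis optional fixed stack axis (default: random per stack).
#' @return list with `config`, `topology`, `truth` (a `scene_truth` with
#'   per-ring cluster labels and exact directors).
#' @export
make_stack_scene <- function(n_stacks, sizes, spacing = 1, tilt_max = 0,
                             jitter = 0, box = NULL, N = 50,
                             bond_length = 0.96, n_dangling = 0, seed = 1L,
                             axis = NULL) {
  stopifnot(length(sizes) == n_stacks)
  set.seed(seed)
  R <- bond_length / (2 * sin(pi / N))
  n_cols <- n_stacks + n_dangling
  pitch <- 2 * R + 4
  n_side <- ceiling(sqrt(n_cols))
  max_h <- max(sizes) * spacing + 2
  if (is.null(box)) box <- max(n_side * pitch, max_h + 2 * R + 2)
  if (n_side * pitch > box + 1e-9)
    stop("overlapping stacks: box too small for requested columns")
  grid <- as.matrix(expand.grid(x = seq_len(n_side),
                                y = seq_len(n_side)))[seq_len(n_cols), ,
                                                      drop = FALSE]
  bases <- cbind((grid - 0.5) * pitch, box / 2)
  coords <- list()
  labels <- integer(0)
  dirs <- list()
  ring_id <- 0
  for (s in seq_len(n_stacks)) {
    ax <- if (is.null(axis)) rnorm(3) else axis
    ax <- ax / sqrt(sum(ax^2))
    for (j in seq_len(sizes[s])) {
      ring_id <- ring_id + 1
      center <- bases[s, ] + (j - (sizes[s] + 1) / 2) * spacing * ax
      normal <- tilt_axis(ax, runif(1, 0, tilt_max))
      ring <- make_planar_ring(N, bond_length, center, normal)
      if (jitter > 0) ring <- ring + matrix(rnorm(3 * N, sd = jitter), N, 3)
      coords[[ring_id]] <- ring
      labels[ring_id] <- s
      dirs[[ring_id]] <- normal
    }
  }
  for (d in seq_len(n_dangling)) {
    ring_id <- ring_id + 1
    normal <- rnorm(3)
    normal <- normal / sqrt(sum(normal^2))
    ring <- make_planar_ring(N, bond_length, bases[n_stacks + d, ], normal)
    if (jitter > 0) ring <- ring + matrix(rnorm(3 * N, sd = jitter), N, 3)
    coords[[ring_id]] <- ring
    labels[ring_id] <- n_stacks + d
    dirs[[ring_id]] <- normal
  }
  topo <- ring_topology(split(seq_len(ring_id * N),
                              rep(seq_len(ring_id), each = N)))
  list(config = scene_config(coords, box), topology = topo,
       truth = scene_truth(cluster_labels = labels,
                           director_truth = do.call(rbind, dirs)))
}

tilt_axis <- function(axis, angle) {
  if (angle == 0) return(axis)
  # rotate `axis` by `angle` about a random perpendicular direction
  p <- rnorm(3)
  p <- p - sum(p * axis) * axis
  p <- p / sqrt(sum(p^2))
  cos(angle) * axis + sin(angle) * p
}

#' Threading scenes with exactly known crossings
#'
#' `"rod_through_ring"`: a straight open rod piercing a planar ring's centre
#' (one crossing). `"ring_chain"`: a closed ring passing once through
#' another's spanning disk (two crossings, depths N/2 and N/2).
#' `"unlinked"`: two distant rings (no threading).
#'
#' @param kind scene type.
#' @param N monomers per ring (even).
#' @param bond_length bond length (sigma).
#' @param box box edge (sigma).
#' @return list with `config`, `topology`, `truth`; the rod (if present) is
#'   an open chain (`closed = FALSE` in the topology).
#' @export
make_threading_scene <- function(kind = c("rod_through_ring", "ring_chain",
                                          "unlinked"),
                                 N = 50, bond_length = 0.96, box = 60) {
  kind <- match.arg(kind)
  center <- c(box / 2, box / 2, box / 2)
  ring_b <- make_planar_ring(N, bond_length, center, c(0, 0, 1))
  if (kind == "rod_through_ring") {
    n_rod <- 12
    rod <- cbind(center[1], center[2],
                 center[3] + bond_length * (seq_len(n_rod) - (n_rod + 1) / 2))
    topo <- ring_topology(list(seq_len(N), N + seq_len(n_rod)),
                          closed = c(TRUE, FALSE))
    truth <- data.frame(active = 2L, passive = 1L, crossings = 1L)
    return(list(config = scene_config(list(ring_b, rod), box),
                topology = topo,
                truth = scene_truth(threading_truth = truth)))
  }
  if (kind == "ring_chain") {
    stopifnot(N %% 2 == 0)
    # active ring in the xz-plane, centred on the passive ring's centre:
    # it pierces the z = 0 spanning disk at two antipodal points
    Ra <- bond_length / (2 * sin(pi / N))
    th <- 2 * pi * (seq_len(N) - 1) / N + pi / N
    ring_a <- cbind(center[1] + Ra * cos(th), center[2],
                    center[3] + Ra * sin(th))
    topo <- ring_topology(list(seq_len(N), N + seq_len(N)))
    truth <- data.frame(active = 2L, passive = 1L, crossings = 2L)
    return(list(config = scene_config(list(ring_b, ring_a), box),
                topology = topo,
                truth = scene_truth(threading_truth = truth)))
  }
  Rring <- bond_length / (2 * sin(pi / N))
  ring_a <- make_planar_ring(N, bond_length, center + c(3 * Rring, 0, 0),
                             c(0, 1, 0))
  topo <- ring_topology(list(seq_len(N), N + seq_len(N)))
  list(config = scene_config(list(ring_b, ring_a), box), topology = topo,
       truth = scene_truth(threading_truth =
                             data.frame(active = integer(0),
                                        passive = integer(0),
                                        crossings = integer(0))))
}

#' Counterion cloud with a planted condensed fraction
#'
#' Places `round(fraction * n_ions)` ions within `shell_width` of randomly
#' chosen monomers (at the monomer-ion contact distance plus a uniform
#' offset), the remainder uniformly in the box.
#'
#' @param monomers matrix of monomer coordinates.
#' @param condensed_fraction target fraction in `[0, 1]`.
#' @param shell_width radial width of the condensation shell (sigma).
#' @param box box edge (sigma).
#' @param n_ions number of ions.
#' @param species ion species label.
#' @param ff a [forcefield()].
#' @param seed integer seed.
#' @return list with `positions` (ion coordinates) and `truth`.
#' @export
make_ion_cloud <- function(monomers, condensed_fraction, shell_width = 0.355,
                           box, n_ions, species = "ion_tri",
                           ff = forcefield(), seed = 1L) {
  stopifnot(condensed_fraction >= 0, condensed_fraction <= 1)
  set.seed(seed)
  n_cond <- round(condensed_fraction * n_ions)
  contact <- (ff$sigma_mon + ff$sigma_ion) / 2
  pos <- matrix(0, n_ions, 3)
  if (n_cond > 0) {
    hosts <- sample(nrow(monomers), n_cond, replace = TRUE)
    for (i in seq_len(n_cond)) {
      u <- rnorm(3)
      u <- u / sqrt(sum(u^2))
      d <- contact + runif(1, 0, 0.9 * shell_width)
      pos[i, ] <- monomers[hosts[i], ] + d * u
    }
  }
  if (n_cond < n_ions)
    pos[(n_cond + 1):n_ions, ] <- matrix(runif(3 * (n_ions - n_cond), 0, box),
                                         ncol = 3)
  list(positions = pos,
       truth = scene_truth(condensed_fraction_truth = condensed_fraction))
}
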