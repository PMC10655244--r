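#' Minimal surface spanning a ring contour
#'
#' Triangulated disk with the N monomer positions as fixed boundary vertices
#' and free interior ghost vertices (concentric rings plus a centre point,
#' about one ghost ring per sigma of radius). The ghost vertices follow a
#' backtracking gradient descent of the total area (virtual surface
#' tension); the area never increases. Convergence: the area changes by at
#' most `tol` (relative, default 0.1 %) over a window of `window`
#' consecutive steps.
#'
#' @param coords N x 3 unwrapped ring coordinates in cyclic order.
#' @param n_rings number of interior ghost rings (default: about one per
#'   sigma of mean contour radius).
#' @param tol relative-area convergence tolerance.
#' @param window convergence window in propagation steps.
#' @param max_steps step budget; exceeding it is an error reporting the last
#'   area.
#' @return object of class `ringstack_surface`: `vertices` (boundary first),
#'   `triangles` (1-based index triples), `area`, `n_boundary`, `steps`.
#' @export
build_minimal_surface <- function(coords, n_rings = NULL, tol = 0.001,
                                  window = 240, max_steps = 20000) {
  coords <- as.matrix(coords)
  if (is.null(n_rings)) {
    ctr <- colMeans(coords)
    rad <- mean(sqrt(rowSums(sweep(coords, 2, ctr)^2)))
    n_rings <- max(1L, min(10L, as.integer(round(rad))))
  }
  res <- rs_minimal_surface(coords, as.integer(n_rings), tol,
                            as.integer(window), as.integer(max_steps))
  if (!res$converged)
    stop(sprintf("minimal surface did not converge in %d steps (last area %.4f)",
                 max_steps, res$area))
  structure(list(vertices = res$vertices, triangles = res$triangles,
                 area = res$area, initial_area = res$initial_area,
                 n_boundary = nrow(coords), steps = res$steps,
                 area_trace = res$area_trace),
            class = "ringstack_surface")
}

#' @export
print.ringstack_surface <- function(x, ...) {
  cat(sprintf("Minimal surface: %d boundary + %d ghost vertices, %d triangles, area %.3f sigma^2\n",
              x$n_boundary, nrow(x$vertices) - x$n_boundary,
              nrow(x$triangles), x$area))
  invisible(x)
}

#' Segment-triangle intersection test
#'
#' Exact parametric (Moeller-Trumbore) test; boundary hits count as
#' intersections. Degenerate (near-zero area) triangles are rejected with
#' `degenerate = TRUE`.
#'
#' @param p0,p1 segment endpoints (3-vectors).
#' @param triangle 3 x 3 matrix of vertex rows.
#' @return list with `hit` (logical), `point` (intersection or `NULL`),
#'   `degenerate`.
#' @export
segment_triangle_intersect <- function(p0, p1, triangle) {
  triangle <- as.matrix(triangle)
  rs_segment_triangle(as.numeric(p0), as.numeric(p1),
                      triangle[1, ], triangle[2, ], triangle[3, ])
}

#' Detect threading events between all ring pairs
#'
#' For every ordered pair (A, B), tests whether any bond vector of ring A
#' (including its periodic images) pierces a triangle of ring B's minimal
#' surface; if so A is the active and B the passive partner. Each bond
#' counts at most one crossing (a bond can pierce a near-flat disk only
#' once). The crossing bonds cut A's contour into segments whose monomer
#' counts are the threading depths; depths always sum to N for a closed
#' active ring. An odd crossing count for a closed pair is geometrically
#' possible only for concatenated rings or mesh artefacts and is flagged via
#' a warning (the record is kept).
#'
#' @param config a [configuration()].
#' @param topo a [ring_topology()].
#' @param surfaces optional precomputed list of [build_minimal_surface()]
#'   results (rebuilt per ring otherwise).
#' @return data.frame-of-records: one row per (active, passive) pair with
#'   columns `active`, `passive`, `crossings`, and list-columns `bonds` and
#'   `depths`.
#' @export
detect_threadings <- function(config, topo, surfaces = NULL) {
  box <- config$box_length
  M <- topo$M
  closed <- if (!is.null(topo$closed)) topo$closed else rep(TRUE, M)
  rings <- lapply(seq_len(M), function(m) {
    unwrap_ring(config$positions[topo$rings[[m]], , drop = FALSE], box)
  })
  if (is.null(surfaces))
    surfaces <- lapply(rings, build_minimal_surface)
  coms <- lapply(rings, colMeans)
  radii <- vapply(seq_len(M), function(m) {
    max(sqrt(rowSums(sweep(rings[[m]], 2, coms[[m]])^2)))
  }, numeric(1))
  records <- list()
  for (A in seq_len(M)) {
    nA <- nrow(rings[[A]])
    s0 <- rings[[A]]
    s1 <- if (closed[A]) rings[[A]][c(2:nA, 1), , drop = FALSE] else
      rings[[A]][-1, , drop = FALSE]
    if (!closed[A]) s0 <- s0[-nA, , drop = FALSE]
    nb <- nrow(s0)
    for (B in seq_len(M)) {
      if (A == B) next
      base <- box * round((coms[[A]] - coms[[B]]) / box)
      hit_bonds <- logical(nb)
      for (sx in -1:1) for (sy in -1:1) for (sz in -1:1) {
        shift <- base + box * c(sx, sy, sz)
        dc <- coms[[A]] - shift - coms[[B]]
        if (sqrt(sum(dc^2)) > radii[A] + radii[B] + 1) next
        hs <- rs_segments_cross_mesh(sweep(s0, 2, shift),
                                     sweep(s1, 2, shift),
                                     surfaces[[B]]$vertices,
                                     surfaces[[B]]$triangles)
        hit_bonds <- hit_bonds | (hs > 0)
      }
      nx <- sum(hit_bonds)
      if (nx == 0) next
      bonds <- which(hit_bonds)
      depths <- if (closed[A] && nx > 0) {
        if (nx %% 2 == 1)
          warning(sprintf("odd crossing count (%d) for pair (%d, %d): possible mesh artefact",
                          nx, A, B))
        diff(c(bonds, bonds[1] + nA))
      } else NA
      records[[length(records) + 1]] <-
        data.frame(active = A, passive = B, crossings = nx,
                   bonds = I(list(bonds)), depths = I(list(depths)))
    }
  }
  if (length(records) == 0)
    return(data.frame(active = integer(0), passive = integer(0),
                      crossings = integer(0), bonds = I(list()),
                      depths = I(list())))
  do.call(rbind, records)
}

#' Threading count statistics and shape correlations
#'
#' Per-ring numbers of passive partners (how many other rings thread this
#' one) and active partners (how many other rings this one threads), their
#' marginal distributions, and normalised joint histograms against
#' prolateness.
#'
#' @param records output of [detect_threadings()] (one frame, or rbind of
#'   frames with an added `frame` column).
#' @param shapes list of [ring_shape()] objects aligned with ring ids.
#' @param p_breaks prolateness bin edges for the joint histograms.
#' @return list with `per_ring` (data.frame: ring, passive, active,
#'   prolateness), `P_passive`, `P_active` (named probability vectors
#'   summing to 1), `joint_passive`, `joint_active` (mass matrices summing
#'   to 1).
#' @export
threading_statistics <- function(records, shapes,
                                 p_breaks = seq(-0.3, 2.05, by = 0.05)) {
  M <- length(shapes)
  passive <- tabulate(records$passive, nbins = M)
  active <- tabulate(records$active, nbins = M)
  prol <- vapply(shapes, `[[`, numeric(1), "prolateness")
  per_ring <- data.frame(ring = seq_len(M), passive = passive,
                         active = active, prolateness = prol)
  pdist <- function(x) {
    tab <- table(factor(x, levels = 0:max(x)))
    p <- as.numeric(tab) / sum(tab)
    names(p) <- names(tab)
    p
  }
  joint <- function(counts) {
    ib <- cut(prol, p_breaks, include.lowest = TRUE)
    h <- table(ib, factor(counts, levels = 0:max(counts)))
    h / sum(h)
  }
  list(per_ring = per_ring, P_passive = pdist(passive),
       P_active = pdist(active), joint_passive = unclass(joint(passive)),
       joint_active = unclass(joint(active)))
}

#' Export a surface mesh in OFF format
#'
#' @param surface a [build_minimal_surface()] result.
#' @param path output file.
#' @export
write_off <- function(surface, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(sprintf("%d %d 0", nrow(surface$vertices),
                     nrow(surface$triangles)), con)
  writeLines(apply(surface$vertices, 1, function(v)
    sprintf("%.8g %.8g %.8g", v[1], v[2], v[3])), con)
  writeLines(apply(surface$triangles, 1, function(t)
    sprintf("3 %d %d %d", t[1] - 1, t[2] - 1, t[3] - 1)), con)
  invisible(path)
}
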