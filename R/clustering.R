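#' Geometric stacking criteria
#'
#' Two rings i < j are stacked when simultaneously (1) their directors are
#' near parallel, |d_i . d_j| >= 1 - delta_omega; (2) the axial centre
#' separation projected on ring i's director is at most `v_parallel`;
#' (3) the lateral (in-plane) centre separation is at most
#' `v_perpendicular`. Boundary equalities count as satisfied. Centre
#' separations use the minimum-image convention.
#'
#' @param delta_omega alignment tolerance (dimensionless, in (0, 1)).
#' @param v_parallel axial distance threshold (sigma).
#' @param v_perpendicular lateral distance threshold (sigma).
#' @param neighbor_cut centre-distance cut used by
#'   [alignment_distribution()]; default `0.5 * rg0` supplied there.
#' @return object of class `ringstack_criteria`.
#' @export
stack_criteria <- function(delta_omega = 0.1, v_parallel = 3.0,
                           v_perpendicular = 2.5, neighbor_cut = NULL) {
  stopifnot(delta_omega > 0, delta_omega < 1, v_parallel > 0,
            v_perpendicular > 0)
  structure(list(delta_omega = delta_omega, v_parallel = v_parallel,
                 v_perpendicular = v_perpendicular,
                 neighbor_cut = neighbor_cut),
            class = "ringstack_criteria")
}

#' Pairwise stacking test
#'
#' @param shape_i,shape_j [ring_shape()] objects; the projection axis is
#'   ring i's director (the pair is taken as i < j).
#' @param criteria a [stack_criteria()].
#' @param box box edge for minimum image.
#' @return `TRUE`/`FALSE`, or `NA` if either director is degenerate (pair
#'   excluded from the graph).
#' @export
pair_stacked <- function(shape_i, shape_j, criteria = stack_criteria(),
                         box = Inf) {
  if (isTRUE(shape_i$degenerate) || isTRUE(shape_j$degenerate)) return(NA)
  if (abs(sum(shape_i$director * shape_j$director)) <
      1 - criteria$delta_omega) return(FALSE)
  rij <- shape_j$com - shape_i$com
  if (is.finite(box)) rij <- rij - box * round(rij / box)
  axial <- sum(rij * shape_i$director)
  if (abs(axial) > criteria$v_parallel) return(FALSE)
  lateral <- sqrt(sum((rij - axial * shape_i$director)^2))
  lateral <= criteria$v_perpendicular
}

#' Stack partition of one frame
#'
#' Builds the strictly-upper-triangular adjacency induced by
#' [pair_stacked()] over all pairs i < j and labels rings by the maximal
#' connected components of the resulting undirected graph (each component is
#' one cylindrical stack).
#'
#' @param shapes list of [ring_shape()] objects (see [shape_frame()]).
#' @param criteria a [stack_criteria()].
#' @param box box edge (defaults to the `box` attribute of `shapes`).
#' @return object of class `ringstack_partition`: `labels` (per-ring cluster
#'   id), `sizes` (per-cluster), `W` (weight fraction per aggregation number
#'   N_s), `Nw` (weight-averaged aggregation number sum N_s W(N_s)),
#'   `dangling_fraction` (= W(1)), `excluded_pairs` (degenerate-director
#'   count).
#' @export
build_partition <- function(shapes, criteria = stack_criteria(), box = NULL) {
  if (is.null(box)) box <- attr(shapes, "box")
  if (is.null(box)) box <- Inf
  M <- length(shapes)
  edges <- matrix(integer(0), 0, 2)
  excluded <- 0L
  if (M > 1) {
    el <- list()
    for (i in seq_len(M - 1)) {
      for (j in (i + 1):M) {
        st <- pair_stacked(shapes[[i]], shapes[[j]], criteria, box)
        if (is.na(st)) excluded <- excluded + 1L
        else if (st) el[[length(el) + 1]] <- c(i, j)
      }
    }
    if (length(el)) edges <- do.call(rbind, el)
  }
  g <- igraph::make_empty_graph(n = M, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  labels <- igraph::components(g)$membership
  sizes <- as.integer(table(labels))
  ns <- sort(unique(sizes))
  W <- vapply(ns, function(s) sum(sizes[sizes == s]) / M, numeric(1))
  names(W) <- ns
  structure(list(labels = as.integer(labels), sizes = sizes, W = W,
                 Nw = sum(ns * W),
                 dangling_fraction = if ("1" %in% names(W)) W[["1"]] else 0,
                 excluded_pairs = excluded),
            class = "ringstack_partition")
}

#' @export
print.ringstack_partition <- function(x, ...) {
  cat(sprintf("Stack partition: %d rings in %d clusters, Nw = %.2f, dangling W(1) = %.2f\n",
              length(x$labels), length(x$sizes), x$Nw, x$dangling_fraction))
  invisible(x)
}

#' Director alignment distribution of neighbouring rings
#'
#' Normalised density of |d_1 . d_2| over ring pairs whose centres of mass
#' are separated by at most `0.5 * rg0` (minimum image).
#'
#' @param shapes list of [ring_shape()] objects.
#' @param rg0 infinite-dilution radius of gyration (sigma).
#' @param box box edge.
#' @param nbins number of bins on [0, 1].
#' @return list with `mids`, `density`, `n_pairs`, `empty` flag; the density
#'   integrates to 1 when pairs exist.
#' @export
alignment_distribution <- function(shapes, rg0, box = NULL, nbins = 20) {
  if (is.null(box)) box <- attr(shapes, "box")
  if (is.null(box)) box <- Inf
  cut <- 0.5 * rg0
  M <- length(shapes)
  vals <- numeric(0)
  if (M > 1) {
    for (i in seq_len(M - 1)) {
      for (j in (i + 1):M) {
        rij <- shapes[[j]]$com - shapes[[i]]$com
        if (is.finite(box)) rij <- rij - box * round(rij / box)
        if (sum(rij^2) <= cut^2)
          vals <- c(vals, abs(sum(shapes[[i]]$director *
                                  shapes[[j]]$director)))
      }
    }
  }
  breaks <- seq(0, 1, length.out = nbins + 1)
  if (length(vals) == 0)
    return(list(mids = (breaks[-1] + breaks[-nbins - 1]) / 2,
                density = rep(NA_real_, nbins), n_pairs = 0L, empty = TRUE))
  h <- hist(pmin(vals, 1), breaks = breaks, plot = FALSE)
  list(mids = h$mids, density = h$density, n_pairs = length(vals),
       empty = FALSE)
}
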