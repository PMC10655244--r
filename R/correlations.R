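#' Centre-of-mass trajectory of the rings
#'
#' Unwraps each ring and returns its centre of mass per frame.
#'
#' @param traj a `ringstack_trajectory`.
#' @return list with `coms` (list of M x 3 matrices), `times`, `box`.
#' @export
com_trajectory <- function(traj) {
  box <- traj$frames[[1]]$box_length
  coms <- lapply(traj$frames, function(fr) {
    t(vapply(traj$topology$rings, function(idx) {
      colMeans(unwrap_ring(fr$positions[idx, , drop = FALSE], fr$box_length))
    }, numeric(3)))
  })
  list(coms = coms, times = vapply(traj$frames, `[[`, numeric(1), "time"),
       box = box)
}

# lattice-legal wavevectors (2 pi / L) * n with 0 < |k| <= kmax
legal_kvectors <- function(box, kmax) {
  dk <- 2 * pi / box
  nmax <- floor(kmax / dk)
  if (nmax < 1) stop("kmax below the smallest legal wavevector 2*pi/L")
  n <- expand.grid(x = -nmax:nmax, y = -nmax:nmax, z = -nmax:nmax)
  K <- as.matrix(n) * dk
  kn <- sqrt(rowSums(K^2))
  keep <- kn > 1e-12 & kn <= kmax + 1e-12
  list(K = K[keep, , drop = FALSE], knorm = kn[keep])
}

#' Static structure factor between ring centres of mass
#'
#' S(k) = (1/M) < |sum_a exp(i k . R_a)|^2 > averaged over configurations
#' and over all lattice-legal wavevectors in shells of width pi/L around
#' each k magnitude; normalised so S -> 1 for uncorrelated points.
#'
#' @param coms list of M x 3 centre-of-mass matrices (one per frame), or the
#'   result of [com_trajectory()].
#' @param box cubic box edge (sigma).
#' @param kmax largest wavenumber to evaluate (1/sigma).
#' @return data.frame with columns `k` (shell centre), `S`, `n_vectors`.
#' @export
structure_factor <- function(coms, box = NULL, kmax = 3) {
  if (is.list(coms) && !is.null(coms$coms)) {
    box <- coms$box
    coms <- coms$coms
  }
  stopifnot(length(coms) >= 1, !is.null(box))
  kv <- legal_kvectors(box, kmax)
  M <- nrow(coms[[1]])
  Sk <- numeric(nrow(kv$K))
  for (fr in coms) {
    ph <- exp(1i * kv$K %*% t(fr))       # n_k x M
    amp <- rowSums(ph)
    Sk <- Sk + Mod(amp)^2 / M
  }
  Sk <- Sk / length(coms)
  # shell-average: bins of width pi/L
  dk <- pi / box
  bin <- floor(kv$knorm / dk + 0.5)
  agg <- tapply(Sk, bin, mean)
  cnt <- tapply(Sk, bin, length)
  kc <- tapply(kv$knorm, bin, mean)
  data.frame(k = as.numeric(kc), S = as.numeric(agg),
             n_vectors = as.integer(cnt))
}

#' Position of the cluster peak of S(k)
#'
#' @param sk data.frame from [structure_factor()].
#' @param k_range optional window `c(kmin, kmax)` to search.
#' @return the `k` of the maximal `S` in the window.
#' @export
structure_factor_peak <- function(sk, k_range = NULL) {
  if (!is.null(k_range)) sk <- sk[sk$k >= k_range[1] & sk$k <= k_range[2], ]
  if (nrow(sk) == 0) stop("no structure-factor bins in window")
  sk$k[which.max(sk$S)]
}

#' Radial distribution function between two species
#'
#' Standard g(r) with ideal-gas normalisation and minimum-image convention.
#' Distances beyond L/2 are truncated (with a warning if explicitly
#' requested).
#'
#' @param frames a `ringstack_trajectory`, a list of [configuration()]s, or
#'   a single configuration.
#' @param species_a,species_b species labels.
#' @param bin_width histogram bin width (sigma).
#' @param r_max maximal distance (default L/2).
#' @return data.frame with columns `r` (bin centres) and `g`.
#' @export
pair_correlation <- function(frames, species_a, species_b, bin_width = 0.05,
                             r_max = NULL) {
  frames <- as_config_list(frames)
  box <- frames[[1]]$box_length
  if (is.null(r_max)) r_max <- box / 2
  if (r_max > box / 2) {
    warning("r_max beyond L/2; truncating to L/2")
    r_max <- box / 2
  }
  nbins <- max(1L, floor(r_max / bin_width))
  r_max <- nbins * bin_width
  counts <- numeric(nbins)
  na <- nb <- 0
  same <- identical(species_a, species_b)
  for (cf in frames) {
    A <- cf$positions[cf$species == species_a, , drop = FALSE]
    B <- cf$positions[cf$species == species_b, , drop = FALSE]
    if (nrow(A) == 0 || nrow(B) == 0)
      stop("species not present in configuration")
    A <- A %% box; B <- B %% box
    counts <- counts + rs_pair_histogram(A, B, same, box, r_max, nbins)
    na <- nrow(A); nb <- nrow(B)
  }
  nf <- length(frames)
  edges <- seq(0, r_max, length.out = nbins + 1)
  vol <- 4 / 3 * pi * diff(edges^3)
  rho_b <- nb / box^3
  # ordered-pair count per bin: unordered histogram doubled for same species
  ordered <- if (same) 2 * counts else counts
  g <- ordered / (nf * na * rho_b * vol)
  data.frame(r = (edges[-1] + edges[-nbins - 1]) / 2, g = g)
}

as_config_list <- function(frames) {
  if (inherits(frames, "ringstack_trajectory")) return(frames$frames)
  if (inherits(frames, "ringstack_configuration")) return(list(frames))
  frames
}

#' Intermediate scattering functions of the ring centres of mass
#'
#' Coherent (collective): F_coh(k, dt) proportional to
#' < sum_ab exp(i k . (R_a(t+dt) - R_b(t))) >, normalised by its dt = 0
#' value. Incoherent (self): F_inc(k, dt) = (1/M) < sum_a
#' exp(i k . (R_a(t+dt) - R_a(t))) >, equal to 1 at dt = 0 by construction.
#' Averaged over all time origins and over the shell of lattice-legal
#' wavevectors with | |k| - k_max | <= pi/L.
#'
#' @param coms result of [com_trajectory()] (or list of M x 3 matrices with
#'   `box` and `times` given).
#' @param k_max shell wavenumber (1/sigma), typically the cluster-peak
#'   position of [structure_factor()].
#' @param mode `"incoherent"` or `"coherent"`.
#' @param box,times required if `coms` is a bare list.
#' @param lags integer frame lags to evaluate (default: log-spaced).
#' @return object of class `ringstack_isf`: data.frame with `lag` (tau) and
#'   `F`, plus attributes `k`, `mode`.
#' @export
isf <- function(coms, k_max, mode = c("incoherent", "coherent"), box = NULL,
                times = NULL, lags = NULL) {
  mode <- match.arg(mode)
  if (is.list(coms) && !is.null(coms$coms)) {
    box <- coms$box
    times <- coms$times
    coms <- coms$coms
  }
  nf <- length(coms)
  stopifnot(nf >= 2)
  M <- nrow(coms[[1]])
  dkshell <- pi / box
  kv <- legal_kvectors(box, k_max + dkshell)
  keep <- abs(kv$knorm - k_max) <= dkshell
  if (!any(keep)) stop("no legal wavevectors in the k_max shell")
  K <- kv$K[keep, , drop = FALSE]
  if (is.null(lags)) {
    lags <- unique(round(exp(seq(0, log(nf - 1), length.out = 20))))
    lags <- c(0, lags[lags >= 1 & lags <= nf - 1])
  }
  # per-frame phase matrices e^{i k . R}
  ph <- lapply(coms, function(fr) exp(1i * K %*% t(fr)))   # n_k x M
  amp <- lapply(ph, rowSums)                               # n_k, coherent
  Fv <- vapply(lags, function(l) {
    orig <- seq_len(nf - l)
    if (mode == "incoherent") {
      v <- vapply(orig, function(t0) {
        mean(Re(rowMeans(ph[[t0 + l]] * Conj(ph[[t0]]))))
      }, numeric(1))
      mean(v)
    } else {
      v <- vapply(orig, function(t0) {
        mean(Re(amp[[t0 + l]] * Conj(amp[[t0]]))) / M
      }, numeric(1))
      mean(v)
    }
  }, numeric(1))
  if (mode == "coherent") Fv <- Fv / Fv[1]
  dt <- if (!is.null(times)) mean(diff(times)) else 1
  structure(data.frame(lag = lags * dt, F = Fv), k = k_max, mode = mode,
            class = c("ringstack_isf", "data.frame"))
}

#' Relaxation time from an ISF series
#'
#' tau_R solves F(k_max, tau_R) = 1/e; found by log-time linear
#' interpolation between the bracketing lags of the first downward crossing.
#' Returns `NA` with attribute `unresolved = TRUE` when the series never
#' crosses 1/e within the window.
#'
#' @param series a data.frame with `lag` and `F` columns (see [isf()]).
#' @return relaxation time (tau), possibly flagged.
#' @export
relaxation_time <- function(series) {
  th <- exp(-1)
  lag <- series$lag
  Fv <- series$F
  pos <- lag > 0
  lag <- lag[pos]; Fv <- Fv[pos]
  below <- which(Fv <= th)
  if (length(below) == 0) {
    out <- NA_real_
    attr(out, "unresolved") <- TRUE
    return(out)
  }
  i2 <- below[1]
  if (i2 == 1) return(lag[1])
  i1 <- i2 - 1
  lt <- log(lag[i1]) + (log(lag[i2]) - log(lag[i1])) *
    (Fv[i1] - th) / (Fv[i1] - Fv[i2])
  exp(lt)
}

#' Condensed counterion fraction
#'
#' Time-averaged fraction of ions of each species whose minimum-image
#' distance to the nearest monomer is at most `shell`.
#'
#' @param frames trajectory, configuration list, or single configuration.
#' @param shell condensation shell radius (sigma); should exceed the
#'   monomer-ion contact distance.
#' @return named numeric vector, one entry per ion species present.
#' @export
condensed_fraction <- function(frames, shell) {
  frames <- as_config_list(frames)
  species <- setdiff(unique(frames[[1]]$species), "monomer")
  out <- setNames(numeric(length(species)), species)
  for (sp in species) {
    fr_frac <- vapply(frames, function(cf) {
      ions <- cf$positions[cf$species == sp, , drop = FALSE]
      mons <- cf$positions[cf$species == "monomer", , drop = FALSE]
      d <- rs_min_dists(ions, mons, cf$box_length)
      mean(d <= shell)
    }, numeric(1))
    out[sp] <- mean(fr_frac)
  }
  out
}
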