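#' Force field for the charged bead-spring ring model
#'
#' Bundles every interaction parameter of the microscopic model in reduced
#' units (sigma_mon = 1 corresponds to 1 nm, k_B T = 1, m = 1): WCA excluded
#' volume, FENE bonds, harmonic cosine bending, unscreened Coulomb with
#' Bjerrum length `bjerrum`, plus the Langevin integration parameters.
#'
#' Defaults are the DNA mini-ring parametrisation: one bead represents three
#' nucleotides of ssDNA and carries charge number -3; counterions are +1
#' (monovalent) or +3 (trivalent) with diameter 0.355 sigma; cross excluded
#' volume uses Lorentz-Berthelot mixing, so monomer-ion contact sits at
#' (sigma_mon + sigma_ion)/2 = 0.6775 sigma.
#'
#' @param epsilon WCA energy scale (k_B T).
#' @param sigma_mon monomer diameter (sigma; 1 sigma corresponds to 1 nm).
#' @param sigma_ion counterion diameter (sigma).
#' @param K_fene FENE spring constant (k_B T / sigma^2).
#' @param R0 FENE maximum extension (sigma).
#' @param K_bend bending constant of the harmonic cosine potential (k_B T).
#' @param bjerrum Bjerrum length (sigma, i.e. nm).
#' @param z_mon,z_ion_mono,z_ion_tri charge numbers of monomers and of the
#'   two counterion species.
#' @param gamma Langevin friction coefficient (1/tau).
#' @param mass particle mass (reduced units).
#' @param dt integration time step (tau).
#' @return object of class `ringstack_forcefield` (a named list).
#' @export
#' @examples
#' ff <- forcefield()
#' ff$bjerrum
forcefield <- function(epsilon = 1, sigma_mon = 1, sigma_ion = 0.355,
                       K_fene = 30, R0 = 1.5, K_bend = 30, bjerrum = 0.71,
                       z_mon = -3, z_ion_mono = 1, z_ion_tri = 3,
                       gamma = 1, mass = 1, dt = 0.005) {
  lens <- c(sigma_mon = sigma_mon, sigma_ion = sigma_ion, R0 = R0,
            bjerrum = bjerrum)
  if (any(lens <= 0)) stop("all lengths must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  if (R0 <= 2^(1 / 6) * (sigma_mon + sigma_ion) / 2 && R0 <= sigma_mon)
    stop("R0 must exceed pairwise contact distances")
  ff <- list(epsilon = epsilon, sigma_mon = sigma_mon, sigma_ion = sigma_ion,
             K_fene = K_fene, R0 = R0, K_bend = K_bend, bjerrum = bjerrum,
             z_mon = z_mon, z_ion_mono = z_ion_mono, z_ion_tri = z_ion_tri,
             gamma = gamma, mass = mass, dt = dt)
  class(ff) <- "ringstack_forcefield"
  ff
}

#' @export
print.ringstack_forcefield <- function(x, ...) {
  cat("Charged bead-spring ring force field (reduced units)\n")
  for (nm in names(x)) cat(sprintf("  %-10s = %g\n", nm, x[[nm]]))
  invisible(x)
}

#' Write / read a force field as a plain-text key = value file
#'
#' @param ff a [forcefield()] object.
#' @param path file path.
#' @return `read_forcefield` returns a `ringstack_forcefield`.
#' @export
write_forcefield <- function(ff, path) {
  stopifnot(inherits(ff, "ringstack_forcefield"))
  writeLines(sprintf("%s = %.17g", names(ff), unlist(ff)), path)
  invisible(path)
}

#' @rdname write_forcefield
#' @export
read_forcefield <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  keys <- trimws(vapply(kv, `[`, "", 1))
  vals <- as.numeric(trimws(vapply(kv, `[`, "", 2)))
  do.call(forcefield, as.list(setNames(vals, keys)))
}

#' Bjerrum length of an aqueous dielectric continuum
#'
#' Computes l_B = e^2 / (4 pi eps0 eps_r k_B T) in nanometres from SI
#' constants. With eps_r = 78.5 and T = 298 K this gives 0.71 nm, the value
#' used by the default force field.
#'
#' @param epsilon_r relative permittivity of the solvent.
#' @param temperature absolute temperature (K).
#' @return Bjerrum length in nm.
#' @export
#' @examples
#' bjerrum_length()  # ~0.71 nm
bjerrum_length <- function(epsilon_r = 78.5, temperature = 298) {
  e <- 1.602176634e-19       # C
  eps0 <- 8.8541878128e-12   # F/m
  kB <- 1.380649e-23         # J/K
  lb_m <- e^2 / (4 * pi * eps0 * epsilon_r * kB * temperature)
  lb_m * 1e9
}

#' Manning condensation parameters of the ring model
#'
#' The contour charge density of the model rings is |z_mon| e per monomer
#' diameter, i.e. 3 e/nm at defaults, or lambda = |z_mon| l_B / sigma_mon in
#' units of e per Bjerrum length. The Manning parameter of a counterion of
#' valence z is xi = z * lambda * l_B (dimensionless); condensation sets in
#' above xi = 1.
#'
#' @param ff a [forcefield()] object.
#' @return list with `line_charge_e_per_lB` (contour charge density in
#'   e / l_B), `xi_mono` and `xi_tri` (Manning parameters of the monovalent
#'   and trivalent counterions).
#' @export
#' @examples
#' manning_parameters(forcefield())
manning_parameters <- function(ff = forcefield()) {
  lambda <- abs(ff$z_mon) / ff$sigma_mon        # e per nm
  list(line_charge_e_per_lB = lambda * ff$bjerrum,
       xi_mono = abs(ff$z_ion_mono) * lambda * ff$bjerrum,
       xi_tri = abs(ff$z_ion_tri) * lambda * ff$bjerrum)
}
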