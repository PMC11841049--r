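# CODATA values
.N_A <- 6.02214076e23   # 1/mol
.k_B <- 1.380649e-23    # J/K

#' Reduced-unit system from the water-bead coarse-graining rule
#'
#' A DPD water bead represents two water molecules at a reduced bead
#' density \eqn{\rho r_c^3 = 3}. Matching that to the real mass density of
#' water fixes the length scale:
#' \deqn{r_c^3 = \rho r_c^3 \, M(\mathrm{2H_2O}) / (N_A \varrho_w)}
#' with \eqn{M(\mathrm{2H_2O}) = 36} g/mol and
#' \eqn{\varrho_w = 1000} g/L, giving \eqn{r_c \simeq 0.564} nm. The
#' energy scale is \eqn{k_B T_{ref}}; every derived conversion factor
#' (pressure, tension, density) is computed from these inputs at run time,
#' never hard-coded.
#'
#' @param T_ref reference absolute temperature in K. The default 298 K
#'   corresponds to the reduced temperature T = 1 of the force field.
#' @param bead_density reduced bead density \eqn{\rho r_c^3} of the
#'   reference water mapping.
#' @param molar_mass molar mass of the water bead in g/mol.
#' @param mass_density real mass density of water in g/L.
#' @return An object of class `dpd_units` with the length scale in nm and
#'   the derived pressure (Pa), tension (mN/m) and molar volume (L/mol)
#'   conversion factors for one reduced unit.
#' @examples
#' u <- dpd_units()
#' u$r_c_nm             # ~0.564
#' pressure_to_real(23.7, u) / 1e9   # ~0.54 GPa
#' @export
dpd_units <- function(T_ref = 298, bead_density = 3, molar_mass = 36,
                      mass_density = 1000) {
  stopifnot(T_ref > 0)
  r_c_nm <- length_scale(bead_density, molar_mass, mass_density)
  r_c_m <- r_c_nm * 1e-9
  energy_J <- .k_B * T_ref
  u <- list(
    T_ref = T_ref,
    bead_density_reduced = bead_density,
    molar_mass_water_bead = molar_mass,
    r_c_nm = r_c_nm,
    energy_J = energy_J,
    pressure_Pa = energy_J / r_c_m^3,        # k_B T / r_c^3
    tension_mN_m = energy_J / r_c_m^2 * 1e3, # k_B T / r_c^2
    molar_volume_L = .N_A * (r_c_m * 10)^3   # N_A r_c^3, ~0.108 L/mol
  )
  class(u) <- "dpd_units"
  u
}

#' @export
print.dpd_units <- function(x, ...) {
  cat("DPD unit system (T_ref =", x$T_ref, "K)\n")
  cat(sprintf("  r_c          : %.4f nm\n", x$r_c_nm))
  cat(sprintf("  pressure unit: %.4g Pa\n", x$pressure_Pa))
  cat(sprintf("  tension unit : %.4g mN/m\n", x$tension_mN_m))
  cat(sprintf("  N_A r_c^3    : %.4g L/mol\n", x$molar_volume_L))
  invisible(x)
}

#' Length scale of the coarse-grained model
#'
#' Computes \eqn{r_c = (\rho r_c^3 \, M / (N_A \varrho))^{1/3}} in nm from
#' the reduced bead density, the bead molar mass (g/mol) and the real mass
#' density (g/L).
#'
#' @param bead_density reduced bead density \eqn{\rho r_c^3}
#' @param molar_mass bead molar mass in g/mol
#' @param mass_density real mass density in g/L
#' @return length in nm
#' @examples
#' length_scale(3, 36, 1000)  # ~0.564 nm
#' @export
length_scale <- function(bead_density, molar_mass, mass_density) {
  if (!(bead_density > 0 && molar_mass > 0 && mass_density > 0))
    stop("all arguments to length_scale() must be positive")
  # volume in L = dm^3; 1 dm = 1e8 nm
  (bead_density * molar_mass / (.N_A * mass_density))^(1 / 3) * 1e8
}

#' Convert a reduced bead density to a real mass density
#'
#' Multiplies by \eqn{M(\mathrm{bead}) / (N_A r_c^3)}, where
#' \eqn{N_A r_c^3 \simeq 0.108} L/mol for the reference water mapping.
#'
#' @param rho_reduced reduced bead density \eqn{\rho r_c^3} (>= 0)
#' @param molar_mass_bead bead molar mass in g/mol
#' @param units a [dpd_units()] object
#' @return mass density in g/L
#' @examples
#' reduced_density_to_real(3.27, 24.3)  # ~736 g/L, liquid dodecane
#' @export
reduced_density_to_real <- function(rho_reduced, molar_mass_bead,
                                    units = dpd_units()) {
  stopifnot(all(rho_reduced >= 0))
  rho_reduced * molar_mass_bead / units$molar_volume_L
}

#' Convert a reduced pressure to Pa
#'
#' One reduced pressure unit is \eqn{k_B T / r_c^3 \simeq 2.3\times 10^7}
#' Pa at 298 K.
#'
#' @param p_reduced pressure in reduced units
#' @inheritParams reduced_density_to_real
#' @return pressure in Pa
#' @export
pressure_to_real <- function(p_reduced, units = dpd_units()) {
  p_reduced * units$pressure_Pa
}

#' Convert a reduced interfacial tension to mN/m
#'
#' One reduced tension unit is \eqn{k_B T / r_c^2 \simeq 12.9} mN/m at
#' 298 K.
#'
#' @param gamma_reduced tension in reduced units
#' @inheritParams reduced_density_to_real
#' @return tension in mN/m
#' @export
tension_to_real <- function(gamma_reduced, units = dpd_units()) {
  gamma_reduced * units$tension_mN_m
}
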