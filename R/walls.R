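#' Smooth-wall specification
#'
#' The substrate is a smooth, featureless plane at z = 0 (mirrored at
#' z = L_z): a hard specularly reflecting barrier augmented by a soft,
#' short-range repulsion
#' \deqn{U_i(z) = (A_{s,i}/2)(1 - z)^2, \quad z < 1,}
#' the exact one-dimensional analog of the DPD pair force, with a
#' bead-specific amplitude \eqn{A_{s,i}} intended to capture the surface
#' chemistry. The range is fixed at one \eqn{r_c} for all species.
#'
#' Amplitudes may be given per bead species, or with the fluid-level
#' shorthands `water` (the `2H2O` bead) and `dodecane` (both alkane bead
#' types share one amplitude).
#'
#' @param amplitudes named numeric vector of repulsion amplitudes,
#'   e.g. `c(water = 10, dodecane = 30)` or
#'   `c("2H2O" = 10, CH2CH2 = 30, CH3 = 30)`
#' @param range soft-repulsion range in \eqn{r_c} (fixed at 1 in this
#'   model; exposed for completeness)
#' @return an object of class `dpd_walls`
#' @examples
#' dpd_walls(c(water = 10, dodecane = 30))
#' @export
dpd_walls <- function(amplitudes = numeric(0), range = 1) {
  stopifnot(range > 0, all(amplitudes >= 0))
  if (length(amplitudes) && is.null(names(amplitudes)))
    stop("wall amplitudes must be named by species or fluid")
  w <- list(amplitudes = amplitudes, range = range)
  class(w) <- "dpd_walls"
  w
}

#' @export
print.dpd_walls <- function(x, ...) {
  cat("Smooth walls at z = 0 and z = L_z, soft range", x$range, "r_c\n")
  if (length(x$amplitudes))
    print(x$amplitudes)
  else cat("  hard (specular) walls only, all amplitudes 0\n")
  invisible(x)
}

# expand fluid-level shorthands to a per-species amplitude vector,
# ordered like ff$species; unknown names are an error
wall_amplitude_vector <- function(walls, ff) {
  if (is.null(walls)) return(rep(0, length(ff$species)))
  amp <- walls$amplitudes
  out <- setNames(rep(0, length(ff$species)), ff$species)
  for (nm in names(amp)) {
    target <- switch(nm,
                     water = "2H2O",
                     dodecane = c("CH2CH2", "CH3"),
                     nm)
    if (!all(target %in% ff$species))
      stop("wall amplitude given for unknown species '", nm, "'")
    out[target] <- amp[[nm]]
  }
  unname(out)
}

#' Soft wall potential and normal force
#'
#' For a bead at height `z` above the wall: energy
#' \eqn{(A_s/2)(1 - z/range)^2 \cdot range} and outward normal force
#' \eqn{A_s (1 - z/range)} for `z < range`, zero beyond. At contact the
#' force equals the amplitude. Callers must fold the upper wall onto the
#' lower one (`z -> L_z - z`) first.
#'
#' @param z height(s) above the wall, >= 0
#' @param amplitude soft repulsion amplitude \eqn{A_s}
#' @param range soft-repulsion range (default 1)
#' @return list with vectors `energy` and `force`
#' @examples
#' wall_potential_force(0.5, 50)$force  # 25
#' @export
wall_potential_force <- function(z, amplitude, range = 1) {
  if (any(z < 0))
    stop("z < 0: apply the specular reflection before evaluating the wall")
  omz <- pmax(0, 1 - z / range)
  list(energy = 0.5 * amplitude * range * omz^2,
       force = amplitude * omz)
}

#' Specular reflection at the hard walls
#'
#' Mirrors beads that crossed z = 0 or z = L_z back into the slab and
#' flips the normal velocity component; in-plane components are untouched,
#' so kinetic energy and in-plane momentum are conserved exactly.
#'
#' @param position N x 3 matrix (or length-3 vector) after a drift step
#' @param velocity matching velocities
#' @param L_z wall separation
#' @return list with reflected `position` and `velocity`
#' @examples
#' apply_specular(c(1, 1, -0.1), c(0, 0, -2), 10)
#' @export
apply_specular <- function(position, velocity, L_z) {
  vec <- is.null(dim(position))
  p <- rbind(position)
  v <- rbind(velocity)
  below <- p[, 3] < 0
  above <- p[, 3] > L_z
  p[below, 3] <- -p[below, 3]
  p[above, 3] <- 2 * L_z - p[above, 3]
  flip <- below | above
  v[flip, 3] <- -v[flip, 3]
  if (any(p[, 3] < 0 | p[, 3] > L_z))
    stop("double wall crossing in one step: reduce the time step")
  if (vec) list(position = p[1, ], velocity = v[1, ])
  else list(position = p, velocity = v)
}

#' Wall-force contribution to the normal pressure
#'
#' The virial of the soft wall forces, \eqn{\sum_i f_{wall,z}(i) z_i' / V}
#' with \eqn{z_i'} the bead's distance from its interacting wall. It
#' enters only the zz component of the pressure tensor; with it included,
#' a confined equilibrium fluid satisfies mechanical equilibrium and the
#' surface-energy estimator mirrors the interfacial-tension formula. The
#' hard-wall reflections act exactly at the wall plane and therefore
#' contribute nothing.
#'
#' @param state a walled [dpd_state()]
#' @param walls a [dpd_walls()]
#' @param ff force field used to map species to amplitudes
#' @return the zz pressure contribution (reduced units)
#' @export
wall_virial <- function(state, walls, ff = default_forcefield()) {
  stopifnot(inherits(state, "dpd_state"))
  if (!state$walled) stop("wall_virial() requires a walled state")
  amp <- wall_amplitude_vector(walls, ff)[state$species]
  z <- state$positions[, 3]
  Lz <- state$box[3]
  lower <- wall_potential_force(z, amp, walls$range)
  upper <- wall_potential_force(Lz - z, amp, walls$range)
  sum(lower$force * z + upper$force * (Lz - z)) / prod(state$box)
}
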