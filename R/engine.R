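#' Run the DPD engine
#'
#' Integrates the DPD equations of motion with the Groot-Warren modified
#' velocity-Verlet scheme: soft conservative pair repulsions, bonded
#' terms, optional smooth walls, and the pairwise dissipative/random
#' thermostat with \eqn{w^D = (w^R)^2 = (1 - r/r_{cut})^2} acting inside a
#' single global cutoff (the largest pair range). The random-force noise
#' obeys the fluctuation-dissipation relation
#' \eqn{\sigma^2 = 2 \gamma k_B T} and is generated from a counter-based
#' hash keyed on (seed, step, pair), so trajectories are reproducible
#' regardless of pair ordering.
#'
#' The virial pressure tensor (conservative interactions plus the kinetic
#' term, with the wall-force contribution added to the zz component when
#' walled) is sampled every `sample_every` steps. With `barostat` set, an
#' isotropic Langevin piston drives the instantaneous pressure toward the
#' target; the piston acts on ln V with mass \eqn{3(N+1) T \tau_p^2}.
#'
#' @param state a [dpd_state()]
#' @param ff a [dpd_forcefield()]
#' @param steps number of time steps
#' @param dt time step (reduced units)
#' @param temperature reduced thermostat temperature
#' @param gamma dissipative friction amplitude (0 disables the thermostat)
#' @param lambda velocity-prediction parameter of the integrator
#' @param sample_every pressure-tensor sampling interval in steps
#'   (0 disables sampling)
#' @param walls optional [dpd_walls()]; requires `state$walled`
#' @param barostat optional list `list(pressure =, tau =, friction =,
#'   noise =)` for NPT runs (fully periodic states only); `tau` is the
#'   piston time constant in reduced time units
#' @param seed integer seed for the engine's random-force stream
#' @param trajectory_every if > 0, a snapshot of the state is kept every
#'   this many steps (in `$frames`)
#' @return an object of class `dpd_run`: the final `state`, a `samples`
#'   data frame (step, temperature, density, the six pressure-tensor
#'   components, box lengths and the wall zz term), optional `frames`,
#'   and bookkeeping fields
#' @examples
#' \donttest{
#' ff <- default_forcefield()
#' st <- build_confined(c(6, 6, 8), "water", density = 3, ff = ff, seed = 1)
#' run <- run_dpd(st, ff, steps = 200, seed = 1)
#' mean(run$samples$temperature)
#' }
#' @export
run_dpd <- function(state, ff, steps, dt = 0.02, temperature = 1,
                    gamma = 4.5, lambda = 0.5, sample_every = 50,
                    walls = NULL, barostat = NULL, seed = 1,
                    trajectory_every = 0) {
  stopifnot(inherits(state, "dpd_state"), inherits(ff, "dpd_forcefield"))
  if (!is.null(walls) && !state$walled)
    stop("walls were supplied for a fully periodic state")
  if (state$walled && is.null(walls)) walls <- dpd_walls()
  if (!is.null(barostat)) {
    if (state$walled) stop("the barostat cannot be combined with walls")
    barostat <- utils::modifyList(
      list(pressure = 23.7, tau = 2, friction = 1, noise = TRUE), barostat)
  }
  wallA <- if (state$walled) wall_amplitude_vector(walls, ff)
           else rep(0, length(ff$species))
  wall_range <- if (is.null(walls)) 1 else walls$range

  seg <- if (trajectory_every > 0) trajectory_every else steps
  frames <- if (trajectory_every > 0) vector("list",
                                             ceiling(steps / seg)) else NULL
  samples <- NULL
  pos <- state$positions
  vel <- state$velocities
  box <- state$box
  offset <- 0
  done <- 0
  k <- 0
  while (done < steps) {
    n_now <- min(seg, steps - done)
    out <- dpd_run_cpp(pos, vel, state$species - 1L, ff$A, ff$R,
                       state$bonds, state$angles, box, state$walled,
                       wallA, wall_range, dt, as.integer(n_now),
                       temperature, gamma, ff$max_cutoff, lambda,
                       as.integer(sample_every),
                       !is.null(barostat),
                       if (is.null(barostat)) 0 else barostat$pressure,
                       if (is.null(barostat)) 0 else barostat$tau,
                       if (is.null(barostat)) 0 else barostat$friction,
                       if (is.null(barostat)) FALSE else
                         isTRUE(barostat$noise),
                       seed, offset, angle_style_code(ff))
    pos <- out$positions
    vel <- out$velocities
    box <- out$box
    offset <- out$step_offset
    s <- out$samples
    if (nrow(s) > 0) {
      s[, 1] <- s[, 1] + done
      samples <- rbind(samples, s)
    }
    done <- done + n_now
    if (!is.null(frames)) {
      k <- k + 1
      frames[[k]] <- dpd_state(pos, state$species, box, velocities = vel,
                               species_names = state$species_names,
                               molecule = state$molecule,
                               bonds = state$bonds, angles = state$angles,
                               walled = state$walled)
    }
  }
  if (is.null(samples)) samples <- matrix(0, 0, 13)
  samples <- as.data.frame(samples)
  names(samples) <- c("step", "temperature", "density", "Pxx", "Pyy",
                      "Pzz", "Pxy", "Pxz", "Pyz", "Lx", "Ly", "Lz",
                      "wall_Pzz")
  final <- dpd_state(pos, state$species, box, velocities = vel,
                     species_names = state$species_names,
                     molecule = state$molecule, bonds = state$bonds,
                     angles = state$angles, walled = state$walled)
  run <- list(state = final, samples = samples, frames = frames,
              wall_included = state$walled, walls = walls,
              params = list(dt = dt, temperature = temperature,
                            gamma = gamma, lambda = lambda, seed = seed,
                            steps = steps, sample_every = sample_every,
                            barostat = barostat))
  class(run) <- "dpd_run"
  run
}

#' @export
print.dpd_run <- function(x, ...) {
  cat(sprintf("DPD run: %d steps, %d beads, %d samples\n",
              x$params$steps, nrow(x$state$positions), nrow(x$samples)))
  if (nrow(x$samples) > 0) {
    s <- tail(x$samples, max(1, nrow(x$samples) %/% 2))
    cat(sprintf("  <T> = %.4f  <P> = %.4f  <rho> = %.4f (second half)\n",
                mean(s$temperature), mean((s$Pxx + s$Pyy + s$Pzz) / 3),
                mean(s$density)))
  }
  invisible(x)
}

#' NVT production run
#'
#' Thin wrapper around [run_dpd()] without a barostat.
#' @inheritParams run_dpd
#' @param ... forwarded to [run_dpd()]
#' @return a `dpd_run`
#' @export
run_nvt <- function(state, ff, steps, ...) run_dpd(state, ff, steps, ...)

#' NPT run under the Langevin-piston barostat
#'
#' Fully periodic boundaries only. The box is scaled isotropically; the
#' returned run's `samples$density` is the reduced-density trace used to
#' read off the equilibrium density at the target pressure.
#'
#' @inheritParams run_dpd
#' @param pressure target reduced pressure
#' @param tau piston time constant (reduced time units)
#' @param friction piston friction (per reduced time)
#' @param noise logical: include the piston's thermal noise
#' @param ... forwarded to [run_dpd()]
#' @return a `dpd_run`
#' @export
run_npt <- function(state, ff, steps, pressure = 23.7, tau = 2,
                    friction = 1, noise = TRUE, ...) {
  run_dpd(state, ff, steps,
          barostat = list(pressure = pressure, tau = tau,
                          friction = friction, noise = noise), ...)
}

#' Instantaneous pressure tensor of a configuration
#'
#' Evaluates \eqn{P_{ab} = (\sum_i m v_a v_b + \sum f_a r_b)/V} over the
#' kinetic term and the conservative (pair, bonded and wall) forces; the
#' wall-force virial enters only the zz component. In bulk equilibrium the
#' three diagonal components agree.
#'
#' @param state a [dpd_state()]
#' @param ff a [dpd_forcefield()]
#' @param walls optional [dpd_walls()] for walled states
#' @return 3x3 pressure tensor (reduced units) with attributes
#'   `wall_Pzz` (the wall term) and `energy` (potential-energy breakdown)
#' @export
pressure_tensor <- function(state, ff, walls = NULL) {
  stopifnot(inherits(state, "dpd_state"))
  if (state$walled && is.null(walls)) walls <- dpd_walls()
  wallA <- if (state$walled) wall_amplitude_vector(walls, ff)
           else rep(0, length(ff$species))
  ev <- dpd_eval_cpp(state$positions, state$velocities, state$species - 1L,
                     ff$A, ff$R, state$bonds, state$angles, state$box,
                     state$walled, wallA,
                     if (is.null(walls)) 1 else walls$range,
                     ff$max_cutoff, angle_style_code(ff))
  P <- ev$pressure
  dimnames(P) <- list(c("x", "y", "z"), c("x", "y", "z"))
  attr(P, "wall_Pzz") <- ev$wall_pzz
  attr(P, "energy") <- ev$energy
  P
}

# conservative forces + energy breakdown for a configuration (internal,
# used by the force-consistency tests)
eval_forces <- function(state, ff, walls = NULL) {
  if (state$walled && is.null(walls)) walls <- dpd_walls()
  wallA <- if (state$walled) wall_amplitude_vector(walls, ff)
           else rep(0, length(ff$species))
  dpd_eval_cpp(state$positions, state$velocities, state$species - 1L,
               ff$A, ff$R, state$bonds, state$angles, state$box,
               state$walled, wallA,
               if (is.null(walls)) 1 else walls$range, ff$max_cutoff,
               angle_style_code(ff))
}

angle_style_code <- function(ff) {
  if (identical(ff$angle_style, "harmonic")) 0L else 1L
}
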