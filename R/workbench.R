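#' Build a two-phase slab for interfacial-tension measurements
#'
#' Places the two fluids in either half of a fully periodic box with
#' *equal bead numbers* per phase, each phase at its own starting reduced
#' density, so the two regions occupy slightly different volumes. The
#' defaults are the equilibrium densities of the bundled model at the
#' operating pressure 23.7 (water 3.0, dodecane 3.27), which makes a
#' plain NVT run start at mechanical equilibrium — the analytic
#' equivalent of the NPT pre-equilibration used in the reference
#' protocol. Bead counts are rounded to whole molecules. Under periodic
#' boundaries the slab has two interfaces normal to z.
#'
#' @param box lengths `c(Lx, Ly, Lz)`
#' @param ff a [dpd_forcefield()]
#' @param species_a,species_b fluid names (molecule templates or bead
#'   species); phase a fills the lower region
#' @param density_a,density_b starting reduced bead density per phase
#' @param seed optional RNG seed for the placement
#' @return a fully periodic [dpd_state()]
#' @examples
#' ff <- default_forcefield()
#' st <- build_slab(c(6, 6, 12), ff, seed = 1)
#' @export
build_slab <- function(box, ff, species_a = "water",
                       species_b = "dodecane", density_a = 3,
                       density_b = 3.27, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ta <- fluid_template(ff, species_a)
  tb <- fluid_template(ff, species_b)
  # equal bead numbers; volumes in inverse proportion to the densities
  half_beads <- prod(box) * density_a * density_b / (density_a + density_b)
  na <- round(half_beads / length(ta$species))
  nb <- round(half_beads / length(tb$species))
  if (na < 1 || nb < 1) stop("box too small for one molecule per phase")
  z_split <- box[3] * density_b / (density_a + density_b)
  blocks <- list(
    place_molecules(ta, na, c(0, 0, 0), c(box[1], box[2], z_split),
                    ff$species),
    place_molecules(tb, nb, c(0, 0, z_split),
                    c(box[1], box[2], box[3] - z_split), ff$species))
  assemble_state(blocks, box, ff$species, walled = FALSE)
}

#' Build a pure fluid confined between the walls
#'
#' Random rejection-free placement of whole molecules at the target
#' density in a box that is periodic in x and y and bounded by the hard
#' specular walls at z = 0 and z = L_z (the soft wall amplitudes are
#' chosen at run time through [dpd_walls()]).
#'
#' @param box lengths `c(Lx, Ly, Lz)`
#' @param fluid fluid name (molecule template or bead species)
#' @param density target reduced bead density
#' @param ff a [dpd_forcefield()]
#' @param seed optional RNG seed for the placement
#' @return a walled [dpd_state()]
#' @examples
#' ff <- default_forcefield()
#' st <- build_confined(c(6, 6, 10), "dodecane", density = 3.27, ff = ff,
#'                      seed = 1)
#' nrow(st$positions) %% 7  # whole 7-mers only
#' @export
build_confined <- function(box, fluid, density = 3,
                           ff = default_forcefield(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  tmpl <- fluid_template(ff, fluid)
  n_mol <- round(density * prod(box) / length(tmpl$species))
  if (n_mol < 1) stop("box too small for one molecule")
  block <- place_molecules(tmpl, n_mol, c(0, 0, 0), box, ff$species)
  assemble_state(list(block), box, ff$species, walled = TRUE)
}

#' Scripted reproduction of the wetting experiments
#'
#' Runs one of the named measurement protocols at a geometric/temporal
#' scale factor and reports the measured values next to the bundled
#' reference values where applicable. `scale = 1` corresponds to the
#' desk-scale defaults documented in the methods vignette (boxes with
#' L_z = 40 and a few times 10^4 steps); `scale = 0` only validates the
#' configuration and returns an empty report.
#'
#' @param name one of `"tension"`, `"surface-energy-scan"`,
#'   `"droplet-validation"`, `"sam-parametrization"`
#' @param scale non-negative scale factor applied to the run lengths
#' @param seed integer seed
#' @param amplitudes wall amplitudes for the surface-energy scan
#' @param ff force field
#' @return a data frame report with one row per measured quantity; the
#'   MD5 content hash of the force-field table used is attached as the
#'   `forcefield_hash` attribute so reports are traceable to their
#'   parameters
#' @export
reproduce_experiment <- function(name = c("tension", "surface-energy-scan",
                                          "droplet-validation",
                                          "sam-parametrization"),
                                 scale = 1, seed = 1,
                                 amplitudes = seq(0, 50, by = 10),
                                 ff = default_forcefield()) {
  name <- match.arg(name)
  stopifnot(scale >= 0)
  ref <- reference_wetting_data()
  stamp <- function(report) {
    attr(report, "forcefield_hash") <- forcefield_hash(ff)
    report
  }
  empty <- stamp(data.frame(quantity = character(), value = numeric(),
                            se = numeric(), reference = numeric()))
  if (name == "tension") {
    if (scale == 0) {
      build_slab(c(10, 10, 40), ff, seed = seed)
      return(empty)
    }
    st <- build_slab(c(10, 10, 40), ff, seed = seed)
    run <- run_dpd(st, ff, steps = round(24000 * scale), seed = seed)
    g <- interfacial_tension(run)
    return(stamp(data.frame(quantity = "gamma_12 [mN/m]", value = g$mN_m,
                            se = g$se_mN_m, reference = ref$gamma_12)))
  }
  if (name == "surface-energy-scan") {
    if (scale == 0) {
      build_confined(c(8, 8, 20), "water", 3, ff, seed = seed)
      return(empty)
    }
    rows <- list()
    for (fluid in c("water", "dodecane")) {
      dens <- if (fluid == "water") 3 else 3.27
      refcol <- ref$surface_energies[[fluid]]
      for (i in seq_along(amplitudes)) {
        st <- build_confined(c(8, 8, 20), fluid, dens, ff,
                             seed = seed + i)
        w <- dpd_walls(setNames(amplitudes[i], fluid))
        run <- run_dpd(st, ff, steps = round(16000 * scale), walls = w,
                       seed = seed + i)
        g <- surface_energy(run)
        refv <- refcol[match(amplitudes[i], ref$surface_energies$A_s)]
        rows[[length(rows) + 1]] <-
          data.frame(quantity = sprintf("gamma_s,%s(A_s=%g) [mN/m]",
                                        fluid, amplitudes[i]),
                     value = g$mN_m, se = g$se_mN_m, reference = refv)
      }
    }
    return(stamp(do.call(rbind, rows)))
  }
  if (name == "droplet-validation") {
    if (scale == 0) {
      build_droplet_config(c(30, 8, 16), c(8, 8, 8), ff)
      return(empty)
    }
    # one reduced cylindrical droplet compared with the Young prediction
    amps <- c(water = 40, dodecane = 30)
    st <- build_droplet_config(c(30, 8, 16), c(8, 8, 8), ff)
    w <- dpd_walls(amps)
    equil <- run_dpd(st, ff, steps = round(20000 * scale), walls = w,
                     seed = seed, sample_every = 0)
    prod <- run_dpd(equil$state, ff, steps = round(20000 * scale),
                    walls = w, seed = seed + 1, sample_every = 0,
                    trajectory_every = 1000)
    ang <- measure_contact_angle(prod$frames, species = "dodecane",
                                 delta_h = 2)
    se_tab <- ref$surface_energies
    young <- young_angle(ref$gamma_12,
                         se_tab$water[se_tab$A_s == amps[["water"]]],
                         se_tab$dodecane[se_tab$A_s == amps[["dodecane"]]])
    return(stamp(data.frame(quantity = "theta(A_wat=40, A_dod=30) [deg]",
                            value = ang$theta_deg, se = NA_real_,
                            reference = young)))
  }
  # sam-parametrization: pure analysis on the bundled tables
  if (scale == 0) return(empty)
  fit <- fit_gamma_cubic(ref$surface_energies$A_s,
                         ref$surface_energies$water)
  g_dod <- ref$surface_energies$dodecane[ref$surface_energies$A_s == 30]
  rows <- lapply(seq_len(nrow(ref$sam)), function(i) {
    inv <- invert_for_amplitude(ref$sam$theta_exp[i], g_dod, fit,
                                ref$gamma_12, free_side = "droplet")
    data.frame(quantity = sprintf("A_s,wat(theta=%g deg)",
                                  ref$sam$theta_exp[i]),
               value = inv$amplitude, se = NA_real_,
               reference = ref$sam$A_s_wat[i])
  })
  stamp(do.call(rbind, rows))
}

# MD5 content hash of the force field's on-disk pair-table representation
forcefield_hash <- function(ff) {
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path))
  write_forcefield(ff, path)
  unname(tools::md5sum(path))
}
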