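#' Block average of a time series
#'
#' Splits the series into `n_blocks` contiguous blocks; the estimate is
#' the mean of the block means and the error is their standard deviation
#' divided by \eqn{\sqrt{n_{blocks}}}, which absorbs short-range
#' autocorrelation between successive samples.
#'
#' @param x numeric series
#' @param n_blocks number of blocks (>= 2 for a defined error)
#' @return list with `mean`, `se` and `n_blocks`
#' @export
block_average <- function(x, n_blocks = 10) {
  stopifnot(length(x) >= n_blocks, n_blocks >= 1)
  if (n_blocks < 2)
    return(list(mean = mean(x), se = NA_real_, n_blocks = 1L))
  idx <- floor(seq_along(x) * n_blocks / (length(x) + 1e-9)) + 1
  bm <- tapply(x, idx, mean)
  list(mean = mean(bm), se = stats::sd(bm) / sqrt(n_blocks),
       n_blocks = as.integer(n_blocks))
}

# shared pressure-anisotropy estimator behind the tension and
# surface-energy front ends
tension_from_samples <- function(samples, discard, n_blocks, units) {
  stopifnot(nrow(samples) >= 2 * n_blocks)
  drop <- floor(nrow(samples) * discard)
  keep <- if (drop > 0) samples[-seq_len(drop), , drop = FALSE] else samples
  g <- keep$Lz / 2 * (keep$Pzz - (keep$Pxx + keep$Pyy) / 2)
  ba <- block_average(g, n_blocks)
  aniso <- block_average(keep$Pxx - keep$Pyy, n_blocks)
  if (is.finite(aniso$se) && aniso$se > 0 &&
      abs(aniso$mean) > 3 * aniso$se)
    warning("in-plane pressure anisotropy exceeds 3 standard errors; ",
            "check the slab geometry")
  out <- list(reduced = ba$mean, se_reduced = ba$se,
              mN_m = tension_to_real(ba$mean, units),
              se_mN_m = tension_to_real(ba$se, units),
              n_blocks = ba$n_blocks, n_samples = nrow(keep))
  class(out) <- "dpd_tension"
  out
}

#' @export
print.dpd_tension <- function(x, ...) {
  cat(sprintf("%.3f +/- %.3f reduced  (%.2f +/- %.2f mN/m, %d samples, %d blocks)\n",
              x$reduced, x$se_reduced, x$mN_m, x$se_mN_m,
              x$n_samples, x$n_blocks))
  invisible(x)
}

#' Interfacial tension from the pressure-tensor anisotropy
#'
#' For a two-phase slab with both interfaces normal to z under full
#' periodic boundaries,
#' \deqn{\gamma_{12} = \frac{L_z}{2}\left[\langle P_{zz}\rangle -
#'   \tfrac12(\langle P_{xx}\rangle + \langle P_{yy}\rangle)\right],}
#' the factor 2 accounting for the two interfaces. The quantity is
#' evaluated per sample and block-averaged; a warning is raised when
#' \eqn{P_{xx}} and \eqn{P_{yy}} disagree beyond error, which indicates a
#' geometry problem. For a liquid/liquid interface the result must be
#' non-negative within error.
#'
#' @param run a [run_dpd()] result for a fully periodic slab
#' @param discard fraction of initial samples dropped as equilibration
#' @param n_blocks blocks for the error estimate
#' @param units a [dpd_units()] for the mN/m conversion
#' @return a `dpd_tension`: reduced and mN/m values with standard errors
#' @export
interfacial_tension <- function(run, discard = 0.2, n_blocks = 10,
                                units = dpd_units()) {
  stopifnot(inherits(run, "dpd_run"))
  if (isTRUE(run$wall_included))
    stop("walled run supplied: use surface_energy() for wall geometries")
  tension_from_samples(run$samples, discard, n_blocks, units)
}

#' Wall surface energy from the augmented pressure tensor
#'
#' Same estimator as [interfacial_tension()] (two walls take the place of
#' the two interfaces), applied to a pure fluid confined between the
#' walls, with the wall-force virial included in \eqn{P_{zz}}. Unlike a
#' liquid/liquid tension the result can be positive *or negative*: a
#' bare hard wall piles beads up against it, raising the lateral pressure
#' locally and driving the surface energy negative.
#'
#' @param run a [run_dpd()] result for a walled geometry; the engine
#'   includes the wall virial automatically for walled states, and this
#'   function refuses runs where it is absent since silently omitting it
#'   corrupts the estimate
#' @inheritParams interfacial_tension
#' @return a `dpd_tension`
#' @export
surface_energy <- function(run, discard = 0.2, n_blocks = 10,
                           units = dpd_units()) {
  stopifnot(inherits(run, "dpd_run"))
  if (!isTRUE(run$wall_included))
    stop("surface_energy() requires a walled run with the wall-force ",
         "virial included in the P_zz samples")
  tension_from_samples(run$samples, discard, n_blocks, units)
}

#' One-dimensional density profile
#'
#' Bins beads along an axis and averages the per-bin number density over
#' the supplied frames (or the single state). The profile integrates to
#' the bead count divided by the cross-sectional area.
#'
#' @param x a [dpd_state()], a [run_dpd()] result (its frames if stored,
#'   else the final state), or a list of states
#' @param species optional species selector: a species name, or the
#'   shorthands `"water"`/`"dodecane"`
#' @param axis one of "x", "y", "z"
#' @param bin_width bin width in reduced units
#' @return data frame with bin midpoints `mid` and reduced number
#'   `density`
#' @export
density_profile <- function(x, species = NULL, axis = "z",
                            bin_width = 0.25) {
  stopifnot(bin_width > 0)
  frames <- as_frames(x)
  ax <- match(match.arg(axis, c("x", "y", "z")), c("x", "y", "z"))
  L <- frames[[1]]$box[ax]
  area <- prod(frames[[1]]$box[-ax])
  edges <- seq(0, L, by = bin_width)
  if (edges[length(edges)] < L) edges <- c(edges, L)
  counts <- 0
  for (fr in frames) {
    sel <- species_selector(fr, species)
    v <- fr$positions[sel, ax]
    counts <- counts + tabulate(findInterval(v, edges,
                                             rightmost.closed = TRUE),
                                nbins = length(edges) - 1)
  }
  widths <- diff(edges)
  data.frame(mid = edges[-length(edges)] + widths / 2,
             density = counts / (length(frames) * area * widths))
}

# normalize the various trajectory containers to a list of states
as_frames <- function(x) {
  if (inherits(x, "dpd_state")) return(list(x))
  if (inherits(x, "dpd_run")) {
    if (!is.null(x$frames)) return(x$frames)
    return(list(x$state))
  }
  if (is.list(x) && length(x) && inherits(x[[1]], "dpd_state")) return(x)
  stop("cannot interpret input as a state, run, or list of frames")
}

# logical bead selector for a species name or fluid shorthand
species_selector <- function(state, species) {
  if (is.null(species)) return(rep(TRUE, length(state$species)))
  target <- unlist(lapply(species, function(nm)
    switch(nm,
           water = "2H2O",
           dodecane = c("CH2CH2", "CH3"),
           nm)))
  target <- intersect(target, state$species_names)
  if (!length(target))
    target <- intersect(species, state$species_names)
  if (!length(target))
    stop("species '", paste(species, collapse = ","),
         "' not present in the state")
  state$species %in% match(target, state$species_names)
}
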