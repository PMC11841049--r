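#' Build a cylindrical-droplet starting configuration
#'
#' Dodecane molecules are placed at their liquid reduced density inside a
#' rectangular parallelepiped sitting on the z = 0 wall, centered in x and
#' spanning y; the rest of the box is filled with water beads at the water
#' density. During equilibration the slab relaxes into a cylindrical cap
#' whose axis runs along y.
#'
#' @param box lengths `c(Lx, Ly, Lz)` of the walled box
#' @param slab lengths `c(lx, ly, lz)` of the initial droplet region;
#'   `ly` is capped at `Ly` (the droplet spans y)
#' @param ff a [dpd_forcefield()]
#' @param droplet,bath fluid names
#' @param droplet_density,bath_density reduced bead densities
#' @param seed optional RNG seed
#' @return a walled [dpd_state()]
#' @export
build_droplet_config <- function(box, slab, ff = default_forcefield(),
                                 droplet = "dodecane", bath = "water",
                                 droplet_density = 3.27, bath_density = 3,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  slab[2] <- min(slab[2], box[2])
  if (slab[1] > box[1] || slab[3] > box[3])
    stop("droplet region does not fit inside the box")
  v_slab <- prod(slab)
  td <- fluid_template(ff, droplet)
  tb <- fluid_template(ff, bath)
  n_drop <- round(droplet_density * v_slab / length(td$species))
  n_bath <- round(bath_density * (prod(box) - v_slab) /
                    length(tb$species))
  origin <- c((box[1] - slab[1]) / 2, 0, 0)
  blocks <- list(place_molecules(td, n_drop, origin, slab, ff$species))
  if (n_bath > 0) {
    # rejection-sample bath beads outside the droplet region
    bath_block <- place_molecules(tb, n_bath, c(0, 0, 0), box, ff$species)
    p <- bath_block$positions
    inside <- p[, 1] > origin[1] & p[, 1] < origin[1] + slab[1] &
      p[, 3] < slab[3]
    while (any(inside)) {
      k <- sum(inside)
      p[inside, ] <- cbind(runif(k, 0, box[1]), runif(k, 0, box[2]),
                           runif(k, 0, box[3]))
      inside <- p[, 1] > origin[1] & p[, 1] < origin[1] + slab[1] &
        p[, 3] < slab[3]
    }
    bath_block$positions <- p
    blocks <- c(blocks, list(bath_block))
  }
  assemble_state(blocks, box, ff$species, walled = TRUE)
}

# cylindrical-cell local densities on an (x, z) grid, averaged along y.
# Counts are normalized by the part of the sampling disc above the wall,
# so near-wall cells are unbiased. Returns the density matrix plus grid
# metadata.
cap_density_grid <- function(frames, species, r_cell, dx, dz) {
  box <- frames[[1]]$box
  nx <- max(8L, round(box[1] / dx))
  dxe <- box[1] / nx  # tile the periodic x direction exactly
  zmax <- max(vapply(frames, function(fr)
    max(fr$positions[species_selector(fr, species), 3]), 0)) + r_cell
  mz <- ceiling(r_cell / dz)
  nz <- min(ceiling(zmax / dz) + mz, floor(box[3] / dz))
  mx <- ceiling(r_cell / dxe)
  off <- expand.grid(ox = -mx:mx, oz = -mz:mz)
  off <- off[(off$ox * dxe)^2 + (off$oz * dz)^2 <= r_cell^2, ]
  # offsets reaching beyond either wall are excluded row by row, so the
  # accessible sampling area is normalized correctly at both slab faces
  nz_wall <- floor(box[3] / dz)
  norm_per_row <- vapply(seq_len(nz), function(i)
    sum(i + off$oz >= 1 & i + off$oz <= nz_wall), 0L)
  cell_area <- dxe * dz
  dens <- vector("list", length(frames))
  for (f in seq_along(frames)) {
    fr <- frames[[f]]
    sel <- species_selector(fr, species)
    px <- fr$positions[sel, 1]
    pz <- fr$positions[sel, 3]
    ix <- (floor(px / dxe) %% nx) + 1
    iz <- floor(pz / dz) + 1
    keep <- iz >= 1 & iz <= nz
    C <- matrix(0, nx, nz)
    tab <- table(factor(ix[keep], levels = 1:nx),
                 factor(iz[keep], levels = 1:nz))
    C[] <- as.numeric(tab)
    D <- matrix(0, nx, nz)
    for (k in seq_len(nrow(off))) {
      ox <- off$ox[k]; oz <- off$oz[k]
      src_x <- ((seq_len(nx) - 1 + ox) %% nx) + 1
      cols <- which(seq_len(nz) + oz >= 1 & seq_len(nz) + oz <= nz)
      D[, cols] <- D[, cols] + C[src_x, cols + oz, drop = FALSE]
    }
    dens[[f]] <- sweep(D, 2, norm_per_row * cell_area * box[2], "/")
  }
  list(density = dens, nx = nx, nz = nz, dx = dxe, dz = dz,
       x_mid = (seq_len(nx) - 0.5) * dxe, z_mid = (seq_len(nz) - 0.5) * dz)
}

# first sub-threshold crossing left/right of the center column, one row
scan_row <- function(row, k_com, thresh) {
  if (row[k_com] < thresh) return(c(NA_integer_, NA_integer_))
  right <- which(row < thresh & seq_along(row) > k_com)
  left <- which(row < thresh & seq_along(row) < k_com)
  c(if (length(left)) max(left) else NA_integer_,
    if (length(right)) min(right) else NA_integer_)
}

#' Extract the droplet boundary from trajectory frames
#'
#' Implements the density-grid boundary detection for a cylindrical
#' droplet lying along y on the z = 0 wall. The droplet center of mass is
#' located in the xz plane (x through a circular mean, so a droplet
#' straddling the periodic boundary is handled); the reference density
#' \eqn{\rho_{ref}} is measured in a y-aligned cylindrical cell of radius
#' `r_cell` at the center of mass. Local densities are sampled on a
#' (`dx`, `dz`) grid from the wall to above the apex; for each height the
#' first cells left and right of the center with
#' \eqn{\rho/\rho_{ref} < 0.5} become boundary points. Points whose
#' relative error across frames (standard error of the per-frame boundary
#' position over the distance from the center) is `max_rel_error` or more
#' are flagged and excluded from the circle fit; near the apex the
#' density fluctuations make this filter bite.
#'
#' @param x frames: a [run_dpd()] result with stored frames, a list of
#'   states, or a single state
#' @param species droplet species selector (e.g. `"dodecane"`)
#' @param r_cell sampling-cell radius (reduced units)
#' @param dx,dz grid spacings
#' @param max_rel_error relative-error cutoff for retaining points
#' @return an object of class `droplet_profile`: data frame `points`
#'   (columns x, z, side, rel_error, keep), `rho_ref`, the `com`, and the
#'   grid parameters
#' @export
extract_boundary <- function(x, species = "dodecane", r_cell = 1.5,
                             dx = 0.2, dz = 0.2, max_rel_error = 0.1) {
  frames <- as_frames(x)
  box <- frames[[1]]$box
  # center of mass over all frames (circular mean in periodic x)
  px <- unlist(lapply(frames, function(fr)
    fr$positions[species_selector(fr, species), 1]))
  pz <- unlist(lapply(frames, function(fr)
    fr$positions[species_selector(fr, species), 3]))
  if (!length(px)) stop("no droplet beads found")
  ang <- 2 * pi * px / box[1]
  x_com <- (atan2(mean(sin(ang)), mean(cos(ang))) / (2 * pi)) %% 1 * box[1]
  z_com <- mean(pz)

  g <- cap_density_grid(frames, species, r_cell, dx, dz)
  k_com <- pmin(g$nx, floor(x_com / g$dx) + 1)
  i_com <- max(1L, min(g$nz, floor(z_com / g$dz) + 1))
  mean_d <- Reduce(`+`, g$density) / length(g$density)
  rho_ref <- mean_d[k_com, i_com]
  if (!is.finite(rho_ref) || rho_ref <= 0)
    stop("degenerate droplet: reference density is zero")
  thresh <- 0.5 * rho_ref

  rows <- t(apply(mean_d, 2, scan_row, k_com = k_com, thresh = thresh))
  per_frame <- lapply(g$density, function(D)
    t(apply(D, 2, scan_row, k_com = k_com, thresh = thresh)))
  pts <- NULL
  for (side in 1:2) {
    idx <- which(!is.na(rows[, side]))
    if (!length(idx)) next
    xb <- g$x_mid[rows[idx, side]]
    fb <- vapply(per_frame, function(m) {
      out <- rep(NA_real_, length(idx))
      ok <- !is.na(m[idx, side])
      out[ok] <- g$x_mid[m[idx[ok], side]]
      out
    }, numeric(length(idx)))
    fb <- matrix(fb, nrow = length(idx))
    se <- apply(fb, 1, function(v) {
      v <- v[!is.na(v)]
      if (length(v) < 2) return(Inf)
      stats::sd(v) / sqrt(length(v))
    })
    rel <- se / pmax(abs(xb - x_com), 1e-9)
    pts <- rbind(pts, data.frame(
      x = xb, z = g$z_mid[idx],
      side = if (side == 1) "left" else "right",
      rel_error = rel, keep = rel < max_rel_error))
  }
  if (is.null(pts) || !nrow(pts))
    stop("no boundary detected: droplet may fill the box or be empty")
  out <- list(points = pts, rho_ref = rho_ref, com = c(x = x_com, z = z_com),
              n_frames = length(frames),
              params = list(r_cell = r_cell, dx = g$dx, dz = dz,
                            max_rel_error = max_rel_error))
  class(out) <- "droplet_profile"
  out
}

#' @export
print.droplet_profile <- function(x, ...) {
  cat(sprintf(
    "Droplet profile: %d boundary points (%d kept), rho_ref = %.3f\n",
    nrow(x$points), sum(x$points$keep), x$rho_ref))
  cat(sprintf("  CoM at x = %.2f, z = %.2f (%d frames)\n",
              x$com[1], x$com[2], x$n_frames))
  invisible(x)
}

#' Algebraic least-squares circle fit
#'
#' Fits a circle to boundary points by the algebraic (modified
#' least-squares) method: minimizing
#' \eqn{\sum_i (x_i^2 + z_i^2 - 2 a x_i - 2 b z_i - c)^2} is a linear
#' problem whose solution gives the center (a, b) and radius
#' \eqn{\sqrt{c + a^2 + b^2}}. The fit is exact on noiseless circular
#' data; collinear points have no circle and raise an error.
#'
#' @param x a `droplet_profile` (kept points are used) or a data
#'   frame/matrix with columns x and z
#' @return an object of class `circle_fit` with `radius` and
#'   `center = c(x, z)`
#' @examples
#' th <- seq(0, 2 * pi, length.out = 20)
#' fit_circle(data.frame(x = 10 * cos(th), z = 5 + 10 * sin(th)))
#' @export
fit_circle <- function(x) {
  if (inherits(x, "droplet_profile")) x <- x$points[x$points$keep, ]
  x <- as.data.frame(x)
  if (is.null(x$x) || is.null(x$z)) {
    names(x)[1:2] <- c("x", "z")
  }
  if (nrow(x) < 3) stop("circle fit requires at least 3 points")
  B <- cbind(2 * x$x, 2 * x$z, 1)
  y <- x$x^2 + x$z^2
  sol <- tryCatch(qr.solve(B, y), error = function(e)
    stop("no circle: boundary points are collinear or degenerate"))
  r2 <- sol[3] + sol[1]^2 + sol[2]^2
  if (!is.finite(r2) || r2 <= 0)
    stop("no circle: boundary points are collinear or degenerate")
  out <- list(radius = sqrt(r2),
              center = c(x = unname(sol[1]), z = unname(sol[2])),
              n_points = nrow(x))
  class(out) <- "circle_fit"
  out
}

#' @export
print.circle_fit <- function(x, ...) {
  cat(sprintf("Circle fit: R = %.4f, center (%.4f, %.4f), %d points\n",
              x$radius, x$center[1], x$center[2], x$n_points))
  invisible(x)
}

#' Contact angle from the fitted circle
#'
#' The droplet profile circle is intersected with the interface plane at
#' height `delta_h` above the wall:
#' \deqn{\cos\theta_{sim}(R) = (\delta h - z_c)/R,}
#' with the angle measured through the droplet phase, so a center above
#' the interface plane gives \eqn{\theta > 90^\circ} (non-wetting bulge)
#' and a center below gives \eqn{\theta < 90^\circ}. The tangency limits
#' \eqn{z_c = \delta h \mp R} map to 0 and 180 degrees.
#'
#' @param fit a [fit_circle()] result
#' @param delta_h interface position above the wall (reduced units)
#' @return an object of class `contact_angle` with `radius`, `cos_theta`
#'   and `theta_deg`
#' @export
contact_angle <- function(fit, delta_h = 2) {
  stopifnot(inherits(fit, "circle_fit"))
  ct <- (delta_h - fit$center["z"]) / fit$radius
  if (abs(ct) > 1)
    stop("circle does not intersect the plane z = ", delta_h)
  out <- list(radius = fit$radius, cos_theta = unname(ct),
              theta_deg = unname(acos(ct) * 180 / pi),
              delta_h = delta_h)
  class(out) <- "contact_angle"
  out
}

#' @export
print.contact_angle <- function(x, ...) {
  cat(sprintf("theta_sim(R = %.3f) = %.2f deg (cos = %.4f, delta_h = %g)\n",
              x$radius, x$theta_deg, x$cos_theta, x$delta_h))
  invisible(x)
}

#' Extrapolate the contact angle to the macroscopic radius
#'
#' \eqn{\cos\theta_{sim}(R)} is linear in 1/R for droplets of a common
#' macroscopic angle, so an ordinary least-squares line through the
#' per-box values extrapolated to \eqn{1/R \to 0} gives
#' \eqn{\theta_{sim}(R \to \infty)}. The intercept is also where the
#' dependence on the interface position `delta_h` drops out.
#'
#' @param x a data frame with columns `radius` and `cos_theta`, or a list
#'   of [contact_angle()] results
#' @return list with `theta_deg`, `cos_intercept`, `slope` and `n`; with
#'   a single radius the value is returned as-is with `extrapolated =
#'   FALSE`
#' @export
extrapolate_angle <- function(x) {
  if (is.list(x) && length(x) && inherits(x[[1]], "contact_angle"))
    x <- data.frame(radius = vapply(x, `[[`, 0, "radius"),
                    cos_theta = vapply(x, `[[`, 0, "cos_theta"))
  x <- as.data.frame(x)
  stopifnot(all(c("radius", "cos_theta") %in% names(x)), nrow(x) >= 1)
  if (length(unique(x$radius)) < 2) {
    return(list(theta_deg = acos(max(-1, min(1, x$cos_theta[1]))) * 180 / pi,
                cos_intercept = x$cos_theta[1], slope = NA_real_,
                n = nrow(x), extrapolated = FALSE))
  }
  fit <- lm(cos_theta ~ I(1 / radius), data = x)
  c0 <- max(-1, min(1, unname(coef(fit)[1])))
  list(theta_deg = acos(c0) * 180 / pi, cos_intercept = c0,
       slope = unname(coef(fit)[2]), n = nrow(x), extrapolated = TRUE)
}

#' Contact angle of one droplet trajectory
#'
#' Convenience pipeline: [extract_boundary()] then [fit_circle()] then
#' [contact_angle()].
#'
#' @inheritParams extract_boundary
#' @param delta_h interface position passed to [contact_angle()]
#' @return a [contact_angle()] result with the profile and fit attached
#'   as attributes
#' @export
measure_contact_angle <- function(x, species = "dodecane", delta_h = 2,
                                  r_cell = 1.5, dx = 0.2, dz = 0.2,
                                  max_rel_error = 0.1) {
  prof <- extract_boundary(x, species, r_cell, dx, dz, max_rel_error)
  fit <- fit_circle(prof)
  ang <- contact_angle(fit, delta_h)
  attr(ang, "profile") <- prof
  attr(ang, "fit") <- fit
  ang
}

#' Synthetic cylindrical-cap density frames
#'
#' Generates bead frames for an ideal cylindrical cap of prescribed
#' contact angle: a circle of radius `radius` whose angle measured at
#' height `contact_height` equals `theta_deg`, filled uniformly with
#' beads at the given density along a periodic y axis. Frames are
#' independent draws, so frame-to-frame scatter mimics (uncorrelated)
#' thermal noise. These fields exercise the full droplet-analysis stack
#' against known geometry; they deliberately lack the interface
#' smearing, layering near the wall and correlated fluctuations of a
#' real trajectory.
#'
#' @param theta_deg prescribed contact angle in degrees (0, 180)
#' @param radius circle radius (reduced units)
#' @param contact_height height at which the angle is prescribed; use the
#'   `delta_h` you will analyze with, or 0 for the wall plane
#' @param density reduced bead density of the cap
#' @param ly box length along the cylinder axis
#' @param n_frames number of independent frames
#' @param seed optional RNG seed
#' @return list of walled [dpd_state()] frames with a single species
#'   named `"dodecane"`
#' @export
synthetic_cap_frames <- function(theta_deg, radius, contact_height = 0,
                                 density = 3.27, ly = 10, n_frames = 6,
                                 seed = NULL) {
  stopifnot(theta_deg > 0, theta_deg < 180, radius > 0)
  if (!is.null(seed)) set.seed(seed)
  z_c <- contact_height - radius * cos(theta_deg * pi / 180)
  apex <- z_c + radius
  if (apex <= 0) stop("cap lies entirely below the wall")
  half_w <- if (z_c >= 0) radius else sqrt(radius^2 - z_c^2)
  Lx <- 2 * half_w + 10
  Lz <- apex + 4
  x_c <- Lx / 2
  # cap cross-section area above the wall
  zz <- seq(0, apex, length.out = 4096)
  area <- sum(2 * sqrt(pmax(0, radius^2 - (zz - z_c)^2))) * (zz[2] - zz[1])
  n <- round(density * area * ly)
  frames <- vector("list", n_frames)
  for (f in seq_len(n_frames)) {
    got <- 0
    px <- pz <- numeric(n)
    while (got < n) {
      m <- 2 * (n - got) + 100
      cx <- runif(m, -half_w, half_w)
      cz <- runif(m, 0, apex)
      ok <- cx^2 + (cz - z_c)^2 < radius^2
      take <- min(n - got, sum(ok))
      px[got + seq_len(take)] <- cx[ok][seq_len(take)] + x_c
      pz[got + seq_len(take)] <- cz[ok][seq_len(take)]
      got <- got + take
    }
    pos <- cbind(px, runif(n, 0, ly), pz)
    frames[[f]] <- dpd_state(pos, rep(1L, n), c(Lx, ly, Lz),
                             velocities = matrix(0, n, 3),
                             species_names = "dodecane", walled = TRUE)
  }
  frames
}
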