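#' Construct a simulation state
#'
#' Holds per-bead positions (reduced units), velocities, species indices,
#' molecule ids, the global bond and angle lists, the box, and the
#' boundary mode. Positions must lie inside the box; when `walled`, the z
#' direction is bounded by hard specular walls at 0 and `box[3]` and only
#' x and y are periodic.
#'
#' @param positions N x 3 matrix
#' @param species integer vector (1-based index into `species_names`)
#' @param box lengths `c(Lx, Ly, Lz)`
#' @param velocities N x 3 matrix; defaults to a Maxwell distribution at
#'   `temperature` with the center-of-mass drift removed
#' @param species_names character vector naming the species levels
#' @param molecule integer molecule id per bead
#' @param bonds matrix/data frame with columns (i, j, k_b, r0), global
#'   1-based bead indices
#' @param angles matrix/data frame with columns (i, j, k, k_a, theta0)
#' @param walled logical: hard specular walls in z
#' @param temperature reduced temperature used to draw missing velocities
#' @return an object of class `dpd_state`
#' @export
dpd_state <- function(positions, species, box, velocities = NULL,
                      species_names = NULL, molecule = NULL, bonds = NULL,
                      angles = NULL, walled = FALSE, temperature = 1) {
  positions <- as.matrix(positions)
  n <- nrow(positions)
  stopifnot(ncol(positions) == 3, length(box) == 3, all(box > 0),
            length(species) == n)
  if (is.null(velocities)) velocities <- init_velocities(n, temperature)
  velocities <- as.matrix(velocities)
  stopifnot(all(dim(velocities) == c(n, 3)))
  if (is.null(species_names))
    species_names <- paste0("S", seq_len(max(species)))
  if (is.null(molecule)) molecule <- seq_len(n)
  if (walled && (any(positions[, 3] < 0) || any(positions[, 3] > box[3])))
    stop("walled state requires 0 <= z <= L_z for every bead")
  empty_b <- matrix(0, 0, 4)
  empty_a <- matrix(0, 0, 5)
  s <- list(
    positions = positions,
    velocities = velocities,
    species = as.integer(species),
    species_names = species_names,
    molecule = as.integer(molecule),
    box = as.numeric(box),
    walled = isTRUE(walled),
    bonds = if (is.null(bonds)) empty_b else
      unname(as.matrix(as.data.frame(bonds)[, 1:4])),
    angles = if (is.null(angles)) empty_a else
      unname(as.matrix(as.data.frame(angles)[, 1:5]))
  )
  class(s) <- "dpd_state"
  s
}

#' @export
print.dpd_state <- function(x, ...) {
  cat(sprintf("DPD state: %d beads in %.4g x %.4g x %.4g box (%s)\n",
              nrow(x$positions), x$box[1], x$box[2], x$box[3],
              if (x$walled) "walls in z" else "fully periodic"))
  tab <- table(factor(x$species_names[x$species], levels = x$species_names))
  cat("  species:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  cat(sprintf("  bonds: %d, angles: %d, density: %.4g\n",
              nrow(x$bonds), nrow(x$angles),
              nrow(x$positions) / prod(x$box)))
  invisible(x)
}

#' Maxwell velocities at a reduced temperature, zero total momentum
#'
#' @param n number of beads
#' @param temperature reduced temperature
#' @return n x 3 matrix
#' @export
init_velocities <- function(n, temperature = 1) {
  v <- matrix(rnorm(3 * n, sd = sqrt(temperature)), n, 3)
  if (n > 1) v <- sweep(v, 2, colMeans(v))
  v
}

# Lay out n_mol copies of a molecule template as compact random walks
# inside [origin, origin + extent), appending to the growing state lists.
# Soft DPD potentials tolerate overlaps, so placement is rejection-free.
place_molecules <- function(template, n_mol, origin, extent, species_names) {
  nb <- length(template$species)
  spec_idx <- match(template$species, species_names)
  if (anyNA(spec_idx)) stop("molecule species missing from force field")
  pos <- matrix(0, n_mol * nb, 3)
  species <- integer(n_mol * nb)
  molecule <- integer(n_mol * nb)
  bonds <- NULL
  angles <- NULL
  if (n_mol == 0)
    return(list(positions = pos, species = species, molecule = molecule,
                bonds = bonds, angles = angles))
  for (m in seq_len(n_mol)) {
    row0 <- (m - 1) * nb
    p <- matrix(0, nb, 3)
    p[1, ] <- origin + runif(3) * extent
    if (nb > 1) {
      for (b in seq_len(nb - 1)) {
        r0 <- template$bonds$r0[b]
        u <- rnorm(3)
        p[b + 1, ] <- p[b, ] + r0 * u / sqrt(sum(u^2))
      }
      # fold the chain back into the region by reflection (keeps walled z
      # legal without stacking beads on the boundary)
      for (d in 1:3) {
        w <- extent[d]
        u2 <- (p[, d] - origin[d]) %% (2 * w)
        p[, d] <- origin[d] + w - abs(u2 - w)
      }
    }
    pos[row0 + seq_len(nb), ] <- p
    species[row0 + seq_len(nb)] <- spec_idx
    molecule[row0 + seq_len(nb)] <- m
  }
  if (nrow(template$bonds) > 0) {
    off <- rep((seq_len(n_mol) - 1) * nb, each = nrow(template$bonds))
    bonds <- cbind(template$bonds$i + off, template$bonds$j + off,
                   rep(template$bonds$k_b, n_mol),
                   rep(template$bonds$r0, n_mol))
  }
  if (nrow(template$angles) > 0) {
    off <- rep((seq_len(n_mol) - 1) * nb, each = nrow(template$angles))
    angles <- cbind(template$angles$i + off, template$angles$j + off,
                    template$angles$k + off,
                    rep(template$angles$k_a, n_mol),
                    rep(template$angles$theta0, n_mol))
  }
  list(positions = pos, species = species, molecule = molecule,
       bonds = bonds, angles = angles)
}

# stack several place_molecules() blocks into one dpd_state
assemble_state <- function(blocks, box, species_names, walled,
                           temperature = 1) {
  pos <- do.call(rbind, lapply(blocks, `[[`, "positions"))
  species <- unlist(lapply(blocks, `[[`, "species"))
  n_off <- 0L
  m_off <- 0L
  molecule <- integer(0)
  bonds <- NULL
  angles <- NULL
  for (bl in blocks) {
    molecule <- c(molecule, bl$molecule + m_off)
    if (!is.null(bl$bonds)) {
      b <- bl$bonds
      b[, 1:2] <- b[, 1:2] + n_off
      bonds <- rbind(bonds, b)
    }
    if (!is.null(bl$angles)) {
      a <- bl$angles
      a[, 1:3] <- a[, 1:3] + n_off
      angles <- rbind(angles, a)
    }
    n_off <- n_off + length(bl$species)
    m_off <- m_off + if (length(bl$molecule)) max(bl$molecule) else 0L
  }
  dpd_state(pos, species, box, species_names = species_names,
            molecule = molecule, bonds = bonds, angles = angles,
            walled = walled, temperature = temperature)
}

# resolve a fluid name to its molecule template
fluid_template <- function(ff, fluid) {
  if (fluid %in% names(ff$molecules)) return(ff$molecules[[fluid]])
  if (fluid %in% ff$species) return(molecule_template(fluid))
  stop("unknown fluid '", fluid, "'")
}
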