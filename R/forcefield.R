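#' Construct a DPD force field
#'
#' Bundles the bead species, the symmetric pair table of repulsion
#' amplitudes `A` and ranges `R` (in units of \eqn{r_c}), and the molecule
#' templates. Pair interactions are the standard soft DPD repulsion
#' \deqn{F_{ij}(r) = A_{ij}(1 - r/R_{ij})\,\hat e_{ij}, \quad r < R_{ij}}
#' with energy \eqn{(A_{ij} R_{ij}/2)(1 - r/R_{ij})^2}.
#'
#' @param species character vector of unique bead species names
#' @param mass named numeric vector of bead molar masses (g/mol)
#' @param A,R symmetric matrices of repulsion amplitudes and cutoffs,
#'   dimnames matching `species`
#' @param molecules named list of molecule templates
#'   (see [molecule_template()])
#' @param angle_style bending-potential form used for angle terms:
#'   `"cosine"` for \eqn{U = k_a(1 - \cos(\theta - \theta_0))} (the form
#'   used by the coarse-grained model family this force field comes from)
#'   or `"harmonic"` for \eqn{U = (k_a/2)(\theta - \theta_0)^2}; the two
#'   agree for small bends
#' @return an object of class `dpd_forcefield`
#' @seealso [default_forcefield()] for the bundled water/dodecane model
#' @export
dpd_forcefield <- function(species, mass, A, R, molecules = list(),
                           angle_style = c("cosine", "harmonic")) {
  angle_style <- match.arg(angle_style)
  stopifnot(is.character(species), !anyDuplicated(species))
  n <- length(species)
  A <- as.matrix(A); R <- as.matrix(R)
  stopifnot(dim(A) == c(n, n), dim(R) == c(n, n))
  if (!isTRUE(all.equal(A, t(A))) || !isTRUE(all.equal(R, t(R))))
    stop("pair tables A and R must be symmetric")
  if (any(A < 0) || any(R <= 0))
    stop("pair table requires A >= 0 and R > 0")
  dimnames(A) <- dimnames(R) <- list(species, species)
  ff <- list(species = species, mass = mass[species], A = A, R = R,
             max_cutoff = max(R), molecules = molecules,
             angle_style = angle_style)
  class(ff) <- "dpd_forcefield"
  ff
}

#' The bundled coarse-grained water/dodecane force field
#'
#' Three bead types: `2H2O` (a pair of water molecules), `CH2CH2` and
#' `CH3`. Water beads interact with amplitude 25 at range 1; the remaining
#' amplitudes and ranges were parametrized against liquid densities and
#' water/octanol partition coefficients. Dodecane is the 7-mer
#' CH3-(CH2CH2)5-CH3 (see [build_dodecane()]). The largest pair cutoff,
#' 1.0740, doubles as the dissipative/random-force range of the
#' thermostat.
#'
#' @param A_water_alkane repulsion amplitude between water and both alkane
#'   bead types. The parametrized value is 45; raising it (e.g. to 100)
#'   sharpens the oil/water interface and increases the interfacial
#'   tension at the cost of the partition-coefficient calibration.
#' @return a [dpd_forcefield()] object
#' @examples
#' ff <- default_forcefield()
#' ff$A["2H2O", "CH2CH2"]  # 45
#' @export
default_forcefield <- function(A_water_alkane = 45) {
  species <- c("2H2O", "CH2CH2", "CH3")
  A <- matrix(c(25.0, A_water_alkane, A_water_alkane,
                A_water_alkane, 22.0, 23.0,
                A_water_alkane, 23.0, 24.0), 3, 3, byrow = TRUE)
  R <- matrix(c(1.0000, 1.0370, 0.9775,
                1.0370, 1.0740, 1.0145,
                0.9775, 1.0145, 0.9550), 3, 3, byrow = TRUE)
  mass <- c("2H2O" = 36.03, "CH2CH2" = 28.05, "CH3" = 15.03)
  dpd_forcefield(species, mass, A, R,
                 molecules = list(water = build_water(),
                                  dodecane = build_dodecane()))
}

#' @export
print.dpd_forcefield <- function(x, ...) {
  cat("DPD force field:", length(x$species), "bead species,",
      length(x$molecules), "molecule templates\n")
  cat("Pair amplitudes A (upper) / ranges R (lower):\n")
  m <- x$A
  m[lower.tri(m)] <- x$R[lower.tri(m)]
  print(m)
  invisible(x)
}

#' Define a molecule template
#'
#' @param species character vector: bead species along the molecule
#' @param bonds data frame with columns `i`, `j`, `k_b`, `r0`
#'   (1-based indices into the molecule, stiffness, rest length)
#' @param angles data frame with columns `i`, `j`, `k`, `k_a`, `theta0`
#'   (`j` is the central bead; `theta0` in radians)
#' @return an object of class `molecule_template`
#' @export
molecule_template <- function(species, bonds = NULL, angles = NULL) {
  n <- length(species)
  if (is.null(bonds))
    bonds <- data.frame(i = integer(), j = integer(),
                        k_b = numeric(), r0 = numeric())
  if (is.null(angles))
    angles <- data.frame(i = integer(), j = integer(), k = integer(),
                         k_a = numeric(), theta0 = numeric())
  stopifnot(all(c(bonds$i, bonds$j, angles$i, angles$j, angles$k) >= 1),
            all(c(bonds$i, bonds$j, angles$i, angles$j, angles$k) <= n),
            all(bonds$r0 > 0),
            all(angles$theta0 > 0 & angles$theta0 <= pi + 1e-12))
  out <- list(species = species, bonds = bonds, angles = angles)
  class(out) <- "molecule_template"
  out
}

#' Dodecane as a bonded 7-mer
#'
#' CH3-(CH2CH2)5-CH3: 7 beads, 6 harmonic bonds (`k_b` = 150; rest length
#' 0.29 for the terminal CH3-CH2CH2 bonds and 0.39 for the internal
#' CH2CH2-CH2CH2 bonds) and 5 angle terms over consecutive triples
#' (`k_a` = 5, rest angle 180 degrees) that keep the chain extended.
#'
#' @return a [molecule_template()]
#' @examples
#' dod <- build_dodecane()
#' length(dod$species)  # 7
#' @export
build_dodecane <- function() {
  species <- c("CH3", rep("CH2CH2", 5), "CH3")
  r0 <- c(0.29, rep(0.39, 4), 0.29)
  bonds <- data.frame(i = 1:6, j = 2:7, k_b = 150, r0 = r0)
  angles <- data.frame(i = 1:5, j = 2:6, k = 3:7, k_a = 5, theta0 = pi)
  molecule_template(species, bonds, angles)
}

#' Water as a single free bead
#' @return a [molecule_template()] with one `2H2O` bead
#' @export
build_water <- function() molecule_template("2H2O")

#' Soft DPD pair force and energy between two beads
#'
#' @param ff a [dpd_forcefield()]
#' @param species_i,species_j bead species names
#' @param rvec separation vector from bead j to bead i (reduced units)
#' @return list with `force` (vector acting on bead i), `energy`, and the
#'   scalar `magnitude`
#' @examples
#' ff <- default_forcefield()
#' pair_force(ff, "2H2O", "2H2O", c(0.5, 0, 0))$magnitude  # 12.5
#' @export
pair_force <- function(ff, species_i, species_j, rvec) {
  r <- sqrt(sum(rvec^2))
  if (r == 0) stop("singular configuration: coincident beads")
  Aij <- ff$A[species_i, species_j]
  Rij <- ff$R[species_i, species_j]
  if (r >= Rij)
    return(list(force = c(0, 0, 0), energy = 0, magnitude = 0))
  omr <- 1 - r / Rij
  f <- Aij * omr
  list(force = f * rvec / r, energy = 0.5 * Aij * Rij * omr^2, magnitude = f)
}

#' Bonded forces: harmonic bonds and angle bending (reference version)
#'
#' Pure-R evaluation of the bonded terms, used as the cross-check against
#' the compiled engine. Bonds follow \eqn{U = (k_b/2)(r - r_0)^2} (so a
#' bond stretched by 0.1 with `k_b` = 150 pulls back with force 15);
#' angles bend about the central bead with either the cosine form
#' \eqn{U = k_a(1 - \cos(\theta - \theta_0))} (default, the form used by
#' the coarse-grained model family this force field comes from) or the
#' harmonic form \eqn{U = (k_a/2)(\theta - \theta_0)^2}; the two agree
#' for small bends.
#'
#' @param positions N x 3 matrix of bead positions
#' @param bonds data frame/matrix with columns (i, j, k_b, r0)
#' @param angles data frame/matrix with columns (i, j, k, k_a, theta0)
#' @param angle_style `"cosine"` or `"harmonic"`
#' @return list with `forces` (N x 3), `energy`, and the 3x3 `virial`
#'   \eqn{\sum f \otimes r} of the bonded interactions
#' @export
bonded_forces <- function(positions, bonds = NULL, angles = NULL,
                          angle_style = c("cosine", "harmonic")) {
  angle_style <- match.arg(angle_style)
  n <- nrow(positions)
  f <- matrix(0, n, 3)
  vir <- matrix(0, 3, 3)
  energy <- 0
  if (!is.null(bonds) && nrow(bonds) > 0) {
    bonds <- as.data.frame(bonds)
    for (b in seq_len(nrow(bonds))) {
      i <- bonds$i[b]; j <- bonds$j[b]
      d <- positions[i, ] - positions[j, ]
      r <- sqrt(sum(d^2))
      if (r < 1e-12) stop("singular configuration: coincident bonded beads")
      dr <- r - bonds$r0[b]
      energy <- energy + 0.5 * bonds$k_b[b] * dr^2
      fvec <- -bonds$k_b[b] * dr * d / r
      f[i, ] <- f[i, ] + fvec
      f[j, ] <- f[j, ] - fvec
      vir <- vir + outer(fvec, d)
    }
  }
  if (!is.null(angles) && nrow(angles) > 0) {
    angles <- as.data.frame(angles)
    for (t in seq_len(nrow(angles))) {
      i <- angles$i[t]; j <- angles$j[t]; k <- angles$k[t]
      a <- positions[i, ] - positions[j, ]
      b2 <- positions[k, ] - positions[j, ]
      la <- sqrt(sum(a^2)); lb <- sqrt(sum(b2^2))
      if (la < 1e-12 || lb < 1e-12)
        stop("singular configuration: coincident angle beads")
      cth <- max(-1, min(1, sum(a * b2) / (la * lb)))
      th <- acos(cth)
      sth <- max(sqrt(1 - cth^2), 1e-8)
      dth <- th - angles$theta0[t]
      if (angle_style == "harmonic") {
        energy <- energy + 0.5 * angles$k_a[t] * dth^2
        coef <- angles$k_a[t] * dth / sth
      } else {
        energy <- energy + angles$k_a[t] * (1 - cos(dth))
        coef <- angles$k_a[t] * sin(dth) / sth
      }
      fi <- coef * (b2 / (la * lb) - cth * a / la^2)
      fk <- coef * (a / (la * lb) - cth * b2 / lb^2)
      f[i, ] <- f[i, ] + fi
      f[k, ] <- f[k, ] + fk
      f[j, ] <- f[j, ] - fi - fk
      vir <- vir + outer(fi, a) + outer(fk, b2)
    }
  }
  list(forces = f, energy = energy, virial = vir)
}

#' Write a force field pair table to TSV
#'
#' One row per unordered species pair with columns `species_i`,
#' `species_j`, `A_ij`, `R_ij`; bead masses are stored in `# mass` header
#' lines. Values are written with full precision so the table round-trips
#' bit-exactly.
#'
#' @param ff a [dpd_forcefield()]
#' @param path output file path
#' @export
write_forcefield <- function(ff, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in ff$species)
    cat(sprintf("# mass\t%s\t%.17g\n", s, ff$mass[[s]]), file = con)
  cat("species_i\tspecies_j\tA_ij\tR_ij\n", file = con)
  n <- length(ff$species)
  for (i in seq_len(n))
    for (j in i:n)
      cat(sprintf("%s\t%s\t%.17g\t%.17g\n", ff$species[i], ff$species[j],
                  ff$A[i, j], ff$R[i, j]), file = con)
  invisible(path)
}

#' Read a force field pair table written by [write_forcefield()]
#'
#' @param path file path
#' @param molecules molecule templates to attach (defaults to the water
#'   and dodecane templates when the species match the bundled model)
#' @return a [dpd_forcefield()]
#' @export
read_forcefield <- function(path, molecules = NULL) {
  lines <- readLines(path)
  mass_lines <- grep("^# mass\t", lines, value = TRUE)
  mass <- numeric(0)
  for (ml in mass_lines) {
    parts <- strsplit(ml, "\t", fixed = TRUE)[[1]]
    mass[parts[2]] <- as.numeric(parts[3])
  }
  tab <- read.table(text = lines[!startsWith(lines, "#")], sep = "\t",
                    header = TRUE, stringsAsFactors = FALSE)
  species <- unique(c(tab$species_i, tab$species_j))
  n <- length(species)
  A <- R <- matrix(NA_real_, n, n, dimnames = list(species, species))
  for (k in seq_len(nrow(tab))) {
    i <- tab$species_i[k]; j <- tab$species_j[k]
    A[i, j] <- A[j, i] <- tab$A_ij[k]
    R[i, j] <- R[j, i] <- tab$R_ij[k]
  }
  if (anyNA(A) || anyNA(R)) stop("incomplete pair table in ", path)
  if (is.null(molecules))
    molecules <- if (setequal(species, c("2H2O", "CH2CH2", "CH3")))
      list(water = build_water(), dodecane = build_dodecane()) else list()
  dpd_forcefield(species, mass, A, R, molecules)
}
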