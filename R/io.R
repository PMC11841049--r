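#' Write states or frames as extended XYZ
#'
#' One block per frame: the bead count, a comment line carrying the box
#' (`Lattice=...`), the boundary mode (`pbc="T T F"` for walled slabs)
#' and the column layout (`Properties=...`), then one row per bead with
#' the species label, position, and optionally velocity.
#'
#' @param x a [dpd_state()], [run_dpd()] result, or list of states
#' @param path output file
#' @param velocities include velocity columns
#' @return the path, invisibly
#' @export
write_xyz <- function(x, path, velocities = FALSE) {
  frames <- as_frames(x)
  con <- file(path, "w")
  on.exit(close(con))
  for (fr in frames) {
    n <- nrow(fr$positions)
    props <- if (velocities) "species:S:1:pos:R:3:vel:R:3"
             else "species:S:1:pos:R:3"
    cat(sprintf("%d\n", n), file = con)
    cat(sprintf(
      'Lattice="%.10g 0 0 0 %.10g 0 0 0 %.10g" Properties=%s pbc="T T %s"\n',
      fr$box[1], fr$box[2], fr$box[3], props,
      if (fr$walled) "F" else "T"), file = con)
    lab <- fr$species_names[fr$species]
    m <- cbind(fr$positions, if (velocities) fr$velocities)
    lines <- paste(lab, apply(m, 1, function(r)
      paste(sprintf("%.10g", r), collapse = " ")))
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read extended-XYZ frames written by [write_xyz()]
#'
#' @param path input file
#' @param species_names optional species ordering; defaults to order of
#'   first appearance
#' @return a list of [dpd_state()] frames
#' @export
read_xyz <- function(path, species_names = NULL) {
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    n <- as.integer(lines[i])
    comment <- lines[i + 1]
    lat <- regmatches(comment,
                      regexpr('Lattice="[^"]*"', comment))
    nums <- as.numeric(strsplit(gsub('Lattice="|"', "", lat), " ")[[1]])
    box <- nums[c(1, 5, 9)]
    walled <- grepl('pbc="T T F"', comment)
    has_vel <- grepl("vel:R:3", comment)
    rows <- strsplit(trimws(lines[i + 1 + seq_len(n)]), "\\s+")
    lab <- vapply(rows, `[[`, "", 1)
    num <- t(vapply(rows, function(r) as.numeric(r[-1]),
                    numeric(if (has_vel) 6 else 3)))
    if (is.null(species_names)) species_names <- unique(lab)
    frames[[length(frames) + 1]] <- dpd_state(
      num[, 1:3, drop = FALSE], match(lab, species_names), box,
      velocities = if (has_vel) num[, 4:6, drop = FALSE]
                   else matrix(0, n, 3),
      species_names = species_names, walled = walled)
    i <- i + 2 + n
  }
  frames
}

#' Write a tension or surface-energy result as annotated TSV
#'
#' @param x a `dpd_tension` (from [interfacial_tension()] or
#'   [surface_energy()])
#' @param path output file
#' @param header named list written as `# key value` comment lines
#'   (box, composition, wall amplitudes, ...)
#' @return the path, invisibly
#' @export
write_tension_tsv <- function(x, path, header = list()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(header))
    cat(sprintf("# %s\t%s\n", nm, paste(header[[nm]], collapse = " ")),
        file = con)
  cat("quantity\treduced\tse_reduced\tmN_m\tse_mN_m\tn_samples\tn_blocks\n",
      file = con)
  cat(sprintf("tension\t%.8g\t%.8g\t%.8g\t%.8g\t%d\t%d\n",
              x$reduced, x$se_reduced, x$mN_m, x$se_mN_m,
              x$n_samples, x$n_blocks), file = con)
  invisible(path)
}

#' Read a run configuration file
#'
#' A minimal TOML-style format: `[section]` headers with `key = value`
#' lines; values may be numbers, strings, booleans or space-separated
#' numeric triples. Used by the `dpdwet` command-line driver.
#'
#' @param path configuration file
#' @return nested named list of sections
#' @export
read_run_config <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  cfg <- list()
  section <- "global"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) < 2) next
    key <- trimws(kv[1])
    val <- trimws(paste(kv[-1], collapse = "="))
    val <- gsub('^"|"$', "", val)
    parsed <- suppressWarnings(as.numeric(strsplit(val, "\\s+")[[1]]))
    out <- if (!anyNA(parsed)) parsed
           else if (val %in% c("true", "false")) val == "true"
           else val
    cfg[[section]][[key]] <- out
  }
  cfg
}

#' @rdname read_run_config
#' @param cfg nested named list of sections
#' @export
write_run_config <- function(cfg, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (section in names(cfg)) {
    cat(sprintf("[%s]\n", section), file = con)
    for (key in names(cfg[[section]])) {
      v <- cfg[[section]][[key]]
      val <- if (is.character(v)) sprintf('"%s"', v)
             else if (is.logical(v)) tolower(as.character(v))
             else paste(format(v, digits = 15), collapse = " ")
      cat(sprintf("%s = %s\n", key, val), file = con)
    }
    cat("\n", file = con)
  }
  invisible(path)
}
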