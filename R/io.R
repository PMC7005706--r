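# Structure and trajectory I/O: PDB v3.3 ATOM/HETATM records with a
# CRYST1 cell, plain and multi-frame XYZ, energy CSV time series.
# Coordinates are Angstrom; atom indices are 1-based in files.

.element_masses <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                     S = 32.06, Au = 196.967, Ar = 39.948)

.known_resnames <- c("ACE", "NH2", "SER", "PHE", "PRO", "GLN", "ASN",
                     "HOH", "AU", "BNZ")

#' Write a system as PDB
#'
#' ATOM records for the peptide (caps as ACE/NH2 residues, numbering
#' from 1), HETATM for metal and water; the in-plane cell goes into a
#' CRYST1 record whose open surface normal is written as a large vacuum
#' gap along c.
#'
#' @param system A `molsys`.
#' @param path Output file.
#' @param vacuum_c c-axis length written for the open direction (A).
#' @return `path`, invisibly.
#' @export
write_pdb <- function(system, path, vacuum_c = 100) {
  lines <- character(0)
  if (!is.null(system$cell)) {
    a1 <- system$cell[, 1]; a2 <- system$cell[, 2]
    gam <- acos(sum(a1 * a2) / sqrt(sum(a1^2) * sum(a2^2))) * 180 / pi
    lines <- c(lines, sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      sqrt(sum(a1^2)), sqrt(sum(a2^2)), vacuum_c, 90, 90, gam))
  }
  at <- system$atoms
  for (i in seq_len(n_atoms(system))) {
    rec <- if (at$group[i] %in% c("surface", "water")) "HETATM" else "ATOM  "
    lines <- c(lines, sprintf(
      "%s%5d  %-3s %-3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      rec, i, at$name[i], at$resname[i], "A", at$resid[i],
      system$coords[i, 1], system$coords[i, 2], system$coords[i, 3],
      1, 0, at$element[i]))
  }
  lines <- c(lines, "TER", "END")
  writeLines(lines, path)
  invisible(path)
}

#' Write a system as XYZ
#'
#' @param system A `molsys`.
#' @param path Output file.
#' @param comment Comment line.
#' @export
write_xyz <- function(system, path, comment = "pepsurf structure") {
  n <- n_atoms(system)
  lines <- c(as.character(n), comment,
             sprintf("%-2s %14.8f %14.8f %14.8f", system$atoms$element,
                     system$coords[, 1], system$coords[, 2],
                     system$coords[, 3]))
  writeLines(lines, path)
  invisible(path)
}

#' Read a structure file
#'
#' @param path PDB or XYZ file.
#' @param format `"pdb"`, `"xyz"`, or `NULL` to infer from the
#'   extension.
#' @return A `molsys`.  For PDB input with recognized residues the
#'   bonded topology is reconstructed from the residue templates;
#'   unknown residue names are an error naming the residue and line.
#' @export
read_structure <- function(path, format = NULL) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  switch(format,
         pdb = read_pdb(path),
         xyz = read_xyz(path),
         stop("unsupported format: ", format, call. = FALSE))
}

#' @rdname read_structure
#' @export
read_pdb <- function(path) {
  lines <- readLines(path)
  rows <- list(); cell <- NULL
  for (ln in seq_along(lines)) {
    line <- lines[ln]
    tag <- substr(line, 1, 6)
    if (tag == "CRYST1") {
      a <- as.numeric(substr(line, 7, 15))
      b <- as.numeric(substr(line, 16, 24))
      gam <- as.numeric(substr(line, 48, 54)) * pi / 180
      cell <- cbind(c(a, 0), b * c(cos(gam), sin(gam)))
    } else if (tag %in% c("ATOM  ", "HETATM")) {
      name <- trimws(substr(line, 13, 16))
      resname <- trimws(substr(line, 18, 20))
      resid <- suppressWarnings(as.integer(substr(line, 23, 26)))
      x <- suppressWarnings(as.numeric(substr(line, 31, 38)))
      y <- suppressWarnings(as.numeric(substr(line, 39, 46)))
      z <- suppressWarnings(as.numeric(substr(line, 47, 54)))
      el <- trimws(substr(line, 77, 78))
      if (anyNA(c(x, y, z)) || is.na(resid))
        stop("malformed PDB record at line ", ln, call. = FALSE)
      if (!toupper(resname) %in% .known_resnames)
        stop("unknown residue '", resname, "' at line ", ln, call. = FALSE)
      rows[[length(rows) + 1L]] <- list(name = name, resname = resname,
                                        resid = resid, x = x, y = y,
                                        z = z, element = el)
    }
  }
  if (!length(rows)) stop("no atom records in ", path, call. = FALSE)
  df <- do.call(rbind, lapply(rows, as.data.frame))
  .system_from_atom_table(df, cell)
}

#' @keywords internal
.system_from_atom_table <- function(df, cell = NULL) {
  n <- nrow(df)
  group <- ifelse(toupper(df$resname) == "AU", "surface",
                  ifelse(df$resname == "HOH", "water", "peptide"))
  # per-atom type/charge/mass from templates where available
  type <- character(n); charge <- numeric(n); mass <- numeric(n)
  bonds <- list()
  gi <- function(resid, name) which(df$resid == resid & df$name == name)
  for (rid in unique(df$resid)) {
    sel <- which(df$resid == rid)
    rn <- toupper(df$resname[sel[1]])
    tmpl <- if (rn %in% names(.three_to_one))
      .residue_table[[.three_to_one[rn]]]
    else if (rn == "ACE") .cap_ace
    else if (rn == "NH2") .cap_nh2
    else if (rn == "HOH") .water_template
    else NULL
    if (!is.null(tmpl)) {
      m <- match(df$name[sel], tmpl$atoms$name)
      if (anyNA(m))
        stop("atom names of residue ", rid, " (", rn,
             ") do not match the ", rn, " template", call. = FALSE)
      type[sel] <- tmpl$atoms$type[m]
      charge[sel] <- tmpl$atoms$charge[m]
      mass[sel] <- tmpl$atoms$mass[m]
      bn <- tmpl$bonds
      if (!is.null(bn) && length(bn))
        for (b in seq_len(nrow(bn)))
          bonds[[length(bonds) + 1L]] <- c(gi(rid, bn[b, 1]),
                                           gi(rid, bn[b, 2]))
    } else { # metal
      type[sel] <- rn
      charge[sel] <- 0
      mass[sel] <- .element_masses[df$element[sel[1]]]
    }
  }
  # peptide bonds between consecutive peptide units
  prid <- sort(unique(df$resid[group == "peptide"]))
  if (length(prid) > 1) {
    for (k in seq_len(length(prid) - 1)) {
      ci <- gi(prid[k], "C"); ni <- gi(prid[k + 1], "N")
      if (length(ci) == 1 && length(ni) == 1)
        bonds[[length(bonds) + 1L]] <- c(ci, ni)
    }
  }
  atoms <- data.frame(name = df$name, element = df$element,
                      resid = df$resid, resname = toupper(df$resname),
                      type = type, charge = charge, mass = mass,
                      group = group, fixed = group == "surface",
                      stringsAsFactors = FALSE)
  coords <- as.matrix(df[, c("x", "y", "z")])
  dimnames(coords) <- NULL
  bonds <- if (length(bonds)) do.call(rbind, bonds) else
    matrix(integer(0), ncol = 2)
  topo <- finalize_topology(atoms, coords, bonds)
  molecular_system(atoms, coords, topo, cell = cell)
}

#' @rdname read_structure
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n)) stop("malformed XYZ header at line 1", call. = FALSE)
  if (length(lines) < n + 2)
    stop("XYZ atom count mismatch at header (line 1): expected ", n,
         " atoms, file has ", length(lines) - 2, call. = FALSE)
  parts <- strsplit(trimws(lines[3:(n + 2)]), "\\s+")
  bad <- which(vapply(parts, length, integer(1)) < 4)
  if (length(bad))
    stop("malformed XYZ record at line ", bad[1] + 2, call. = FALSE)
  el <- vapply(parts, `[[`, character(1), 1)
  xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
  mass <- unname(.element_masses[el])
  mass[is.na(mass)] <- 12
  atoms <- data.frame(name = el, element = el, resid = 1L,
                      resname = "UNK", type = "LJ", charge = 0,
                      mass = mass, group = "other", fixed = FALSE,
                      stringsAsFactors = FALSE)
  molecular_system(atoms, xyz)
}

#' Write a trajectory as multi-frame XYZ
#'
#' One XYZ block per frame; the comment line carries step, time,
#' potential energy and temperature.
#'
#' @param traj `md_trajectory`.
#' @param path Output file.
#' @export
write_trajectory_xyz <- function(traj, path) {
  el <- traj$system$atoms$element
  n <- length(el)
  con <- file(path, "w")
  on.exit(close(con))
  for (f in seq_along(traj$frames)) {
    e <- traj$energies[f, ]
    writeLines(c(as.character(n),
                 sprintf("step=%d time_fs=%.3f e_pot=%.6f temperature=%.2f",
                         e$step, e$time_fs, e$e_pot, e$temperature),
                 sprintf("%-2s %14.8f %14.8f %14.8f", el,
                         traj$frames[[f]][, 1], traj$frames[[f]][, 2],
                         traj$frames[[f]][, 3])), con)
  }
  invisible(path)
}

#' Write the energy time series of a trajectory as CSV
#' @param traj `md_trajectory`.
#' @param path Output file.
#' @export
write_energy_csv <- function(traj, path) {
  utils::write.csv(traj$energies, path, row.names = FALSE)
  invisible(path)
}
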