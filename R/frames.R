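# Molecular frame container and file I/O (extended XYZ and PDB).
# Coordinates are in Angstrom, masses in amu.

ELEMENT_MASSES <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                    NA. = 22.990, CL = 35.45, S = 32.06, P = 30.974)

element_mass <- function(element) {
  key <- toupper(element)
  key[key == "NA"] <- "NA."
  m <- ELEMENT_MASSES[key]
  ifelse(is.na(m), 12.011, m)  # unknown elements fall back to carbon mass
}

#' Construct a molecular frame
#'
#' A frame is a snapshot of atoms with positions (Angstrom), masses (amu),
#' molecule membership and a solute/solvent/ion role, optionally with a
#' covalent bond list used by hydrogen-bond detection.
#'
#' @param atoms Data frame with columns `element`, `x`, `y`, `z`, `mass`,
#'   `molecule_id`, `role` (one of `"solute"`, `"solvent"`, `"ion"`).
#' @param bonds Optional 2-column integer matrix of covalently bonded atom
#'   index pairs.
#' @param time Frame time in ns.
#' @param metadata Named list (e.g. generator spec, bridge molecule ids).
#' @return An object of class `molecular_frame`.
#' @export
molecular_frame <- function(atoms, bonds = NULL, time = 0, metadata = list()) {
  required <- c("element", "x", "y", "z", "mass", "molecule_id", "role")
  missing_cols <- setdiff(required, names(atoms))
  if (length(missing_cols)) {
    stop(sprintf("atoms is missing columns: %s",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!all(atoms$mass > 0)) stop("all atom masses must be positive")
  if (!all(atoms$role %in% c("solute", "solvent", "ion"))) {
    stop("role must be one of solute, solvent, ion")
  }
  if (!is.null(bonds)) {
    bonds <- matrix(as.integer(bonds), ncol = 2)
    if (any(bonds < 1) || any(bonds > nrow(atoms))) {
      stop("bond indices out of range")
    }
  }
  structure(list(atoms = atoms, bonds = bonds, time = time,
                 metadata = metadata),
            class = "molecular_frame")
}

#' @export
print.molecular_frame <- function(x, ...) {
  tab <- table(x$atoms$role)
  cat(sprintf("Molecular frame at t = %g ns: %d atoms (%s), %d molecules\n",
              x$time, nrow(x$atoms),
              paste(sprintf("%s %d", names(tab), tab), collapse = ", "),
              length(unique(x$atoms$molecule_id))))
  invisible(x)
}

coords_matrix <- function(frame, idx = seq_len(nrow(frame$atoms))) {
  as.matrix(frame$atoms[idx, c("x", "y", "z")])
}

# Resolve a selection (role name or molecule id) to atom indices.
select_atoms <- function(frame, selection) {
  a <- frame$atoms
  if (is.character(selection) && length(selection) == 1 &&
      selection %in% c("solute", "solvent", "ion")) {
    idx <- which(a$role == selection)
  } else {
    idx <- which(a$molecule_id %in% selection)
  }
  if (length(idx) == 0) {
    stop(sprintf("empty selection: %s", paste(selection, collapse = ",")))
  }
  idx
}

#' Write a frame in extended XYZ format
#'
#' Dialect: line 1 atom count; line 2 `time=<ns>`; then one row per atom:
#' `element x y z mass molecule_id role` (whitespace-separated).
#'
#' @param frame A [molecular_frame()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frame_xyz <- function(frame, path) {
  a <- frame$atoms
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(nrow(a)), con)
  writeLines(sprintf("time=%.17g", frame$time), con)
  writeLines(sprintf("%s %.17g %.17g %.17g %.17g %s %s",
                     a$element, a$x, a$y, a$z, a$mass,
                     as.character(a$molecule_id), a$role), con)
  invisible(path)
}

#' Read a frame (or concatenated frames) from extended XYZ
#'
#' @param path File written by [write_frame_xyz()]; may contain several
#'   concatenated frames.
#' @return A single [molecular_frame()] if the file holds one frame, else a
#'   list of frames.
#' @export
read_frame_xyz <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  lines <- readLines(path)
  frames <- list()
  i <- 1
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1; next }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n)) stop(sprintf("line %d: expected atom count", i))
    tm <- 0
    cm <- lines[i + 1]
    m <- regmatches(cm, regexec("time=([-0-9.eE+]+)", cm))[[1]]
    if (length(m) == 2) tm <- as.numeric(m[2])
    rows <- lines[(i + 2):(i + 1 + n)]
    fields <- strsplit(trimws(rows), "\\s+")
    bad <- which(lengths(fields) != 7)
    if (length(bad)) {
      stop(sprintf("line %d: expected 7 whitespace-separated fields",
                   i + 1 + bad[1]))
    }
    fm <- do.call(rbind, fields)
    atoms <- data.frame(
      element = fm[, 1],
      x = as.numeric(fm[, 2]), y = as.numeric(fm[, 3]),
      z = as.numeric(fm[, 4]), mass = as.numeric(fm[, 5]),
      molecule_id = fm[, 6], role = fm[, 7])
    frames[[length(frames) + 1]] <- molecular_frame(atoms, time = tm)
    i <- i + 2 + n
  }
  if (length(frames) == 0) stop(sprintf("no frames found in %s", path))
  if (length(frames) == 1) frames[[1]] else frames
}

#' Read a molecular frame from a PDB file
#'
#' Parsed with \pkg{bio3d}.  Molecule ids are `chain:resno`; water residues
#' (HOH/WAT/SOL/TIP3) become `role = "solvent"`, monatomic ion residues
#' (NA/CL/K/MG/CA/H3O) `role = "ion"`, everything else `role = "solute"`.
#' Masses come from the element inferred by bio3d.
#'
#' @param path PDB file path.
#' @return A [molecular_frame()].
#' @export
read_frame_pdb <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path))
  pdb <- bio3d::read.pdb(path)
  a <- pdb$atom
  elem <- a$elesy
  if (is.null(elem) || all(is.na(elem)) || all(!nzchar(trimws(elem)))) {
    elem <- substr(trimws(a$elety), 1, 1)
  }
  elem <- trimws(elem)
  resid <- toupper(trimws(a$resid))
  role <- ifelse(resid %in% c("HOH", "WAT", "SOL", "TIP3", "TIP", "SPC"),
                 "solvent",
                 ifelse(resid %in% c("NA", "CL", "K", "MG", "CA", "ZN", "H3O"),
                        "ion", "solute"))
  chain <- ifelse(is.na(a$chain) | !nzchar(a$chain), "A", a$chain)
  atoms <- data.frame(
    element = elem,
    x = a$x, y = a$y, z = a$z,
    mass = element_mass(elem),
    molecule_id = paste0(chain, ":", a$resno),
    role = role)
  molecular_frame(atoms)
}
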