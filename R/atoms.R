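# Atom containers and structure I/O.

# Bondi-style van der Waals radii (Å) for the elements seen in protein and
# common ligand heavy atoms; hydrogens included for completeness.
VDW_RADII <- c(
  H = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
  F = 1.47, CL = 1.75, BR = 1.85, I = 1.98, SE = 1.90,
  FE = 1.40, ZN = 1.39, MG = 1.73, CA = 1.90, MN = 1.40, "NA" = 2.27, K = 2.75
)

#' Construct an atom set
#'
#' The atom set is the common currency of the pocket pipeline: a data frame
#' with one row per atom carrying coordinates, element, residue identity,
#' van der Waals radius, partial charge and ligand/heavy flags.
#'
#' @param coord n x 3 matrix of coordinates (Å).
#' @param element Character vector of element symbols.
#' @param chain,resnum,resname Residue identity vectors.
#' @param atom_name PDB atom names (e.g. "CA", "OD1").
#' @param charge Partial charges (e); defaults to 0.
#' @param is_ligand Logical flag separating ligand atoms from protein atoms.
#' @param vdw_radius Radii in Å; defaults to a Bondi-style table by element.
#' @return A data frame of class `atom_set` with an `id` column.
#' @export
atom_set <- function(coord, element, chain = "A", resnum = 1L,
                     resname = "UNK", atom_name = element, charge = 0,
                     is_ligand = FALSE, vdw_radius = NULL) {
  coord <- rbind(coord)
  n <- nrow(coord)
  if (!all(is.finite(coord))) stop("atom coordinates must be finite")
  element <- toupper(rep_len(element, n))
  if (is.null(vdw_radius)) {
    vdw_radius <- unname(VDW_RADII[element])
    vdw_radius[is.na(vdw_radius)] <- 1.7
  }
  if (any(!is.finite(vdw_radius)) || any(vdw_radius <= 0)) {
    stop("vdw_radius must be positive and finite")
  }
  out <- data.frame(
    id = seq_len(n),
    x = coord[, 1], y = coord[, 2], z = coord[, 3],
    element = element,
    chain = rep_len(chain, n),
    resnum = as.integer(rep_len(resnum, n)),
    resname = toupper(rep_len(resname, n)),
    atom_name = toupper(rep_len(atom_name, n)),
    vdw_radius = rep_len(vdw_radius, n),
    charge = rep_len(charge, n),
    is_ligand = rep_len(is_ligand, n),
    stringsAsFactors = FALSE
  )
  out$is_heavy <- out$element != "H"
  class(out) <- c("atom_set", "data.frame")
  out
}

atom_coords <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z"), drop = FALSE])
}

#' Read a protein structure from PDB
#'
#' Thin wrapper over [bio3d::read.pdb()] producing an [atom_set()]. Ligand
#' atoms are non-water `HETATM` records by default, or a specific residue
#' selected by name (and optionally chain) as `"RES"` or `"RES:CHAIN"`.
#' Only the first model of multi-model files is used.
#'
#' @param file Path to a PDB file.
#' @param ligand `NULL` (all non-water HETATM), or `"RES"` / `"RES:CHAIN"`.
#' @return An `atom_set`.
#' @export
read_structure <- function(file, ligand = NULL) {
  pdb <- bio3d::read.pdb(file, multi = FALSE, verbose = FALSE)
  a <- pdb$atom
  elem <- toupper(trimws(a$elesy))
  bad <- is.na(elem) | elem == ""
  if (any(bad)) elem[bad] <- toupper(substr(trimws(a$elety[bad]), 1, 1))
  is_het <- a$type == "HETATM"
  resname <- toupper(trimws(a$resid))
  if (is.null(ligand)) {
    is_lig <- is_het & !(resname %in% c("HOH", "WAT", "DOD"))
  } else {
    parts <- strsplit(ligand, ":", fixed = TRUE)[[1]]
    is_lig <- resname == toupper(parts[1])
    if (length(parts) > 1) is_lig <- is_lig & a$chain == parts[2]
  }
  atom_set(
    coord = cbind(a$x, a$y, a$z),
    element = elem,
    chain = ifelse(is.na(a$chain), "A", a$chain),
    resnum = a$resno,
    resname = resname,
    atom_name = toupper(trimws(a$elety)),
    is_ligand = is_lig
  )
}

#' Read per-atom charges and radii from PQR
#'
#' Parses the whitespace-delimited PQR dialect (ATOM/HETATM records whose
#' last two fields are partial charge and radius) and returns an
#' `atom_set` with those values attached.
#'
#' @param file Path to a PQR file.
#' @return An `atom_set` with `charge` and `vdw_radius` from the file.
#' @export
read_pqr <- function(file) {
  lines <- readLines(file)
  lines <- lines[grepl("^(ATOM|HETATM)", lines)]
  if (!length(lines)) stop("no ATOM/HETATM records in PQR file: ", file)
  fields <- strsplit(trimws(lines), "\\s+")
  nf <- vapply(fields, length, integer(1))
  if (any(nf < 10)) stop("malformed PQR record (fewer than 10 fields)")
  get <- function(i) vapply(fields, `[[`, character(1), i)
  # fields: record serial name resname [chain] resnum x y z charge radius
  has_chain <- nf == 11
  name <- toupper(get(3))
  resname <- toupper(get(4))
  chain <- ifelse(has_chain, get(5), "A")
  off <- ifelse(has_chain, 1L, 0L)
  num_at <- function(i) as.numeric(mapply(`[[`, fields, i))
  resnum <- as.integer(num_at(5 + off))
  x <- num_at(6 + off); y <- num_at(7 + off); z <- num_at(8 + off)
  charge <- num_at(9 + off)
  radius <- num_at(10 + off)
  # atom names like CA/CB are carbons; a two-letter element is assumed
  # only for monoatomic ions whose atom name equals the residue name
  is_ion <- name %in% names(VDW_RADII) & name == resname
  elem <- ifelse(is_ion, name, substr(gsub("^[0-9]", "", name), 1, 1))
  atom_set(
    coord = cbind(x, y, z), element = elem, chain = chain,
    resnum = resnum, resname = resname, atom_name = name,
    charge = charge, vdw_radius = ifelse(radius > 0, radius, NA),
    is_ligand = grepl("^HETATM", lines) & !(resname %in% c("HOH", "WAT"))
  )
}

#' Write an atom set to PDB
#'
#' @param atoms An `atom_set`.
#' @param file Output path.
#' @export
write_structure <- function(atoms, file) {
  type <- ifelse(atoms$is_ligand, "HETATM", "ATOM")
  bio3d::write.pdb(
    file = file,
    type = type,
    xyz = as.numeric(t(atom_coords(atoms))),
    resno = atoms$resnum,
    resid = atoms$resname,
    eleno = atoms$id,
    elety = atoms$atom_name,
    chain = atoms$chain,
    elesy = atoms$element
  )
  invisible(file)
}
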