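# Reading PDB coordinate files into the internal atom table and computing
# centered radial geometry. All downstream similarities work on the radial
# distance of each atom from the structure's geometric center.

#' Construct a protein structure object
#'
#' A `protein_structure` is an identifier plus an ordered atom table with one
#' row per accepted coordinate record: element symbol, Cartesian coordinates
#' (in the source file's native length unit), residue name, residue sequence
#' number and chain identifier.
#'
#' @param id Single character identifier.
#' @param atoms `data.frame` with columns `element`, `x`, `y`, `z`,
#'   `resname`, `resno`, `chain`.
#' @return An object of class `protein_structure`.
#' @export
protein_structure <- function(id, atoms) {
  stopifnot(is.character(id), length(id) == 1L, is.data.frame(atoms))
  need <- c("element", "x", "y", "z", "resname", "resno", "chain")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols) > 0L) {
    stop("atom table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(atoms) < 1L) stop("a protein structure must contain at least one atom")
  if (!all(is.finite(atoms$x)) || !all(is.finite(atoms$y)) || !all(is.finite(atoms$z))) {
    stop("atom coordinates must be finite")
  }
  if (any(!nzchar(atoms$element))) stop("every atom needs a non-empty element symbol")
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms), class = "protein_structure")
}

#' @export
print.protein_structure <- function(x, ...) {
  cat(sprintf("<protein_structure> %s: %d atoms, %d residues, elements: %s\n",
              x$id, nrow(x$atoms),
              length(unique(paste(x$atoms$chain, x$atoms$resno))),
              paste(sort(unique(x$atoms$element)), collapse = " ")))
  invisible(x)
}

# Three-letter codes of the 20 standard amino acids.
STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

WATER_RESNAMES <- c("HOH", "WAT", "DOD", "H2O")

# Fallback when the element column (cols 77-78) is blank: strip digits from
# the atom-name field and take its first letter. Correct for standard
# protein atoms (CA -> C); files with metals should carry the element column.
.element_from_atom_name <- function(name) {
  cleaned <- toupper(gsub("[^A-Za-z]", "", name))
  substr(cleaned, 1L, 1L)
}

#' Read a PDB-format structure file
#'
#' Parses fixed-column ATOM/HETATM coordinate records (via bio3d) into a
#' [protein_structure]. Defaults keep ATOM records only, drop HETATM groups
#' and waters, keep hydrogens if present, use the first model of multi-model
#' files, and keep only the first alternate location of each atom. The
#' element symbol is taken from the element column, falling back to the
#' atom-name field when blank.
#'
#' @param path Path to a PDB-format file.
#' @param id Structure identifier; defaults to the file name without
#'   extension.
#' @param include_hetatm Keep non-water HETATM records? Default `FALSE`.
#' @param include_water Keep water residues? Default `FALSE`.
#' @param include_hydrogens Keep hydrogen atoms? Default `TRUE`.
#' @return A [protein_structure].
#' @export
read_structure <- function(path, id = NULL,
                           include_hetatm = FALSE,
                           include_water = FALSE,
                           include_hydrogens = TRUE) {
  if (!file.exists(path)) stop("structure file not found: ", path)
  if (is.null(id)) id <- sub("\\.[^.]*$", "", basename(path))

  # Pre-scan so malformed coordinate lines are reported with their line number.
  lines <- readLines(path, warn = FALSE)
  is_coord <- grepl("^(ATOM  |HETATM)", lines)
  if (!any(is_coord)) stop("no ATOM/HETATM records in ", path)
  too_short <- which(is_coord & nchar(lines) < 54L)
  if (length(too_short) > 0L) {
    stop(sprintf("malformed coordinate record at line %d of %s (record shorter than the coordinate columns)",
                 too_short[1L], path))
  }

  pdb <- tryCatch(
    bio3d::read.pdb(path, multi = FALSE, rm.alt = TRUE, verbose = FALSE),
    error = function(e) stop("failed to parse PDB file ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  at <- pdb$atom

  keep <- rep(TRUE, nrow(at))
  is_water <- at$resid %in% WATER_RESNAMES
  if (!include_water) keep <- keep & !is_water
  if (!include_hetatm) keep <- keep & (at$type == "ATOM")
  at <- at[keep, , drop = FALSE]

  element <- trimws(as.character(at$elesy))
  blank <- is.na(element) | !nzchar(element)
  element[blank] <- .element_from_atom_name(at$elety[blank])
  element <- toupper(element)

  if (!include_hydrogens) {
    hyd <- element %in% c("H", "D")
    at <- at[!hyd, , drop = FALSE]
    element <- element[!hyd]
  }

  if (nrow(at) == 0L) stop("no atoms accepted from ", path,
                           " under the current record filters")

  chain <- as.character(at$chain)
  chain[is.na(chain) | !nzchar(chain)] <- "A"
  protein_structure(id, data.frame(
    element = element,
    x = at$x, y = at$y, z = at$z,
    resname = as.character(at$resid),
    resno = as.integer(at$resno),
    chain = chain,
    stringsAsFactors = FALSE
  ))
}

#' Write a structure as a minimal PDB-format file
#'
#' Emits column-correct ATOM records (coordinates to 0.001 units, element in
#' columns 77-78) so that the file round-trips through [read_structure()].
#' Intended for synthetic fixtures; occupancy and B-factor are written as
#' placeholders.
#'
#' @param s A [protein_structure].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path) {
  stopifnot(inherits(s, "protein_structure"))
  a <- s$atoms
  name <- ifelse(nchar(a$element) == 1L, paste0(" ", a$element), a$element)
  recs <- sprintf("ATOM  %5d %-4s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
                  seq_len(nrow(a)) %% 100000L, name, a$resname,
                  substr(a$chain, 1L, 1L), a$resno %% 10000L,
                  a$x, a$y, a$z, 1.0, 0.0,
                  formatC(a$element, width = 2, flag = " "))
  writeLines(c(recs, "END"), path)
  invisible(path)
}

#' Geometric center of a structure
#'
#' Unweighted arithmetic mean of the atom coordinates; every atom counts
#' equally regardless of element.
#'
#' @param s A [protein_structure].
#' @return Numeric 3-vector (x, y, z).
#' @export
geometric_center <- function(s) {
  stopifnot(inherits(s, "protein_structure"))
  c(x = mean(s$atoms$x), y = mean(s$atoms$y), z = mean(s$atoms$z))
}

#' Radial distance of each atom from the geometric center
#'
#' Euclidean distances, order-preserving with respect to the atom table.
#' Translating all coordinates by a constant vector leaves the result
#' unchanged, since the center moves with the atoms.
#'
#' @param s A [protein_structure].
#' @return Non-negative numeric vector, one entry per atom.
#' @export
radial_distances <- function(s) {
  stopifnot(inherits(s, "protein_structure"))
  ctr <- geometric_center(s)
  sqrt((s$atoms$x - ctr[[1]])^2 + (s$atoms$y - ctr[[2]])^2 + (s$atoms$z - ctr[[3]])^2)
}
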