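# IUPAC 2021 standard atomic weights for the elements that occur in
# protein crystal structures (Da).
ATOMIC_MASSES <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
  P = 30.974, SE = 78.971, FE = 55.845, ZN = 65.38, MG = 24.305,
  `NA` = 22.99, K = 39.098, CA = 40.078, CL = 35.45, MN = 54.938
)

# Mainchain heavy-atom names; hydrogens bonded to these inherit the
# backbone role (names assigned by protonate()).
BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")
BACKBONE_H <- c("H", "H1", "H2", "H3", "HA", "HA1", "HA2", "HA3", "HXT", "HN")

#' Assign backbone/side-chain roles from PDB atom names
#'
#' Backbone is the \{N, CA, C, O, OXT\} set plus hydrogens attached to it
#' (H, H1-H3, HA, HA2/HA3, HXT); every other atom is side chain.
#'
#' @param atom_name character vector of PDB atom names.
#' @return character vector, `"backbone"` or `"sidechain"`.
#' @export
assign_roles <- function(atom_name) {
  ifelse(atom_name %in% c(BACKBONE_ATOMS, BACKBONE_H), "backbone", "sidechain")
}

element_from_name <- function(atom_name) {
  # PDB amino-acid atom names start with the element letter once leading
  # digits are stripped (e.g. "1HB" -> H, "CA" -> C for ATOM records).
  stripped <- sub("^[0-9]+", "", atom_name)
  toupper(substr(stripped, 1L, 1L))
}

#' Construct a structure model
#'
#' The container used throughout the package: an atom table plus the bulk
#' quantities N (atom count), V (bounding-box volume, Angstrom^3) and
#' rho0 = N/V (number density) that normalise the pair distribution
#' function.
#'
#' @param atoms data.frame with columns `element`, `atom_name`,
#'   `residue_index` (1-based position in the chain), `residue_name`,
#'   `chain_id`, `x`, `y`, `z` (Angstrom) and optionally `role`
#'   (`"backbone"`/`"sidechain"`; derived from `atom_name` when absent).
#' @param label free-text label for reports.
#' @param box_margin margin in Angstrom added on every side of the
#'   axis-aligned bounding box before computing V (default 0).
#' @param volume optional explicit box volume in Angstrom^3, overriding the
#'   bounding-box convention (used e.g. for ideal-gas clouds whose box is
#'   known exactly).
#' @return object of class `structure_model` with fields `atoms`, `label`,
#'   `N`, `V`, `rho0`, `box_margin`.  For degenerate geometries (all atoms
#'   coplanar) `V` and `rho0` are `NA`; [bulk_properties()] then errors.
#' @export
structure_model <- function(atoms, label = "structure", box_margin = 0,
                            volume = NULL) {
  stopifnot(is.data.frame(atoms))
  needed <- c("element", "atom_name", "residue_index", "residue_name",
              "chain_id", "x", "y", "z")
  missing_cols <- setdiff(needed, names(atoms))
  if (length(missing_cols) > 0L)
    stop("atoms is missing columns: ", paste(missing_cols, collapse = ", "))
  if (nrow(atoms) < 1L) stop("structure must contain at least one atom (N >= 1)")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  if (!all(is.finite(xyz))) stop("non-finite atom coordinates")
  blank <- is.na(atoms$element) | atoms$element == ""
  if (any(blank)) atoms$element[blank] <- element_from_name(atoms$atom_name[blank])
  atoms$element <- toupper(atoms$element)
  if (is.null(atoms$role)) atoms$role <- assign_roles(atoms$atom_name)
  rownames(atoms) <- NULL

  n <- nrow(atoms)
  if (is.null(volume)) {
    span <- apply(xyz, 2L, function(v) diff(range(v))) + 2 * box_margin
    volume <- prod(span)
  }
  if (!is.finite(volume) || volume <= 0) volume <- NA_real_
  structure(
    list(atoms = atoms, label = label, N = n, V = volume,
         rho0 = if (is.na(volume)) NA_real_ else n / volume,
         box_margin = box_margin),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model> %s: %d atoms, %d residues",
              x$label, x$N, length(unique(x$atoms$residue_index))))
  if (!is.na(x$V))
    cat(sprintf(", V = %.1f A^3, rho0 = %.6f atoms/A^3", x$V, x$rho0))
  cat("\n")
  invisible(x)
}

coords <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

#' Read a PDB file into a structure model
#'
#' Parses ATOM (and optionally HETATM) records with wwPDB v3.3 fixed
#' columns.  Alternate locations are resolved to a single conformer
#' (altloc `' '` or `'A'` kept).  Residues are renumbered 1..n in order of
#' appearance within the selected chain.
#'
#' @param path PDB file.
#' @param chain single-character chain identifier, or `NULL` for all
#'   chains (e.g. when reading a whole pMHC-TCR complex).
#' @param include_hydrogens keep H atoms?  Off by default: X-ray entries
#'   are unprotonated and stray H records are dropped.
#' @param include_het keep HETATM records (waters, ligands)?  Default
#'   `FALSE`, matching a water-free cleft assumption.
#' @param label label for the model; defaults to file base name.
#' @param box_margin passed to [structure_model()].
#' @return a [structure_model()].
#' @export
read_pdb <- function(path, chain = NULL, include_hydrogens = FALSE,
                     include_het = FALSE, label = NULL, box_margin = 0) {
  if (!file.exists(path)) stop("PDB file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1L, 6L)
  keep <- rec == "ATOM  " | (include_het & rec == "HETATM")
  lines <- lines[keep]
  if (length(lines) == 0L)
    stop("no ATOM records in ", path, " (chain absent/empty)")

  fld <- function(a, b) trimws(substr(lines, a, b))
  altloc <- substr(lines, 17L, 17L)
  atoms <- data.frame(
    atom_name = fld(13L, 16L),
    residue_name = fld(18L, 20L),
    chain_id = substr(lines, 22L, 22L),
    resseq = fld(23L, 27L),   # includes insertion code column
    x = as.numeric(fld(31L, 38L)),
    y = as.numeric(fld(39L, 46L)),
    z = as.numeric(fld(47L, 54L)),
    element = toupper(fld(77L, 78L)),
    stringsAsFactors = FALSE
  )
  atoms <- atoms[altloc %in% c(" ", "A"), , drop = FALSE]
  if (!is.null(chain)) {
    atoms <- atoms[atoms$chain_id == chain, , drop = FALSE]
    if (nrow(atoms) == 0L)
      stop("chain '", chain, "' absent/empty in ", path)
  }
  blank <- atoms$element == ""
  atoms$element[blank] <- element_from_name(atoms$atom_name[blank])
  if (!include_hydrogens)
    atoms <- atoms[!(atoms$element %in% c("H", "D")), , drop = FALSE]
  if (nrow(atoms) == 0L)
    stop("zero atoms after filtering in ", path)

  key <- paste(atoms$chain_id, atoms$resseq, sep = "|")
  atoms$residue_index <- match(key, unique(key))
  atoms$resseq <- NULL
  atoms$role <- assign_roles(atoms$atom_name)
  if (is.null(label))
    label <- sub("\\.[^.]*$", "", basename(path))
  structure_model(atoms, label = label, box_margin = box_margin)
}

#' Write a structure model to a PDB file
#'
#' Emits standards-conformant ATOM records (coordinates at 3 decimals,
#' element right-justified in columns 77-78).  Errors on more than 9999
#' atoms rather than overflowing the serial field.
#'
#' @param s a [structure_model()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(s, path) {
  a <- s$atoms
  if (nrow(a) > 9999L)
    stop("PDB serial field overflow: structure has ", nrow(a), " atoms (> 9999)")
  pad_name <- function(nm) {
    # single-letter elements start in column 14
    ifelse(nchar(nm) >= 4L, substr(nm, 1L, 4L), sprintf(" %-3s", nm))
  }
  lines <- sprintf(
    "ATOM  %5d %4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), pad_name(a$atom_name), a$residue_name,
    substr(paste0(a$chain_id, " "), 1L, 1L), a$residue_index,
    a$x, a$y, a$z, 1.0, 0.0, a$element
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(lines, "END"), con)
  invisible(path)
}

#' Extract a peptide plus its environment shell
#'
#' Returns the peptide atoms together with every non-peptide atom of the
#' complex lying within `cutoff` of at least one peptide atom, e.g. the
#' cleft environment "up to 7 A from each of the peptide atoms".
#' Peptide atoms are registered against the complex by coordinates
#' (1e-3 A tolerance), so the peptide model may have been read separately.
#'
#' @param complex structure model of the full complex.
#' @param peptide structure model of the peptide chain.
#' @param cutoff shell radius in Angstrom (> 0).
#' @param box_margin passed to the returned model.
#' @return a [structure_model()] containing the peptide atoms followed by
#'   the shell atoms, without duplicates.
#' @export
extract_environment <- function(complex, peptide, cutoff, box_margin = 0) {
  if (!inherits(complex, "structure_model") || !inherits(peptide, "structure_model"))
    stop("complex and peptide must be structure_model objects")
  if (peptide$N < 1L) stop("empty peptide")
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be positive")
  pc <- coords(peptide)
  cc <- coords(complex)
  # registration: complex atoms coinciding with peptide atoms (<= 1e-3 A)
  keyp <- apply(round(pc, 3L), 1L, paste, collapse = ",")
  keyc <- apply(round(cc, 3L), 1L, paste, collapse = ",")
  is_pep <- keyc %in% keyp
  other <- which(!is_pep)
  if (length(other) == 0L)
    return(structure_model(peptide$atoms,
                           label = paste0(peptide$label, "+shell", cutoff),
                           box_margin = box_margin))
  oc <- cc[other, , drop = FALSE]
  d2min <- rep(Inf, nrow(oc))
  for (i in seq_len(nrow(pc))) {
    d2 <- (oc[, 1L] - pc[i, 1L])^2 + (oc[, 2L] - pc[i, 2L])^2 +
          (oc[, 3L] - pc[i, 3L])^2
    d2min <- pmin(d2min, d2)
  }
  shell_idx <- other[d2min <= cutoff^2]
  shell <- complex$atoms[shell_idx, , drop = FALSE]
  if (nrow(shell) > 0L) {
    # keep shell residues distinguishable from peptide residues
    shell$residue_index <- shell$residue_index + max(peptide$atoms$residue_index)
  }
  structure_model(rbind(peptide$atoms, shell),
                  label = paste0(peptide$label, "+shell", cutoff),
                  box_margin = box_margin)
}

#' Bulk properties of a structure
#'
#' @param s a [structure_model()].
#' @return list with `N` (atoms), `V` (Angstrom^3, axis-aligned bounding
#'   box plus the model's margin), `rho0` = N/V (atoms/Angstrom^3) and
#'   `mass_density` (g/cm^3, via 1 Da/Angstrom^3 = 1.66054 g/cm^3).
#' @export
bulk_properties <- function(s) {
  stopifnot(inherits(s, "structure_model"))
  if (is.na(s$V))
    stop("degenerate geometry: bounding-box volume is zero ",
         "(collinear/coplanar atoms)")
  m <- ATOMIC_MASSES[s$atoms$element]
  if (anyNA(m))
    stop("unknown element(s): ",
         paste(unique(s$atoms$element[is.na(m)]), collapse = ", "))
  list(N = s$N, V = s$V, rho0 = s$rho0,
       mass_density = sum(m) / s$V * 1.66054)
}

#' Distance between the terminal alpha carbons
#'
#' Euclidean distance in Angstrom between the CA atoms of the first and
#' last residues, a coarse measure of peptide confinement.
#'
#' @param s a [structure_model()].
#' @export
terminal_ca_distance <- function(s) {
  a <- s$atoms
  r1 <- min(a$residue_index); r2 <- max(a$residue_index)
  ca1 <- a[a$residue_index == r1 & a$atom_name == "CA", , drop = FALSE]
  ca2 <- a[a$residue_index == r2 & a$atom_name == "CA", , drop = FALSE]
  if (nrow(ca1) == 0L) stop("no CA atom on N-terminal residue")
  if (nrow(ca2) == 0L) stop("no CA atom on C-terminal residue")
  sqrt(sum((as.numeric(ca1[1L, c("x", "y", "z")]) -
            as.numeric(ca2[1L, c("x", "y", "z")]))^2))
}
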