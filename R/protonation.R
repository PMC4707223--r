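# Geometric protonation: saturate heavy atoms of standard residues with
# hydrogens at ideal sp2/sp3 geometry.  This is a deterministic stand-in
# for quantum-chemical H relaxation: heavy atoms never move, X-H bond
# lengths are exact by construction, rotatable hydrogens are staggered
# (trans) relative to the heavy-atom frame.  H-partial statistics built
# on these positions are therefore qualitative.

# hydrogens carried by each side-chain heavy atom (pH-7 states:
# Asp/Glu deprotonated, Lys/Arg protonated, His neutral Ne2-H tautomer)
H_TABLE <- list(
  ALA = c(CB = 3),
  ARG = c(CB = 2, CG = 2, CD = 2, NE = 1, NH1 = 2, NH2 = 2),
  ASN = c(CB = 2, ND2 = 2),
  ASP = c(CB = 2),
  CYS = c(CB = 2, SG = 1),
  GLN = c(CB = 2, CG = 2, NE2 = 2),
  GLU = c(CB = 2, CG = 2),
  GLY = c(),
  HIS = c(CB = 2, CD2 = 1, CE1 = 1, NE2 = 1),
  ILE = c(CB = 1, CG1 = 2, CG2 = 3, CD1 = 3),
  LEU = c(CB = 2, CG = 1, CD1 = 3, CD2 = 3),
  LYS = c(CB = 2, CG = 2, CD = 2, CE = 2, NZ = 3),
  MET = c(CB = 2, CG = 2, CE = 3),
  PHE = c(CB = 2, CD1 = 1, CD2 = 1, CE1 = 1, CE2 = 1, CZ = 1),
  PRO = c(CB = 2, CG = 2, CD = 2),
  SER = c(CB = 2, OG = 1),
  THR = c(CB = 1, OG1 = 1, CG2 = 3),
  TRP = c(CB = 2, CD1 = 1, NE1 = 1, CE3 = 1, CZ2 = 1, CZ3 = 1, CH2 = 1),
  TYR = c(CB = 2, CD1 = 1, CD2 = 1, CE1 = 1, CE2 = 1, OH = 1),
  VAL = c(CB = 1, CG1 = 3, CG2 = 3)
)

# planar NH2 groups (in the sp2 plane of the attached carbon)
SP2_NH2 <- c("ARG.NH1", "ARG.NH2", "ASN.ND2", "GLN.NE2")

#' Protonation scheme
#'
#' @param zwitterion protonate the N-terminal amine to NH3+ (NH2+ for an
#'   N-terminal proline) and leave the C-terminal carboxylate bare
#'   (COO-)?  When `FALSE` the termini are neutral (NH2 / COOH).
#' @param deprotonate_phenols remove the tyrosine hydroxyl hydrogen (the
#'   "u" stereochemical variants)?
#' @param bond_lengths X-H distances in Angstrom by heavy element.
#' @return object of class `protonation_scheme`.
#' @export
protonation_scheme <- function(zwitterion = TRUE, deprotonate_phenols = FALSE,
                               bond_lengths = c(C = 1.09, N = 1.01,
                                                O = 0.96, S = 1.34)) {
  if (any(bond_lengths <= 0 | bond_lengths >= 1.5))
    stop("every X-H bond length must be in (0, 1.5) Angstrom")
  structure(list(zwitterion = zwitterion,
                 deprotonate_phenols = deprotonate_phenols,
                 bond_lengths = bond_lengths),
            class = "protonation_scheme")
}

heavy_bond_cutoff <- function(el_a, el_b) {
  ifelse(el_a == "S" | el_b == "S", 1.95, 1.75)
}

h_name_for <- function(heavy_name, idx, n_total) {
  if (heavy_name == "N") {
    if (n_total == 1L) return("H")
    return(paste0("H", idx))
  }
  if (heavy_name == "OXT") return("HXT")
  base <- paste0("H", sub("^[A-Z]", "", heavy_name))
  if (n_total == 1L) base else paste0(base, idx)
}

place_hydrogens <- function(X, nbs, ref, nH, d, sp2_nh2 = FALSE) {
  # X: position of heavy atom; nbs: matrix of bonded heavy positions;
  # ref: position of a neighbour-of-neighbour (may be NULL); nH: count;
  # d: X-H bond length.  Returns nH x 3 matrix.
  k <- nrow(nbs)
  us <- t(apply(nbs, 1L, function(p) unit3(p - X)))
  fallback_perp <- function(v) {
    w <- cross3(v, c(1, 0, 0))
    if (sum(w^2) < 1e-8) w <- cross3(v, c(0, 1, 0))
    unit3(w)
  }
  if (k >= 3L && nH == 1L) {
    dir <- -colSums(us[1:3, , drop = FALSE])
    if (sum(dir^2) < 1e-8) dir <- cross3(us[1L, ], us[2L, ])
    return(matrix(X + d * unit3(dir), nrow = 1L))
  }
  if (k == 2L && nH == 1L) {
    dir <- -(us[1L, ] + us[2L, ])
    if (sum(dir^2) < 1e-8) dir <- fallback_perp(us[1L, ])
    return(matrix(X + d * unit3(dir), nrow = 1L))
  }
  if (k == 2L && nH == 2L) {
    b <- -(us[1L, ] + us[2L, ])
    b <- if (sum(b^2) < 1e-8) fallback_perp(us[1L, ]) else unit3(b)
    p <- unit3(cross3(us[1L, ], us[2L, ]))
    half <- 54.75 * pi / 180
    return(rbind(X + d * (cos(half) * b + sin(half) * p),
                 X + d * (cos(half) * b - sin(half) * p)))
  }
  if (k == 1L) {
    B <- nbs[1L, ]
    if (sp2_nh2 && !is.null(ref)) {
      u <- unit3(X - B)
      w <- (ref - B) - sum((ref - B) * u) * u
      w <- if (sum(w^2) < 1e-8) fallback_perp(u) else unit3(w)
      s3 <- sqrt(3) / 2
      return(rbind(X + d * (0.5 * u + s3 * w),
                   X + d * (0.5 * u - s3 * w)))
    }
    if (is.null(ref)) ref <- B + fallback_perp(unit3(X - B))
    tors <- switch(as.character(nH), "1" = 180, "2" = c(180, 60),
                   "3" = c(180, 60, -60))
    return(do.call(rbind, lapply(tors, function(t)
      nerf(ref, B, X, d, 109.47, t))))
  }
  stop("unsupported hydrogen geometry: ", k, " heavy neighbours, ",
       nH, " hydrogens")
}

#' Add hydrogens to an unprotonated structure
#'
#' Saturates every heavy atom of the standard residues with the hydrogen
#' count expected at neutral pH, at ideal geometry with the scheme's
#' bond lengths.  Heavy-atom coordinates are unchanged bit for bit.  A
#' zwitterionic scheme puts 3 H on the N-terminal amine and none on the
#' carboxylate; `deprotonate_phenols` drops each tyrosine OH hydrogen.
#'
#' @param s a [structure_model()] without hydrogens, standard residues
#'   only.
#' @param scheme a [protonation_scheme()].
#' @return a protonated [structure_model()].
#' @export
protonate <- function(s, scheme = protonation_scheme()) {
  stopifnot(inherits(s, "structure_model"),
            inherits(scheme, "protonation_scheme"))
  a <- s$atoms
  if (any(a$element == "H"))
    stop("structure already contains hydrogens; protonate() expects an ",
         "unprotonated input")
  unknown <- setdiff(unique(a$residue_name), names(H_TABLE))
  if (length(unknown) > 0L)
    stop("unknown residue(s): ", paste(unknown, collapse = ", "))

  xyz <- coords(s)
  n <- nrow(a)
  # heavy-atom bond graph from interatomic distances
  d <- as.matrix(stats::dist(xyz))
  cut <- outer(a$element, a$element, heavy_bond_cutoff)
  bonded <- d > 0.1 & d < cut
  nb_list <- lapply(seq_len(n), function(i) which(bonded[i, ]))

  first_res <- min(a$residue_index)
  last_res <- max(a$residue_index)
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    heavy <- a[i, ]
    rows[[i]] <- list(heavy = heavy, h = NULL)
    nm <- heavy$atom_name; rn <- heavy$residue_name
    nH <- 0L
    if (nm == "N") {
      if (heavy$residue_index == first_res) {
        nH <- if (rn == "PRO") 2L else 3L
        if (!scheme$zwitterion) nH <- nH - 1L
      } else nH <- if (rn == "PRO") 0L else 1L
    } else if (nm == "CA") {
      nH <- if (rn == "GLY") 2L else 1L
    } else if (nm == "OXT") {
      nH <- if (scheme$zwitterion) 0L else 1L
    } else if (nm %in% c("C", "O")) {
      nH <- 0L
    } else {
      tab <- H_TABLE[[rn]]
      if (nm %in% names(tab)) nH <- as.integer(tab[[nm]])
      if (rn == "TYR" && nm == "OH" && scheme$deprotonate_phenols) nH <- 0L
    }
    if (nH == 0L) next

    nbs_idx <- nb_list[[i]]
    if (length(nbs_idx) == 0L)
      stop("atom ", nm, " in residue ", heavy$residue_index,
           " has no bonded heavy neighbour; cannot place H")
    ref <- NULL
    # reference atom two bonds away, for torsion-placed hydrogens
    bnb <- nb_list[[nbs_idx[1L]]]
    bnb <- setdiff(bnb, i)
    if (length(bnb) > 0L) ref <- xyz[min(bnb), ]
    dlen <- scheme$bond_lengths[[heavy$element]]
    if (is.null(dlen) || is.na(dlen))
      stop("no X-H bond length for element ", heavy$element)
    hp <- place_hydrogens(xyz[i, ], xyz[nbs_idx, , drop = FALSE], ref, nH,
                          dlen, sp2_nh2 = paste(rn, nm, sep = ".") %in% SP2_NH2)
    hdf <- data.frame(
      element = "H",
      atom_name = vapply(seq_len(nH), h_name_for, character(1),
                         heavy_name = nm, n_total = nH),
      residue_index = heavy$residue_index, residue_name = rn,
      chain_id = heavy$chain_id,
      x = hp[, 1L], y = hp[, 2L], z = hp[, 3L],
      role = heavy$role, stringsAsFactors = FALSE
    )
    rows[[i]]$h <- hdf
  }
  out <- do.call(rbind, lapply(rows, function(r) {
    if (is.null(r$h)) r$heavy else rbind(r$heavy, r$h)
  }))
  rownames(out) <- NULL
  structure_model(out, label = paste0(s$label, "_protonated"),
                  box_margin = s$box_margin)
}
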