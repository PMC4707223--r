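# Seeded generators for download-free validation inputs: peptide-like
# chains with realistic first-shell bond lengths (C-C ~1.5, C-N ~1.3 A),
# planted over-/under-coordinated variants, ideal-gas clouds and toy PDB
# files.
#
# Chains are built from internal coordinates (NeRF placement) with
# idealized bond lengths/angles and randomized torsions under a clash
# floor; realism is limited to what the pipeline's statistics can sense
# (bond-length peaks, density, backbone/side-chain structure) - no
# rotamer libraries, no force field.

unit3 <- function(v) v / sqrt(sum(v^2))
cross3 <- function(a, b) c(a[2L] * b[3L] - a[3L] * b[2L],
                           a[3L] * b[1L] - a[1L] * b[3L],
                           a[1L] * b[2L] - a[2L] * b[1L])

# Place atom X bonded to C with |CX| = bond, angle(B,C,X) = ang (deg) and
# dihedral(A,B,C,X) = tors (deg).
nerf <- function(A, B, C, bond, ang, tors) {
  th <- ang * pi / 180
  ta <- tors * pi / 180
  bc <- unit3(C - B)
  n <- unit3(cross3(B - A, bc))
  m <- cross3(n, bc)
  d <- c(-bond * cos(th), bond * sin(th) * cos(ta), bond * sin(th) * sin(ta))
  C + bc * d[1L] + m * d[2L] + n * d[3L]
}

AA_CODES <- c(A = "ALA", R = "ARG", F = "PHE", G = "GLY", L = "LEU",
              P = "PRO", V = "VAL", Y = "TYR")

# Side-chain heavy-atom templates (internal coordinates).  Each row:
# atom name, element, three reference atoms already placed in the same
# residue, bond length (A), bond angle (deg), torsion (deg; expressions
# may use the per-residue random torsions t1..t3).
sidechain_template <- function(resname) {
  T <- function(...) {
    m <- matrix(c(...), ncol = 6L, byrow = TRUE)
    data.frame(name = m[, 1L], el = m[, 2L], a = m[, 3L], b = m[, 4L],
               c = m[, 5L], geom = m[, 6L], stringsAsFactors = FALSE)
  }
  # geom column packs "bond|angle|torsion"
  switch(resname,
    ALA = T("CB", "C", "C", "N", "CA", "1.52|110.4|-122"),
    VAL = T("CB", "C", "C", "N", "CA", "1.54|110.4|-122",
            "CG1", "C", "N", "CA", "CB", "1.52|110.5|t1",
            "CG2", "C", "N", "CA", "CB", "1.52|110.5|t1+120"),
    LEU = T("CB", "C", "C", "N", "CA", "1.53|110.4|-122",
            "CG", "C", "N", "CA", "CB", "1.53|116.3|t1",
            "CD1", "C", "CA", "CB", "CG", "1.52|110.7|t2",
            "CD2", "C", "CA", "CB", "CG", "1.52|110.7|t2+120"),
    PHE = T("CB", "C", "C", "N", "CA", "1.53|110.4|-122",
            "CG", "C", "N", "CA", "CB", "1.51|113.8|t1",
            "CD1", "C", "CA", "CB", "CG", "1.39|120.8|t2",
            "CD2", "C", "CA", "CB", "CG", "1.39|120.8|t2+180",
            "CE1", "C", "CB", "CG", "CD1", "1.39|120.6|180",
            "CE2", "C", "CB", "CG", "CD2", "1.39|120.6|180",
            "CZ", "C", "CG", "CD1", "CE1", "1.39|120.0|0"),
    TYR = T("CB", "C", "C", "N", "CA", "1.53|110.4|-122",
            "CG", "C", "N", "CA", "CB", "1.51|113.8|t1",
            "CD1", "C", "CA", "CB", "CG", "1.39|120.8|t2",
            "CD2", "C", "CA", "CB", "CG", "1.39|120.8|t2+180",
            "CE1", "C", "CB", "CG", "CD1", "1.39|120.6|180",
            "CE2", "C", "CB", "CG", "CD2", "1.39|120.6|180",
            "CZ", "C", "CG", "CD1", "CE1", "1.39|120.0|0",
            "OH", "O", "CD1", "CE1", "CZ", "1.38|119.9|180"),
    GLY = NULL,
    ARG = T("CB", "C", "C", "N", "CA", "1.53|110.4|-122",
            "CG", "C", "N", "CA", "CB", "1.52|114.1|t1",
            "CD", "C", "CA", "CB", "CG", "1.52|111.5|t2",
            "NE", "N", "CB", "CG", "CD", "1.46|112.0|t3",
            "CZ", "C", "CG", "CD", "NE", "1.33|124.5|-178",
            "NH1", "N", "CD", "NE", "CZ", "1.33|120.0|0",
            "NH2", "N", "CD", "NE", "CZ", "1.33|120.0|180"),
    NULL
  )
}

# Proline's pyrrolidine ring (CB, CG, CD closing back onto N): the
# pucker torsions (magnitudes fixed so the CD-N closure lands near
# 1.5 A) flip sign together via the random variable p1 = +/-1, giving
# the two mirror puckers as retry variability.
PRO_TEMPLATE <- data.frame(
  name = c("CB", "CG", "CD"), el = c("C", "C", "C"),
  a = c("C", "N", "CA"), b = c("N", "CA", "CB"), c = c("CA", "CB", "CG"),
  geom = c("1.53|103.2|-120*p1", "1.50|104.5|31*p1", "1.51|105.5|-37*p1"),
  stringsAsFactors = FALSE
)

# ring-closure bonds not implied by the placement order
EXTRA_BONDS <- list(
  PHE = list(c("CZ", "CE2")), TYR = list(c("CZ", "CE2")),
  PRO = list(c("CD", "N"))
)

parse_geom <- function(g, env) {
  p <- strsplit(g, "|", fixed = TRUE)[[1L]]
  tors <- eval(parse(text = p[3L]), envir = env)
  list(bond = as.numeric(p[1L]), angle = as.numeric(p[2L]), tors = tors)
}

#' Specification for a synthetic peptide-like chain
#'
#' The stated world of the generator: 9-residue chains whose
#' backbone bond lengths put the first-shell C-C peak at 1.5 A and the
#' C-N peak at 1.3 A, with per-residue side-chain sizes mirroring a
#' 9-mer epitope (4,4,7,0,8,3,3,8,3 heavy atoms).
#'
#' @param n_residues chain length (default 9).
#' @param seed RNG seed; fixed seed gives bit-identical output.
#' @param backbone_lengths named bond lengths in Angstrom
#'   (`N-CA`, `CA-C`, `C-N`, `C-O`).
#' @param sidechain_sizes integer vector of side-chain heavy-atom counts
#'   per residue (recycled); ignored when `sequence` is given.
#' @param sequence optional one-letter sequence (subset of ARFGLPVY) to
#'   build idealized standard residues instead of generic chains.
#' @param scale_factor uniform dilation applied by [make_variant()]
#'   defaults.
#' @return object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_residues = 9, seed = 1,
                           backbone_lengths = c("N-CA" = 1.46, "CA-C" = 1.52,
                                                "C-N" = 1.33, "C-O" = 1.23),
                           sidechain_sizes = NULL, sequence = NULL,
                           scale_factor = 1) {
  if (!is.null(sequence)) {
    letters1 <- strsplit(sequence, "")[[1L]]
    if (!all(letters1 %in% names(AA_CODES)))
      stop("sequence may only contain ", paste(names(AA_CODES), collapse = ""),
           " (idealized templates available for these residues)")
    n_residues <- length(letters1)
  }
  if (n_residues < 1L) stop("n_residues must be >= 1")
  if (scale_factor <= 0) stop("scale_factor must be > 0")
  needed <- c("N-CA", "CA-C", "C-N", "C-O")
  if (!all(needed %in% names(backbone_lengths)))
    stop("backbone_lengths must name ", paste(needed, collapse = ", "))
  if (any(backbone_lengths <= 0)) stop("bond lengths must be positive")
  if (is.null(sidechain_sizes))
    sidechain_sizes <- c(4L, 4L, 7L, 0L, 8L, 3L, 3L, 8L, 3L)
  sizes <- rep_len(as.integer(sidechain_sizes), n_residues)
  structure(
    list(n_residues = as.integer(n_residues), seed = as.integer(seed),
         backbone_lengths = backbone_lengths, sidechain_sizes = sizes,
         sequence = sequence, scale_factor = scale_factor),
    class = "synthetic_spec"
  )
}

GENERIC_SC_NAMES <- c("CB", "CG", "CD", "CE", "CZ", "CH", "CI", "CK")
GENERIC_SC_TORS <- c("-122", "t1", "t2", "t3", "t1+120", "t2+120",
                     "t3+120", "t1-120")

generic_template <- function(size) {
  if (size < 1L) return(NULL)
  if (size > length(GENERIC_SC_NAMES))
    stop("generic side chains support at most ", length(GENERIC_SC_NAMES),
         " heavy atoms")
  rows <- lapply(seq_len(size), function(k) {
    if (k == 1L)
      c("CB", "C", "C", "N", "CA", "1.52|110.4|-122")
    else if (k == 2L)
      c("CG", "C", "N", "CA", "CB", paste0("1.52|112.0|", GENERIC_SC_TORS[2L]))
    else {
      prev <- if (k == 3L) c("CA", "CB", "CG")
              else GENERIC_SC_NAMES[(k - 3L):(k - 1L)]
      c(GENERIC_SC_NAMES[k], "C", prev[1L], prev[2L], prev[3L],
        paste0("1.52|112.0|", GENERIC_SC_TORS[k]))
    }
  })
  m <- do.call(rbind, rows)
  data.frame(name = m[, 1L], el = m[, 2L], a = m[, 3L], b = m[, 4L],
             c = m[, 5L], geom = m[, 6L], stringsAsFactors = FALSE)
}

graph_within2 <- function(adj, i) {
  n1 <- adj[[i]]
  unique(c(i, n1, unlist(adj[n1])))
}

#' Generate a synthetic peptide-like chain
#'
#' Builds a self-avoiding chain from idealized internal coordinates with
#' randomized backbone/side-chain torsions.  Species are labeled C/N/O
#' and roles backbone/side chain, so every analysis in the package can
#' run on the result.  Deterministic under the spec's seed.
#'
#' @param spec a [synthetic_spec()].
#' @param label model label (default derived from the spec).
#' @param max_tries torsion redraws allowed per residue before declaring
#'   the geometry impossible (clash floor 2.4 A between atoms more than
#'   two bonds apart).
#' @return a [structure_model()].
#' @export
make_chain <- function(spec, label = NULL, max_tries = 80L,
                       max_restarts = 25L) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  last_err <- NULL
  for (attempt in seq_len(max_restarts)) {
    out <- tryCatch(build_chain_once(spec, label, max_tries),
                    error = function(e) e)
    if (!inherits(out, "error")) return(out)
    last_err <- out
  }
  stop(conditionMessage(last_err), " (after ", max_restarts,
       " chain restarts)")
}

build_chain_once <- function(spec, label, max_tries) {
  bl <- spec$backbone_lengths
  n_res <- spec$n_residues
  resnames <- if (!is.null(spec$sequence))
    AA_CODES[strsplit(spec$sequence, "")[[1L]]]
  else rep("UNK", n_res)
  if (is.null(label))
    label <- if (!is.null(spec$sequence)) paste0(spec$sequence, "_synthetic")
             else sprintf("chain%d_seed%d", n_res, spec$seed)

  xyz <- matrix(NA_real_, nrow = 0L, ncol = 3L)
  name <- character(0); el <- character(0); res <- integer(0)
  rnm <- character(0)
  adj <- list()
  clash_floor <- 2.4

  add_atom <- function(nm, e, ri, rn, pos, bond_to) {
    xyz <<- rbind(xyz, pos)
    name <<- c(name, nm); el <<- c(el, e); res <<- c(res, ri)
    rnm <<- c(rnm, rn)
    k <- nrow(xyz)
    adj[[k]] <<- integer(0)
    for (b in bond_to) {
      adj[[k]] <<- c(adj[[k]], b)
      adj[[b]] <<- c(adj[[b]], k)
    }
    k
  }
  find_in_res <- function(nm, ri) which(name == nm & res == ri)[1L]

  snapshot <- function() list(xyz = xyz, name = name, el = el, res = res,
                              rnm = rnm, adj = adj)
  restore <- function(st) {
    xyz <<- st$xyz; name <<- st$name; el <<- st$el; res <<- st$res
    rnm <<- st$rnm; adj <<- st$adj
  }

  clash_free <- function(first_new) {
    n <- nrow(xyz)
    if (first_new > n) return(TRUE)
    for (k in seq.int(first_new, n)) {
      excl <- graph_within2(adj, k)
      others <- setdiff(seq_len(k - 1L), excl)
      if (length(others) == 0L) next
      d2 <- (xyz[others, 1L] - xyz[k, 1L])^2 +
            (xyz[others, 2L] - xyz[k, 2L])^2 +
            (xyz[others, 3L] - xyz[k, 3L])^2
      if (any(d2 < clash_floor^2)) return(FALSE)
    }
    TRUE
  }

  for (i in seq_len(n_res)) {
    rn <- resnames[i]
    placed <- FALSE
    st <- snapshot()
    for (try in seq_len(max_tries)) {
      restore(st)
      first_new <- nrow(xyz) + 1L
      wide <- try > max_tries %/% 2  # widen sampling if the region is tight
      phi <- if (rn == "PRO") -65 + stats::rnorm(1L, 0, 8)
             else if (wide) stats::runif(1L, -160, -50)
             else -120 + stats::rnorm(1L, 0, 25)
      psi <- if (wide) stats::runif(1L, 60, 180)
             else 135 + stats::rnorm(1L, 0, 25)
      tenv <- list2env(list(
        t1 = sample(c(-60, 60, 180), 1L) + stats::rnorm(1L, 0, 8),
        t2 = sample(c(-60, 60, 180), 1L) + stats::rnorm(1L, 0, 8),
        t3 = sample(c(-60, 60, 180), 1L) + stats::rnorm(1L, 0, 8),
        p1 = sample(c(1, -1), 1L)
      ))

      if (i == 1L) {
        iN <- add_atom("N", "N", i, rn, c(0, 0, 0), integer(0))
        iCA <- add_atom("CA", "C", i, rn, c(bl[["N-CA"]], 0, 0), iN)
        dummy <- c(0, 0, 1)
        posC <- nerf(dummy, xyz[iN, ], xyz[iCA, ], bl[["CA-C"]], 111.0,
                     stats::runif(1L, -180, 180))
        iC <- add_atom("C", "C", i, rn, posC, iCA)
      } else {
        # N was already placed (and clash-checked) in iteration i-1
        iN <- find_in_res("N", i)
        iCp <- find_in_res("C", i - 1L)
        iCAp <- find_in_res("CA", i - 1L)
        posCA <- nerf(xyz[iCAp, ], xyz[iCp, ], xyz[iN, ], bl[["N-CA"]],
                      121.7, 180)  # omega = 180, trans peptide bond
        iCA <- add_atom("CA", "C", i, rn, posCA, iN)
        posC <- nerf(xyz[iCp, ], xyz[iN, ], xyz[iCA, ], bl[["CA-C"]],
                     111.0, phi)
        iC <- add_atom("C", "C", i, rn, posC, iCA)
      }

      tmpl <- if (rn == "UNK") generic_template(spec$sidechain_sizes[i])
              else if (rn == "PRO") PRO_TEMPLATE
              else sidechain_template(rn)
      ok <- TRUE
      if (!is.null(tmpl) && nrow(tmpl) > 0L) {
        for (j in seq_len(nrow(tmpl))) {
          g <- parse_geom(tmpl$geom[j], tenv)
          ia <- find_in_res(tmpl$a[j], i); ib <- find_in_res(tmpl$b[j], i)
          ic <- find_in_res(tmpl$c[j], i)
          if (anyNA(c(ia, ib, ic))) { ok <- FALSE; break }
          pos <- nerf(xyz[ia, ], xyz[ib, ], xyz[ic, ], g$bond, g$angle,
                      g$tors)
          add_atom(tmpl$name[j], tmpl$el[j], i, rn, pos, ic)
        }
      }
      if (ok && rn %in% names(EXTRA_BONDS)) {
        for (eb in EXTRA_BONDS[[rn]]) {
          k1 <- find_in_res(eb[1L], i); k2 <- find_in_res(eb[2L], i)
          adj[[k1]] <- c(adj[[k1]], k2); adj[[k2]] <- c(adj[[k2]], k1)
        }
      }

      if (ok) {
        if (i < n_res) {
          # next residue's N and this residue's carbonyl O both hang off
          # psi, so they are placed (and clash-checked) now
          posNn <- nerf(xyz[iN, ], xyz[iCA, ], xyz[iC, ], bl[["C-N"]],
                        116.2, psi)
          iNn <- add_atom("N", "N", i + 1L, resnames[i + 1L], posNn, iC)
          posO <- nerf(xyz[iNn, ], xyz[iCA, ], xyz[iC, ], bl[["C-O"]],
                       121.0, 180)  # anti to the next N
          add_atom("O", "O", i, rn, posO, iC)
        } else {
          # C-terminal carboxylate in the CA-C plane
          posO <- nerf(xyz[iN, ], xyz[iCA, ], xyz[iC, ], bl[["C-O"]],
                       117.0, psi + 180)
          add_atom("O", "O", i, rn, posO, iC)
          posOXT <- nerf(xyz[iN, ], xyz[iCA, ], xyz[iC, ], bl[["C-O"]],
                         117.0, psi)
          add_atom("OXT", "O", i, rn, posOXT, iC)
        }
      }

      if (ok && clash_free(first_new)) {
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("impossible geometry: clash tolerance exceeded after ",
           max_tries, " retries at residue ", i)
  }

  ord <- order(res)  # stable: keeps placement order within each residue
  xyz <- xyz[ord, , drop = FALSE]
  name <- name[ord]; el <- el[ord]; res <- res[ord]; rnm <- rnm[ord]

  atoms <- data.frame(
    element = el, atom_name = name, residue_index = res,
    residue_name = rnm, chain_id = "A",
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    stringsAsFactors = FALSE
  )
  structure_model(atoms, label = label)
}

#' Idealized synthetic stand-in for a real peptide
#'
#' Convenience wrapper around [synthetic_spec()] + [make_chain()] for a
#' one-letter sequence, producing standard residue/atom names so that
#' protonation and backbone/side-chain decomposition behave as they
#' would on a crystal structure.  The result is a geometric stand-in
#' (idealized bonds, random torsions), not a crystal conformation, and
#' is labelled `"<sequence>_synthetic"` to make that explicit.
#'
#' @param sequence one-letter sequence over ARFGLPVY, e.g. "LLFGYPVYV".
#' @param seed RNG seed.
#' @param label optional label override.
#' @return a [structure_model()].
#' @export
synthetic_peptide <- function(sequence, seed = 1, label = NULL) {
  make_chain(synthetic_spec(sequence = sequence, seed = seed), label = label)
}

#' Planted variant of a base structure
#'
#' Either dilates all coordinates about the centroid by `scale_factor`
#' (f > 1 lengthens every pair distance, planting under-coordination;
#' f < 1 plants over-coordination), or compacts a single residue's side
#' chain toward its CA, planting a known dominant interaction group for
#' decomposition tests.
#'
#' @param base a [structure_model()].
#' @param scale_factor uniform dilation factor f > 0 about the centroid.
#' @param perturb_residue optional residue index; only that residue's
#'   side-chain atoms are moved (scaled about the residue's CA by
#'   `compact`), `scale_factor` is then ignored.
#' @param compact side-chain compaction factor used with
#'   `perturb_residue` (default 0.7).
#' @param seed seed for the optional coordinate jitter.
#' @param jitter s.d. in Angstrom of Gaussian noise added to the moved
#'   atoms (default 0 = deterministic).
#' @param label label for the variant.
#' @return a [structure_model()].
#' @export
make_variant <- function(base, scale_factor = 1, perturb_residue = NULL,
                         compact = 0.7, seed = 1, jitter = 0,
                         label = NULL) {
  stopifnot(inherits(base, "structure_model"))
  if (scale_factor <= 0) stop("scale_factor must be > 0")
  a <- base$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  set.seed(seed)
  if (is.null(perturb_residue)) {
    ctr <- colMeans(xyz)
    xyz <- sweep(sweep(xyz, 2L, ctr), 2L, rep(scale_factor, 3L), `*`)
    xyz <- sweep(xyz, 2L, ctr, `+`)
    moved <- seq_len(nrow(xyz))
    if (is.null(label))
      label <- sprintf("%s_f%.3f", base$label, scale_factor)
  } else {
    if (!perturb_residue %in% a$residue_index)
      stop("residue index ", perturb_residue, " out of range")
    ca <- which(a$residue_index == perturb_residue & a$atom_name == "CA")
    if (length(ca) == 0L)
      stop("residue ", perturb_residue, " has no CA to compact about")
    ctr <- xyz[ca[1L], ]
    moved <- which(a$residue_index == perturb_residue & a$role == "sidechain")
    if (length(moved) == 0L)
      stop("residue ", perturb_residue, " has no side-chain atoms")
    xyz[moved, ] <- sweep(sweep(xyz[moved, , drop = FALSE], 2L, ctr), 2L,
                          rep(compact, 3L), `*`)
    xyz[moved, ] <- sweep(xyz[moved, , drop = FALSE], 2L, ctr, `+`)
    if (is.null(label))
      label <- sprintf("%s_res%dcompact", base$label, perturb_residue)
  }
  if (jitter > 0)
    xyz[moved, ] <- xyz[moved, , drop = FALSE] +
      matrix(stats::rnorm(3L * length(moved), 0, jitter), ncol = 3L)
  a$x <- xyz[, 1L]; a$y <- xyz[, 2L]; a$z <- xyz[, 3L]
  structure_model(a, label = label, box_margin = base$box_margin)
}

#' Uniform random atom cloud (ideal-gas oracle)
#'
#' i.i.d. uniform positions in a cubic box; for such a cloud g(r) is to
#' 1 up to edge effects and Monte Carlo noise, which makes it the
#' normalization oracle for the PDF.  The model's volume is the exact
#' box volume (not the bounding box).
#'
#' @param n number of atoms (>= 2).
#' @param box cube edge in Angstrom.
#' @param seed RNG seed.
#' @param element species label for all atoms (default "C").
#' @return a [structure_model()].
#' @export
make_ideal_gas <- function(n, box, seed = 1, element = "C") {
  if (n < 2L) stop("n must be >= 2")
  if (box <= 0) stop("box must be > 0")
  set.seed(seed)
  xyz <- matrix(stats::runif(3L * n, 0, box), ncol = 3L)
  atoms <- data.frame(
    element = element, atom_name = element, residue_index = seq_len(n),
    residue_name = "GAS", chain_id = "A",
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    role = "sidechain", stringsAsFactors = FALSE
  )
  structure_model(atoms, label = sprintf("gas%d_seed%d", n, seed),
                  volume = box^3)
}

#' Surround a peptide with a synthetic environment shell
#'
#' Plants `n_decoys` environment atoms at radial distances drawn
#' uniformly from `band` (measured from randomly chosen peptide atoms,
#' rejecting positions closer than 2.4 A to any peptide atom), emulating
#' a cleft/complex around a synthetic peptide for scale-dependence
#' checks.
#'
#' @param peptide a [structure_model()].
#' @param n_decoys number of environment atoms.
#' @param band radial band c(rmin, rmax) in Angstrom (default c(4, 10)).
#' @param seed RNG seed.
#' @param element decoy species (default "C").
#' @return a [structure_model()] of peptide + environment; decoy residues
#'   are numbered after the peptide's.
#' @export
make_decoy_complex <- function(peptide, n_decoys, band = c(4, 10), seed = 1,
                               element = "C") {
  stopifnot(inherits(peptide, "structure_model"))
  if (band[1L] <= 0 || band[2L] <= band[1L]) stop("invalid radial band")
  set.seed(seed)
  pxyz <- coords(peptide)
  res0 <- max(peptide$atoms$residue_index)
  out <- matrix(NA_real_, nrow = n_decoys, ncol = 3L)
  k <- 0L; guard <- 0L
  while (k < n_decoys && guard < 200L * n_decoys) {
    guard <- guard + 1L
    anchor <- pxyz[sample.int(nrow(pxyz), 1L), ]
    u <- stats::rnorm(3L); u <- u / sqrt(sum(u^2))
    pos <- anchor + u * stats::runif(1L, band[1L], band[2L])
    dmin <- min(sqrt((pxyz[, 1L] - pos[1L])^2 + (pxyz[, 2L] - pos[2L])^2 +
                     (pxyz[, 3L] - pos[3L])^2))
    if (dmin >= 2.4 && (k == 0L ||
        min(sqrt((out[seq_len(k), 1L] - pos[1L])^2 +
                 (out[seq_len(k), 2L] - pos[2L])^2 +
                 (out[seq_len(k), 3L] - pos[3L])^2)) >= 2.4)) {
      k <- k + 1L
      out[k, ] <- pos
    }
  }
  if (k < n_decoys) stop("could not place decoy shell without clashes")
  decoys <- data.frame(
    element = element, atom_name = element,
    residue_index = res0 + seq_len(n_decoys), residue_name = "ENV",
    chain_id = "E", x = out[, 1L], y = out[, 2L], z = out[, 3L],
    role = "sidechain", stringsAsFactors = FALSE
  )
  pa <- peptide$atoms
  structure_model(rbind(pa, decoys),
                  label = paste0(peptide$label, "_complex"))
}

#' Write a synthetic structure as a toy PDB file
#'
#' Alias of [write_pdb()]; coordinates are preserved to the format's
#' 3 decimals and the file round-trips through [read_pdb()].
#'
#' @param s a [structure_model()].
#' @param path output file.
#' @export
write_toy_pdb <- function(s, path) write_pdb(s, path)
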