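# Builders and independent brute-force oracles shared across tests.
# The oracles deliberately avoid the package's histogram/binning code
# path: they enumerate atom pairs directly.

toy_structure <- function(xyz, elements = "C", atom_names = NULL,
                          residue_index = NULL, residue_name = "UNK",
                          roles = NULL, label = "toy", volume = NULL) {
  xyz <- matrix(xyz, ncol = 3L)
  n <- nrow(xyz)
  elements <- rep_len(elements, n)
  if (is.null(atom_names)) atom_names <- elements
  if (is.null(residue_index)) residue_index <- seq_len(n)
  atoms <- data.frame(
    element = elements, atom_name = rep_len(atom_names, n),
    residue_index = rep_len(residue_index, n),
    residue_name = rep_len(residue_name, n), chain_id = "A",
    x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
    stringsAsFactors = FALSE
  )
  if (!is.null(roles)) atoms$role <- rep_len(roles, n)
  structure_model(atoms, label = label, volume = volume)
}

# all unordered pair distances for a species selection, by enumeration
brute_pair_distances <- function(s, selector = "total") {
  a <- s$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  out <- numeric(0)
  for (i in seq_len(nrow(a) - 1L)) {
    for (j in seq.int(i + 1L, nrow(a))) {
      pair <- sort(c(a$element[i], a$element[j]))
      if (identical(selector, "total") ||
          identical(pair, sort(strsplit(selector, "-")[[1L]])))
        out <- c(out, sqrt(sum((xyz[i, ] - xyz[j, ])^2)))
    }
  }
  out
}

# cumulative coordination at distance r by pair counting: every pair
# below r is shared by two atoms, so n(0, r) = 2 * #pairs(d < r) / N
brute_cumulative <- function(s, r, selector = "total") {
  d <- brute_pair_distances(s, selector)
  2 * sum(d < r) / s$N
}

random_rigid_transform <- function(s, seed = 1) {
  set.seed(seed)
  # random rotation via QR of a Gaussian matrix
  qr_ <- qr(matrix(rnorm(9L), 3L))
  R <- qr.Q(qr_)
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  t_ <- runif(3L, -20, 20)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% R
  xyz <- sweep(xyz, 2L, t_, `+`)
  a <- s$atoms
  a$x <- xyz[, 1L]; a$y <- xyz[, 2L]; a$z <- xyz[, 3L]
  structure_model(a, label = paste0(s$label, "_moved"))
}

# a small random heterogeneous structure with no duplicate positions
random_structure <- function(n, seed, box = 8, elements = c("C", "N", "O")) {
  set.seed(seed)
  toy_structure(matrix(runif(3L * n, 0, box), ncol = 3L),
                elements = sample(elements, n, replace = TRUE),
                label = sprintf("rand%d_%d", n, seed))
}

# hand-written wwPDB v3.3 fixture: two chains, an altloc pair, a
# hydrogen, and a HETATM water, with known coordinates
TOY_PDB_LINES <- c(
  "HEADER    TEST STRUCTURE",
  "ATOM      1  N   ALA A   1       0.000   0.000   0.000  1.00  0.00           N",
  "ATOM      2  CA  ALA A   1       1.458   0.000   0.000  1.00  0.00           C",
  "ATOM      3  C   ALA A   1       2.009   1.420   0.000  1.00  0.00           C",
  "ATOM      4  O   ALA A   1       1.251   2.390   0.123  1.00  0.00           O",
  "ATOM      5  CB AALA A   1       1.988  -0.773  -1.199  0.60  0.00           C",
  "ATOM      6  CB BALA A   1       1.990  -0.775  -1.201  0.40  0.00           C",
  "ATOM      7  HA  ALA A   1       1.800  -0.520   0.890  1.00  0.00           H",
  "ATOM      8  N   GLY A   2       3.320   1.540  -0.100  1.00  0.00           N",
  "ATOM      9  CA  GLY A   2       3.985   2.835  -0.123  1.00  0.00           C",
  "ATOM     10  C   GLY A   2       5.480   2.700   0.050  1.00  0.00           C",
  "ATOM     11  O   GLY A   2       6.020   1.600   0.200  1.00  0.00           O",
  "ATOM     12  OXT GLY A   2       6.150   3.740   0.010  1.00  0.00           O",
  "ATOM     13  N   LEU B   1      10.000  10.000  10.000  1.00  0.00           N",
  "ATOM     14  CA  LEU B   1      11.458  10.000  10.000  1.00  0.00           C",
  "HETATM   15  O   HOH A 101       8.000   8.000   8.000  1.00  0.00           O",
  "END"
)

write_toy_pdb_fixture <- function(path = tempfile(fileext = ".pdb")) {
  writeLines(TOY_PDB_LINES, path)
  path
}
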