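test_that("read_pdb parses fixed columns, resolves altlocs, filters H/HETATM", {
  path <- write_toy_pdb_fixture()
  s <- read_pdb(path, chain = "A")
  expect_s3_class(s, "structure_model")
  expect_equal(s$N, 10L)                       # no H, no water, altloc A only
  expect_equal(s$atoms$x[1L], 0)
  expect_equal(s$atoms$x[2L], 1.458)
  expect_equal(sum(s$atoms$atom_name == "CB"), 1L)   # altloc B dropped
  expect_equal(unique(s$atoms$chain_id), "A")
  expect_equal(max(s$atoms$residue_index), 2L)

  expect_equal(read_pdb(path, chain = "A", include_hydrogens = TRUE)$N, 11L)
  expect_equal(read_pdb(path, include_het = TRUE)$N, 13L)
  expect_equal(read_pdb(path, chain = "B")$N, 2L)
})

test_that("read_pdb failure modes are distinct and descriptive", {
  expect_error(read_pdb(tempfile()), "not found")
  path <- write_toy_pdb_fixture()
  expect_error(read_pdb(path, chain = "Z"), "chain 'Z' absent")
  empty <- tempfile(fileext = ".pdb")
  writeLines(c("HEADER    NOTHING", "END"), empty)
  expect_error(read_pdb(empty), "no ATOM records")
})

test_that("write_pdb round-trips synthetic structures at 3 decimals", {
  s <- make_chain(synthetic_spec(n_residues = 3, seed = 11))
  path <- tempfile(fileext = ".pdb")
  write_toy_pdb(s, path)
  back <- read_pdb(path, chain = "A")
  expect_equal(back$N, s$N)
  expect_equal(back$atoms$element, s$atoms$element)
  expect_equal(back$atoms$atom_name, s$atoms$atom_name)
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               round(as.matrix(s$atoms[, c("x", "y", "z")]), 3L),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("backbone/side-chain partition is exhaustive with 4 mainchain heavies", {
  s <- synthetic_peptide("LLFGYPVYV", seed = 3)
  a <- s$atoms
  expect_true(all(a$role %in% c("backbone", "sidechain")))
  for (ri in unique(a$residue_index)) {
    bb <- a$atom_name[a$residue_index == ri & a$role == "backbone"]
    expect_setequal(setdiff(bb, "OXT"), c("N", "CA", "C", "O"))
  }
  # terminal OXT rides on the backbone of the last residue
  expect_true("OXT" %in% a$atom_name[a$residue_index == 9L])
})

test_that("bulk_properties: analytic box, exact rho0*V = N, degenerate error", {
  cube <- toy_structure(as.matrix(expand.grid(0:1, 0:1, 0:1)))
  bp <- bulk_properties(cube)
  expect_equal(bp$V, 1)
  expect_equal(bp$rho0, 8)
  expect_identical(bp$rho0 * bp$V, as.numeric(bp$N))

  s <- make_chain(synthetic_spec(n_residues = 4, seed = 2))
  bp2 <- bulk_properties(s)
  expect_equal(bp2$rho0 * bp2$V, as.numeric(bp2$N), tolerance = 1e-12)

  flat <- toy_structure(cbind(runif(5), runif(5), 0))
  expect_error(bulk_properties(flat), "degenerate")
})

test_that("mass density / number density ratio equals mean atomic mass", {
  # convention-independent oracle: the box volume cancels in the ratio
  s <- synthetic_peptide("LLFGYPVYV", seed = 5)
  bp <- bulk_properties(s)
  masses <- c(C = 12.011, N = 14.007, O = 15.999)
  expect_equal(bp$mass_density / bp$rho0, mean(masses[s$atoms$element]) * 1.66054,
               tolerance = 1e-12)
})

test_that("terminal_ca_distance: 3-4-5 toy, rigid-motion invariance, errors", {
  two <- toy_structure(rbind(c(0, 0, 0), c(3, 4, 0)),
                       elements = "C", atom_names = "CA",
                       residue_index = c(1L, 2L), residue_name = "GLY")
  expect_equal(terminal_ca_distance(two), 5)

  s <- synthetic_peptide("LLFGYPVYV", seed = 1)
  d0 <- terminal_ca_distance(s)
  expect_gt(d0, 15); expect_lt(d0, 32)   # extended 9-mer scale
  expect_equal(terminal_ca_distance(random_rigid_transform(s, 4)), d0,
               tolerance = 1e-9)

  noca <- toy_structure(rbind(c(0, 0, 0), c(3, 4, 0)),
                        atom_names = c("N", "CA"), residue_index = c(1L, 2L))
  expect_error(terminal_ca_distance(noca), "N-terminal")
})

test_that("extract_environment keeps exactly the atoms within the cutoff", {
  pep <- make_chain(synthetic_spec(n_residues = 3, seed = 8))
  pxyz <- as.matrix(pep$atoms[, c("x", "y", "z")])
  # decoys planted at known distances from peptide atom 1, pointing away
  # from the chain so atom 1 is their nearest peptide atom
  u <- pxyz[1L, ] - colMeans(pxyz)
  u <- u / sqrt(sum(u^2))
  decoys <- rbind(pxyz[1L, ] + 6.9 * u, pxyz[1L, ] + 7.1 * u)
  # ensure the planted distances are the decoys' minimum distances
  stopifnot(min(sqrt(rowSums(sweep(pxyz, 2, decoys[1L, ])^2))) > 6.89,
            min(sqrt(rowSums(sweep(pxyz, 2, decoys[2L, ])^2))) > 7.09)
  comp <- toy_structure(rbind(pxyz, decoys),
                        elements = c(pep$atoms$element, "C", "C"),
                        atom_names = c(pep$atoms$atom_name, "C", "C"),
                        residue_index = c(pep$atoms$residue_index, 90L, 91L),
                        residue_name = c(pep$atoms$residue_name, "ENV", "ENV"))
  shell <- extract_environment(comp, pep, cutoff = 7)
  expect_equal(shell$N, pep$N + 1L)   # only the 6.9 A decoy

  # brute-force oracle over a decoy cloud + monotonicity in cutoff
  comp2 <- make_decoy_complex(pep, 40, band = c(3, 12), seed = 2)
  for (cutoff in c(4, 7)) {
    shell2 <- extract_environment(comp2, pep, cutoff)
    cxyz <- as.matrix(comp2$atoms[, c("x", "y", "z")])
    dec <- cxyz[-seq_len(pep$N), , drop = FALSE]
    n_in <- sum(apply(dec, 1L, function(p)
      min(sqrt(rowSums(sweep(pxyz, 2, p)^2))) <= cutoff))
    expect_equal(shell2$N, pep$N + n_in)
  }
  s4 <- extract_environment(comp2, pep, 4)
  s7 <- extract_environment(comp2, pep, 7)
  expect_lte(s4$N, s7$N)
  key <- function(m) apply(round(as.matrix(m$atoms[, c("x", "y", "z")]), 6), 1,
                           paste, collapse = ",")
  expect_true(all(key(s4) %in% key(s7)))   # shell(c1) subset of shell(c2)

  # empty shell: all decoys out of reach -> shell identical to peptide
  far <- extract_environment(comp2, pep, 0.5)
  expect_equal(far$N, pep$N)
  expect_error(extract_environment(comp2, pep, -1), "cutoff")
})
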