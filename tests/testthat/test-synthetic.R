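test_that("synthetic_spec validates and is deterministic under seed", {
  expect_error(synthetic_spec(n_residues = 0), "n_residues")
  expect_error(synthetic_spec(scale_factor = -1), "scale_factor")
  expect_error(synthetic_spec(sequence = "LXZ"), "sequence")
  s1 <- make_chain(synthetic_spec(n_residues = 5, seed = 42))
  s2 <- make_chain(synthetic_spec(n_residues = 5, seed = 42))
  expect_identical(s1$atoms, s2$atoms)
  s3 <- make_chain(synthetic_spec(n_residues = 5, seed = 43))
  expect_false(identical(s1$atoms, s3$atoms))
})

test_that("generated chains carry the specified bond lengths", {
  s <- make_chain(synthetic_spec(n_residues = 6, seed = 7))
  a <- s$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  at <- function(nm, ri) xyz[which(a$atom_name == nm & a$residue_index == ri)[1L], ]
  for (ri in 1:6) {
    expect_equal(sqrt(sum((at("N", ri) - at("CA", ri))^2)), 1.46,
                 tolerance = 1e-6)
    expect_equal(sqrt(sum((at("CA", ri) - at("C", ri))^2)), 1.52,
                 tolerance = 1e-6)
    expect_equal(sqrt(sum((at("C", ri) - at("O", ri))^2)), 1.23,
                 tolerance = 1e-6)
    if (ri < 6)  # peptide bond C(i)-N(i+1)
      expect_equal(sqrt(sum((at("C", ri) - at("N", ri + 1L))^2)), 1.33,
                   tolerance = 1e-6)
  }
  # self-avoidance: atoms more than two bonds apart keep their distance
  d <- as.matrix(dist(xyz))
  diag(d) <- Inf
  expect_gt(min(d), 1.2)   # nothing closer than a bond
})

test_that("first-shell peaks of generated chains land on 1.5 and 1.3 A", {
  for (seed in c(1, 23)) {
    s <- make_chain(synthetic_spec(seed = seed))
    expect_equal(first_shell_peak(pdf_from_histogram(
      build_histogram(s, "C-C"))), 1.5)
    expect_equal(first_shell_peak(pdf_from_histogram(
      build_histogram(s, "C-N"))), 1.3)
  }
})

test_that("make_variant: identity, density scaling, residue perturbation", {
  s <- make_chain(synthetic_spec(n_residues = 5, seed = 19))
  same <- make_variant(s, scale_factor = 1)
  expect_equal(as.matrix(same$atoms[, c("x", "y", "z")]),
               as.matrix(s$atoms[, c("x", "y", "z")]), tolerance = 1e-12)

  up <- make_variant(s, scale_factor = 1.05)
  expect_equal(up$rho0, s$rho0 / 1.05^3, tolerance = 1e-9)
  expect_equal(up$V, s$V * 1.05^3, tolerance = 1e-9)

  pert <- make_variant(s, perturb_residue = 3)
  moved <- which(abs(pert$atoms$x - s$atoms$x) > 1e-12)
  expect_true(all(s$atoms$residue_index[moved] == 3L))
  expect_true(all(s$atoms$role[moved] == "sidechain"))
  expect_error(make_variant(s, perturb_residue = 99), "out of range")
  expect_error(make_variant(s, scale_factor = 0), "scale_factor")
})

test_that("ideal gas generator is seeded and uses the exact box volume", {
  g1 <- make_ideal_gas(100, 20, seed = 5)
  g2 <- make_ideal_gas(100, 20, seed = 5)
  expect_identical(g1$atoms, g2$atoms)
  expect_equal(g1$V, 8000)
  expect_equal(g1$rho0, 100 / 8000)
  two <- make_ideal_gas(2, 10, seed = 1)
  h <- build_histogram(two, r_max = 20)
  expect_equal(sum(h$counts), 1L)
  expect_error(make_ideal_gas(1, 10), "n must be")
})

test_that("toy PDB round trip preserves species, roles and coordinates", {
  s <- synthetic_peptide("GYV", seed = 2)
  path <- tempfile(fileext = ".pdb")
  write_toy_pdb(s, path)
  back <- read_pdb(path, chain = "A")
  expect_identical(back$atoms$element, s$atoms$element)
  expect_identical(back$atoms$role, s$atoms$role)
  expect_identical(back$atoms$residue_name, s$atoms$residue_name)
  expect_equal(as.matrix(back$atoms[, c("x", "y", "z")]),
               round(as.matrix(s$atoms[, c("x", "y", "z")]), 3L),
               ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("PDB serial overflow is refused", {
  big <- make_ideal_gas(10001, 200, seed = 1)
  expect_error(write_toy_pdb(big, tempfile()), "overflow")
})

test_that("decoy complexes respect the radial band", {
  pep <- make_chain(synthetic_spec(n_residues = 4, seed = 6))
  comp <- make_decoy_complex(pep, 30, band = c(4, 9), seed = 3)
  pxyz <- as.matrix(pep$atoms[, c("x", "y", "z")])
  dec <- as.matrix(comp$atoms[-seq_len(pep$N), c("x", "y", "z")])
  dmin <- apply(dec, 1L, function(p)
    min(sqrt(rowSums(sweep(pxyz, 2, p)^2))))
  expect_true(all(dmin >= 2.4))
  expect_true(all(dmin <= 9 + 1e-9))
})
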