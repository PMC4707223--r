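test_that("protonation_scheme validates bond lengths", {
  expect_error(protonation_scheme(bond_lengths = c(C = 1.6)), "1.5")
  expect_error(protonation_scheme(bond_lengths = c(C = -1)), "bond length")
  sch <- protonation_scheme()
  expect_true(sch$zwitterion)
  expect_equal(sch$bond_lengths[["C"]], 1.09)
})

test_that("alanine dipeptide hydrogen count matches valence bookkeeping", {
  # oracle, computed by hand: zwitterionic ALA-ALA
  #   res1: NH3+ (3) + HA (1) + CB (3) = 7
  #   res2: NH (1) + HA (1) + CB (3) + COO- (0) = 5
  s <- synthetic_peptide("AA", seed = 2)
  p <- protonate(s)
  expect_equal(sum(p$atoms$element == "H"), 12L)
  hs <- p$atoms[p$atoms$element == "H", ]
  expect_equal(as.integer(table(hs$residue_index)), c(7L, 5L))
  # neutral termini: one H fewer at N, one more on OXT
  pn <- protonate(s, protonation_scheme(zwitterion = FALSE))
  expect_equal(sum(pn$atoms$element == "H"), 12L)
  expect_true("HXT" %in% pn$atoms$atom_name)
  expect_false("HXT" %in% p$atoms$atom_name)
})

test_that("zwitterion carries an NH3+ terminus and a bare carboxylate", {
  p <- protonate(synthetic_peptide("LLFGYPVYV", seed = 1))
  a <- p$atoms
  nterm_h <- a[a$residue_index == 1L & a$atom_name %in% c("H1", "H2", "H3"), ]
  expect_equal(nrow(nterm_h), 3L)
  # all three within bonding distance of the terminal N
  npos <- as.numeric(a[a$residue_index == 1L & a$atom_name == "N",
                       c("x", "y", "z")])
  for (k in seq_len(3L))
    expect_equal(sqrt(sum((as.numeric(nterm_h[k, c("x", "y", "z")]) - npos)^2)),
                 1.01, tolerance = 1e-6)
  expect_equal(sum(a$atom_name == "HXT"), 0L)   # COO- keeps no H
})

test_that("X-H bond lengths are exact and heavy atoms never move", {
  s <- synthetic_peptide("LFGYV", seed = 9)
  p <- protonate(s)
  a <- p$atoms
  heavy <- a[a$element != "H", ]
  expect_identical(unname(as.matrix(heavy[, c("x", "y", "z")])),
                   unname(as.matrix(s$atoms[, c("x", "y", "z")])))
  hxyz <- as.matrix(a[a$element == "H", c("x", "y", "z")])
  hvyxyz <- as.matrix(heavy[, c("x", "y", "z")])
  sch <- protonation_scheme()
  expected <- sch$bond_lengths[c(C = "C", N = "N", O = "O")]
  for (i in seq_len(nrow(hxyz))) {
    d <- sqrt(colSums((t(hvyxyz) - hxyz[i, ])^2))
    j <- which.min(d)
    expect_equal(min(d), sch$bond_lengths[[heavy$element[j]]],
                 tolerance = 1e-6)
  }
})

test_that("protonation is guarded and phenol toggle removes one H per Tyr", {
  s <- synthetic_peptide("LLFGYPVYV", seed = 1)
  p <- protonate(s)
  expect_error(protonate(p), "already contains hydrogens")
  expect_error(protonate(make_chain(synthetic_spec(n_residues = 2, seed = 1))),
               "unknown residue")

  u <- protonate(s, protonation_scheme(deprotonate_phenols = TRUE))
  n_tyr <- length(unique(s$atoms$residue_index[s$atoms$residue_name == "TYR"]))
  expect_equal(n_tyr, 2L)
  expect_equal(sum(p$atoms$element == "H") - sum(u$atoms$element == "H"),
               n_tyr)
})

test_that("per-residue H counts follow the residue tables", {
  p <- protonate(synthetic_peptide("LLFGYPVYV", seed = 1))
  hs <- p$atoms[p$atoms$element == "H", ]
  counts <- as.integer(table(factor(hs$residue_index, levels = 1:9)))
  # L(nterm) L F G Y P V Y V with zwitterionic termini
  expect_equal(counts, c(13L, 11L, 9L, 3L, 9L, 7L, 9L, 9L, 9L))
  # proline backbone N carries no H
  expect_false(any(hs$residue_index == 6L & hs$atom_name == "H"))
  # glycine CA carries two
  expect_equal(sum(hs$residue_index == 4L & grepl("^HA", hs$atom_name)), 2L)
})
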