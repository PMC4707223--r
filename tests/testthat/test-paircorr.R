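test_that("histogram counts pairs once in half-open bins", {
  two <- toy_structure(rbind(c(0, 0, 0), c(1.5, 0, 0)))
  h <- build_histogram(two, "total", bin_size = 0.1, r_max = 3)
  expect_equal(sum(h$counts), 1L)
  expect_equal(h$counts[16L], 1L)          # bin [1.5, 1.6)

  s <- random_structure(50, seed = 21)
  h50 <- build_histogram(s, "total", r_max = 40)
  expect_equal(sum(h50$counts), 50L * 49L / 2L)     # 1225 by enumeration
  expect_true(all(h50$counts >= 0))
  expect_type(h50$counts, "integer")
})

test_that("duplicate atoms raise a descriptive error, not a bin-0 count", {
  dup <- toy_structure(rbind(c(0, 0, 0), c(0, 0, 0), c(2, 0, 0)))
  expect_error(build_histogram(dup), "duplicate atoms")
  expect_error(build_histogram(toy_structure(c(0, 0, 0))), "fewer than 2")
})

test_that("partial histograms and PDFs sum to the total (shared normalisation)", {
  s <- random_structure(80, seed = 5)
  r_max <- default_r_max(s)
  tot <- build_histogram(s, "total", r_max = r_max)
  pairs <- c("C-C", "C-N", "C-O", "N-N", "N-O", "O-O")
  part <- lapply(pairs, function(p) build_histogram(s, p, r_max = r_max))
  summed <- Reduce(`+`, lapply(part, `[[`, "counts"))
  expect_identical(summed, tot$counts)

  g_tot <- pdf_from_histogram(tot)
  g_sum <- Reduce(`+`, lapply(part, function(h) pdf_from_histogram(h)$values))
  nz <- g_tot$values > 0
  expect_equal(g_sum[nz] / g_tot$values[nz], rep(1, sum(nz)),
               tolerance = 1e-9)
})

test_that("empty bins give g = 0 and the RDF closed form holds exactly", {
  s <- random_structure(40, seed = 31)
  h <- build_histogram(s)
  g <- pdf_from_histogram(h)
  expect_true(all(g$values[h$counts == 0L] == 0))
  expect_true(all(g$values >= 0))
  R <- rdf_from_pdf(g)
  # R * dr = 2 * counts / N: the 2 pi r^2 rho0 factors cancel
  expect_equal(R$values * h$bin_size, 2 * h$counts / s$N, tolerance = 1e-9)
  expect_error(rdf_from_pdf(R), "PDF")
})

test_that("coordination windows: analytic two-atom case and N-1 identity", {
  two <- toy_structure(rbind(c(0, 0, 0), c(2.35, 0, 0)), volume = 125)
  R <- rdf_from_pdf(pdf_from_histogram(build_histogram(two, r_max = 5)))
  expect_equal(coordination(R, 0, 5), 1)     # one pair shared by two atoms
  expect_equal(coordination(R, 2, 3), 1)
  expect_equal(coordination(R, 3, 5), 0)
  expect_equal(coordination(R, 0, 2), 0)
  expect_error(coordination(R, 3, 1), "r1 < r2")
  expect_error(coordination(R, 0, 50), "beyond the computed grid")

  for (seed in 1:3) {
    s <- random_structure(35, seed = seed)
    R <- rdf_from_pdf(pdf_from_histogram(build_histogram(s)))
    expect_equal(coordination(R, 0, max(R$r) + R$bin_size / 2), s$N - 1,
                 tolerance = 1e-9)
    prof <- cumulative_profile(R)
    expect_equal(prof$n_cum[length(prof$n_cum)], s$N - 1, tolerance = 1e-9)
    expect_true(all(diff(prof$n_cum) >= 0))
  }
})

test_that("cumulative coordination equals the brute-force pair-count oracle", {
  for (seed in 1:4) {
    s <- random_structure(sample(10:60, 1L), seed = seed)
    for (sel in c("total", "C-C", "C-N")) {
      h <- try(build_histogram(s, sel), silent = TRUE)
      if (inherits(h, "try-error")) next
      prof <- cumulative_profile(rdf_from_pdf(pdf_from_histogram(h)))
      oracle <- vapply(prof$r, function(r) brute_cumulative(s, r, sel),
                       numeric(1))
      expect_equal(prof$n_cum, oracle, tolerance = 1e-9)
    }
  }
})

test_that("all derived statistics are rigid-motion invariant", {
  s <- synthetic_peptide("LFGYV", seed = 13)
  m <- random_rigid_transform(s, seed = 99)
  r_max <- default_r_max(list(s, m))
  for (sel in c("total", "C-C")) {
    h1 <- build_histogram(s, sel, r_max = r_max)
    h2 <- build_histogram(m, sel, r_max = r_max)
    expect_identical(h1$counts, h2$counts)
  }
  # volume/rho0 are box-convention dependent and may change under rotation;
  # coordination (counts-based) must not
  p1 <- cumulative_profile(rdf_from_pdf(pdf_from_histogram(
    build_histogram(s, r_max = r_max))))
  p2 <- cumulative_profile(rdf_from_pdf(pdf_from_histogram(
    build_histogram(m, r_max = r_max))))
  expect_equal(p1$n_cum, p2$n_cum, tolerance = 1e-9)
})

test_that("uniform dilation shifts coordination monotonically", {
  s <- make_chain(synthetic_spec(n_residues = 6, seed = 17))
  r_max <- default_r_max(s) * 1.2
  prof <- function(x) cumulative_profile(rdf_from_pdf(pdf_from_histogram(
    build_histogram(x, r_max = r_max))))
  p0 <- prof(s)
  up <- prof(make_variant(s, scale_factor = 1.05))
  dn <- prof(make_variant(s, scale_factor = 0.95))
  expect_true(all(up$n_cum - p0$n_cum <= 1e-12))
  expect_true(all(dn$n_cum - p0$n_cum >= -1e-12))
  d <- coordination_delta(up, p0)
  expect_true(all(d$delta <= 1e-12))
  d0 <- coordination_delta(p0, p0)
  expect_true(all(d0$delta == 0))
})

test_that("delta requires a shared grid", {
  s <- make_chain(synthetic_spec(n_residues = 4, seed = 3))
  p1 <- cumulative_profile(rdf_from_pdf(pdf_from_histogram(
    build_histogram(s, r_max = 10))))
  p2 <- cumulative_profile(rdf_from_pdf(pdf_from_histogram(
    build_histogram(s, r_max = 12))))
  expect_error(coordination_delta(p1, p2), "grid mismatch")
})

test_that("ideal-gas cloud has g close to 1 over interior bins", {
  gas <- make_ideal_gas(3000, box = 30, seed = 42)
  g <- pdf_from_histogram(build_histogram(gas, r_max = 5))
  interior <- g$r > 0.5 & g$r < 2.5
  expect_gt(mean(g$values[interior]), 0.9)
  expect_lt(mean(g$values[interior]), 1.1)
})

test_that("halving the bin size barely changes cumulative coordination at 7 A", {
  s <- synthetic_peptide("LLFGYPVYV", seed = 1)
  n_at <- function(bin) {
    R <- rdf_from_pdf(pdf_from_histogram(
      build_histogram(s, bin_size = bin, r_max = 30)))
    coordination(R, 0, 7)
  }
  expect_lt(abs(n_at(0.05) - n_at(0.1)) / n_at(0.1), 0.01)
})

test_that("first-shell peaks sit on the bonded C-C and C-N spacings", {
  s <- synthetic_peptide("LLFGYPVYV", seed = 4)
  g_cc <- pdf_from_histogram(build_histogram(s, "C-C"))
  g_cn <- pdf_from_histogram(build_histogram(s, "C-N"))
  expect_equal(first_shell_peak(g_cc), 1.5)
  expect_equal(first_shell_peak(g_cn), 1.3)
})
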