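# Pair distribution function g(r), radial distribution function
# R(r) = 4 pi r^2 rho0 g(r), and coordination n(r1,r2) = int R(r) dr.
#
# Binning convention: bin i covers the half-open interval
# [(i-1)*dr, i*dr), so a distance exactly on a boundary lands in the
# upper bin.  The 1/r^2 prefactor uses the bin centre (i - 0.5)*dr; with
# that choice the identity R(bin)*dr = 2*counts(bin)/N holds exactly and
# every coordination integral is independent of the centre convention.

selected_pair_distances <- function(s, pair_selector) {
  el <- s$atoms$element
  xyz <- coords(s)
  if (identical(pair_selector, "total")) {
    if (nrow(xyz) < 2L) stop("fewer than 2 atoms selected")
    return(as.numeric(stats::dist(xyz)))
  }
  sp <- strsplit(pair_selector, "-", fixed = TRUE)[[1L]]
  if (length(sp) != 2L)
    stop("pair_selector must be 'total' or of the form 'C-N'")
  a <- toupper(sp[1L]); b <- toupper(sp[2L])
  ia <- which(el == a); ib <- which(el == b)
  if (a == b) {
    if (length(ia) < 2L)
      stop("fewer than 2 atoms selected for pair ", pair_selector)
    return(as.numeric(stats::dist(xyz[ia, , drop = FALSE])))
  }
  if (length(ia) == 0L || length(ib) == 0L)
    stop("fewer than 2 atoms selected for pair ", pair_selector)
  xa <- xyz[ia, , drop = FALSE]; xb <- xyz[ib, , drop = FALSE]
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  sqrt(pmax(d2, 0))
}

#' Default maximum distance for a structure's histogram grid
#'
#' The structure's maximum interatomic distance rounded up to a whole bin,
#' so the full-range cumulative coordination reaches N-1.
#'
#' @param s a [structure_model()] (or list of them; the overall maximum is
#'   used so all grids are commensurate).
#' @param bin_size bin width in Angstrom.
#' @export
default_r_max <- function(s, bin_size = 0.1) {
  if (inherits(s, "structure_model")) s <- list(s)
  dmax <- max(vapply(s, function(m) {
    xyz <- coords(m)
    if (nrow(xyz) < 2L) return(bin_size)
    max(stats::dist(xyz))
  }, numeric(1)))
  ceiling(dmax / bin_size + 1e-9) * bin_size
}

#' Histogram of interatomic distances
#'
#' Counts every unordered atom pair matching the species selector whose
#' distance is below `r_max`, in bins of width `bin_size` (half-open
#' `[r, r + dr)`).  Partials share the total structure's N and rho0 so
#' that partial curves sum to the total curve bin by bin.
#'
#' @param s a [structure_model()].
#' @param pair_selector `"total"` or a species pair such as `"C-C"`,
#'   `"C-N"`, `"O-H"` (order irrelevant).
#' @param bin_size bin width dr in Angstrom (default 0.1).
#' @param r_max histogram range; default [default_r_max()] of `s`.
#' @return object of class `pair_histogram`: `bin_size`, `counts`
#'   (integer per bin), `pair_selector`, `n_atoms`, `rho0`, `label`.
#' @export
build_histogram <- function(s, pair_selector = "total", bin_size = 0.1,
                            r_max = NULL) {
  stopifnot(inherits(s, "structure_model"))
  if (!is.numeric(bin_size) || bin_size <= 0) stop("bin_size must be > 0")
  if (is.null(r_max)) r_max <- default_r_max(s, bin_size)
  if (r_max < bin_size) stop("r_max must be >= bin_size")
  d <- selected_pair_distances(s, pair_selector)
  dup <- which(d < 1e-6)
  if (length(dup) > 0L)
    stop("zero-distance pair(s) found (duplicate atoms) in '", s$label,
         "': ", length(dup), " pair(s) closer than 1e-6 A")
  nbins <- as.integer(round(r_max / bin_size))
  idx <- floor(d / bin_size + 1e-9) + 1  # half-open [r, r+dr)
  idx <- idx[idx <= nbins]
  counts <- tabulate(idx, nbins = nbins)
  structure(
    list(bin_size = bin_size, counts = as.integer(counts),
         pair_selector = pair_selector, n_atoms = s$N, rho0 = s$rho0,
         label = s$label),
    class = "pair_histogram"
  )
}

#' @export
print.pair_histogram <- function(x, ...) {
  cat(sprintf("<pair_histogram> %s [%s]: %d bins x %.2f A, %d pairs\n",
              x$label, x$pair_selector, length(x$counts), x$bin_size,
              sum(x$counts)))
  invisible(x)
}

new_curve <- function(h, values, kind) {
  structure(
    list(r = (seq_along(h$counts) - 0.5) * h$bin_size, values = values,
         kind = kind, bin_size = h$bin_size, n_atoms = h$n_atoms,
         rho0 = h$rho0, pair_selector = h$pair_selector,
         counts = h$counts, label = h$label),
    class = "correlation_curve"
  )
}

#' Pair distribution function g(r) from a histogram
#'
#' g at bin centre r is `counts / (2 pi N r^2 rho0 dr)`; for an ideal gas
#' g -> 1, and peaks mark preferred interatomic spacings (bond lengths in
#' the first coordination shell).
#'
#' @param h a [build_histogram()] result.
#' @return a `correlation_curve` with `kind = "PDF"`.
#' @export
pdf_from_histogram <- function(h) {
  stopifnot(inherits(h, "pair_histogram"))
  if (!is.finite(h$rho0) || h$rho0 <= 0)
    stop("source structure has no valid number density rho0")
  r_c <- (seq_along(h$counts) - 0.5) * h$bin_size
  g <- h$counts / (2 * pi * h$n_atoms * r_c^2 * h$rho0 * h$bin_size)
  new_curve(h, g, "PDF")
}

#' Radial distribution function R(r) from a PDF
#'
#' `R(r) = 4 pi r^2 rho0 g(r)` (atoms per Angstrom); the r^2 weight shifts
#' emphasis onto larger interatomic spacings, which is what makes the
#' 5-7 Angstrom window informative.
#'
#' @param c a PDF `correlation_curve`.
#' @return a `correlation_curve` with `kind = "RDF"`.
#' @export
rdf_from_pdf <- function(c) {
  stopifnot(inherits(c, "correlation_curve"))
  if (c$kind != "PDF") stop("input curve must have kind 'PDF'")
  out <- c
  out$values <- 4 * pi * c$r^2 * c$rho0 * c$values
  out$kind <- "RDF"
  out
}

#' @export
print.correlation_curve <- function(x, ...) {
  cat(sprintf("<correlation_curve> %s [%s] %s: %d bins x %.2f A\n",
              x$label, x$pair_selector, x$kind, length(x$r), x$bin_size))
  invisible(x)
}

#' @export
as.data.frame.correlation_curve <- function(x, ...) {
  data.frame(r = x$r, value = x$values, kind = x$kind,
             selector = x$pair_selector, structure = x$label)
}

#' Coordination number over a distance window
#'
#' Integral of R(r) over `[r1, r2)`, i.e. the sum of `R * dr` over bins
#' fully inside the window: the average number of (selector-matching)
#' atoms surrounding a reference atom at those distances.  With `r1 = 0`
#' this is the cumulative coordination.
#'
#' @param c an RDF `correlation_curve`.
#' @param r1,r2 window bounds in Angstrom, `0 <= r1 < r2`; `r2` may not
#'   exceed the computed grid.
#' @export
coordination <- function(c, r1, r2) {
  stopifnot(inherits(c, "correlation_curve"))
  if (c$kind != "RDF") stop("input curve must have kind 'RDF'")
  if (!(r1 >= 0 && r2 > r1)) stop("need 0 <= r1 < r2")
  dr <- c$bin_size
  upper <- c$r + dr / 2
  if (r2 > max(upper) + 1e-9) stop("window extends beyond the computed grid")
  lower <- c$r - dr / 2
  inside <- lower >= r1 - 1e-9 & upper <= r2 + 1e-9
  sum(c$values[inside] * dr)
}

#' Cumulative coordination profile n(0, r)
#'
#' Running sum of `R * dr`; entry i is the coordination accumulated up to
#' the upper edge of bin i.  Non-decreasing; for the total selector its
#' final value is exactly N - 1.
#'
#' @param c an RDF `correlation_curve`.
#' @return object of class `coordination_profile` with `r` (bin upper
#'   edges) and `n_cum`.
#' @export
cumulative_profile <- function(c) {
  stopifnot(inherits(c, "correlation_curve"))
  if (c$kind != "RDF") stop("input curve must have kind 'RDF'")
  structure(
    list(r = c$r + c$bin_size / 2, n_cum = cumsum(c$values * c$bin_size),
         bin_size = c$bin_size, pair_selector = c$pair_selector,
         label = c$label, n_atoms = c$n_atoms),
    class = "coordination_profile"
  )
}

#' @export
print.coordination_profile <- function(x, ...) {
  cat(sprintf(
    "<coordination_profile> %s [%s]: n(0, %.1f A) = %.3f\n",
    x$label, x$pair_selector, max(x$r), x$n_cum[length(x$n_cum)]))
  invisible(x)
}

#' @export
as.data.frame.coordination_profile <- function(x, ...) {
  data.frame(r = x$r, value = x$n_cum, kind = "coordination",
             selector = x$pair_selector, structure = x$label)
}

#' Cumulative coordination difference variant - index
#'
#' The discriminating metric: positive values mean the variant is
#' over-coordinated relative to the index at that distance, negative
#' under-coordinated.  Both profiles must share the same grid (bin size
#' and range), so compute them with a common `r_max`.
#'
#' @param variant,index [cumulative_profile()] results.
#' @return object of class `coordination_delta` with `r`, `delta`,
#'   `index_label`, `variant_label`, `pair_selector`.
#' @export
coordination_delta <- function(variant, index) {
  stopifnot(inherits(variant, "coordination_profile"),
            inherits(index, "coordination_profile"))
  if (length(variant$r) != length(index$r) ||
      max(abs(variant$r - index$r)) > 1e-9)
    stop("grid mismatch: variant and index profiles must share bin size ",
         "and r_max")
  structure(
    list(r = variant$r, delta = variant$n_cum - index$n_cum,
         index_label = index$label, variant_label = variant$label,
         pair_selector = variant$pair_selector, bin_size = variant$bin_size),
    class = "coordination_delta"
  )
}

#' @export
print.coordination_delta <- function(x, ...) {
  cat(sprintf("<coordination_delta> %s - %s [%s]: delta(%.1f A) = %+.3f\n",
              x$variant_label, x$index_label, x$pair_selector,
              max(x$r), x$delta[length(x$delta)]))
  invisible(x)
}

#' @export
as.data.frame.coordination_delta <- function(x, ...) {
  data.frame(r = x$r, value = x$delta, kind = "delta",
             selector = x$pair_selector,
             structure = paste0(x$variant_label, "-", x$index_label))
}

#' First-coordination-shell peak position
#'
#' Position of the strongest PDF peak below `r_limit`, reported as the
#' lower edge of the winning bin (distances quoted to one decimal for the
#' default 0.1 Angstrom bin, e.g. 1.5 for C-C, 1.3 for C-N bonds).
#'
#' @param c a PDF `correlation_curve`.
#' @param r_limit search limit in Angstrom (default 2.0, the first shell).
#' @export
first_shell_peak <- function(c, r_limit = 2.0) {
  stopifnot(inherits(c, "correlation_curve"))
  if (c$kind != "PDF") stop("input curve must have kind 'PDF'")
  sel <- which(c$r < r_limit)
  if (length(sel) == 0L || all(c$values[sel] == 0))
    stop("no occupied bins below ", r_limit, " A")
  best <- sel[which.max(c$values[sel])]
  # lower edge of the bin, rounded to the bin grid
  round((best - 1L) * c$bin_size, digits = max(0L, -floor(log10(c$bin_size))))
}
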