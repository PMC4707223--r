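# Short-range-order statistics of atomic clusters centred on one species.

#' Cluster statistics around a central species
#'
#' For every atom of `central` species, neighbours of any species with
#' distance `< cutoff` form its cluster.  Reports the average cluster
#' coordination number, the cluster number density and mass density
#' (spherical volume of radius `cutoff`, central atom included), and the
#' histogram-weighted mean neighbour distance
#' `sum(x_i N_i) / sum(N_i)` with `x_i` the bin centres.
#'
#' @param s a [structure_model()].
#' @param central element symbol (`"C"`, `"N"`, `"O"`, ...).
#' @param cutoff cluster radius in Angstrom (default 4, the short-range
#'   order limit).
#' @param bin_size bin width for the weighted mean (default 0.1).
#' @param interior_margin exclude central atoms closer than this to a
#'   bounding-box face (useful for bulk-density checks on uniform clouds;
#'   default 0 = use all central atoms).
#' @return object of class `species_cluster_stats`: `central_species`,
#'   `cutoff`, `n_central`, `mean_cn`, `cluster_number_density`
#'   (atoms/Angstrom^3), `cluster_mass_density` (g/cm^3),
#'   `weighted_mean_distance` (Angstrom, NA when no neighbour).
#' @export
cluster_stats <- function(s, central, cutoff = 4, bin_size = 0.1,
                          interior_margin = 0) {
  stopifnot(inherits(s, "structure_model"))
  if (!is.numeric(cutoff) || cutoff <= 0) stop("cutoff must be > 0")
  el <- toupper(s$atoms$element)
  central <- toupper(central)
  xyz <- coords(s)
  ic <- which(el == central)
  if (length(ic) == 0L)
    stop("no atoms of central species '", central, "'")
  if (interior_margin > 0) {
    rng <- apply(xyz, 2L, range)
    inner <- xyz[ic, 1L] >= rng[1L, 1L] + interior_margin &
             xyz[ic, 1L] <= rng[2L, 1L] - interior_margin &
             xyz[ic, 2L] >= rng[1L, 2L] + interior_margin &
             xyz[ic, 2L] <= rng[2L, 2L] - interior_margin &
             xyz[ic, 3L] >= rng[1L, 3L] + interior_margin &
             xyz[ic, 3L] <= rng[2L, 3L] - interior_margin
    if (!any(inner))
      stop("no central atoms remain inside the interior margin")
    ic <- ic[inner]
  }

  masses <- ATOMIC_MASSES[el]
  if (anyNA(masses))
    stop("unknown element(s): ", paste(unique(el[is.na(masses)]), collapse = ", "))
  vol <- 4 / 3 * pi * cutoff^3

  cn <- numeric(length(ic))
  cluster_mass <- numeric(length(ic))
  all_d <- vector("list", length(ic))
  for (k in seq_along(ic)) {
    i <- ic[k]
    d <- sqrt((xyz[, 1L] - xyz[i, 1L])^2 + (xyz[, 2L] - xyz[i, 2L])^2 +
              (xyz[, 3L] - xyz[i, 3L])^2)
    nb <- which(d < cutoff & seq_along(d) != i)
    cn[k] <- length(nb)
    cluster_mass[k] <- masses[i] + sum(masses[nb])
    all_d[[k]] <- d[nb]
  }
  dists <- unlist(all_d)
  wmd <- if (length(dists) == 0L) NA_real_ else {
    idx <- floor(dists / bin_size + 1e-9) + 1
    counts <- tabulate(idx)
    centers <- (seq_along(counts) - 0.5) * bin_size
    sum(centers * counts) / sum(counts)
  }
  structure(
    list(central_species = central, cutoff = cutoff, n_central = length(ic),
         mean_cn = mean(cn),
         cluster_number_density = (mean(cn) + 1) / vol,
         cluster_mass_density = mean(cluster_mass) / vol * 1.66054,
         weighted_mean_distance = wmd, label = s$label),
    class = "species_cluster_stats"
  )
}

#' @export
print.species_cluster_stats <- function(x, ...) {
  cat(sprintf(
    "<cluster_stats> %s, %s centres (n=%d, cutoff %.1f A): CN = %.2f, n-dens = %.4f /A^3, dens = %.3f g/cm^3, <r> = %.2f A\n",
    x$label, x$central_species, x$n_central, x$cutoff, x$mean_cn,
    x$cluster_number_density, x$cluster_mass_density,
    x$weighted_mean_distance))
  invisible(x)
}

#' @export
as.data.frame.species_cluster_stats <- function(x, ...) {
  data.frame(structure = x$label, central_species = x$central_species,
             cutoff = x$cutoff, n_central = x$n_central, mean_cn = x$mean_cn,
             cluster_number_density = x$cluster_number_density,
             cluster_mass_density = x$cluster_mass_density,
             weighted_mean_distance = x$weighted_mean_distance)
}
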