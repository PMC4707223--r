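# Immunological identity call from the sign of the coordination
# difference over the short-range-order window.

#' Call over-/under-coordination of a variant
#'
#' Averages the cumulative coordination difference over the window
#' (default 5-7 Angstrom, where short-range order carries the signal) and
#' maps its sign to an identity call: positive = over-coordinated
#' (agonist-like), negative = under-coordinated (antagonist-like),
#' |mean| below `tolerance` = indeterminate.
#'
#' @param delta a [coordination_delta()].
#' @param window two distances in Angstrom, default `c(5, 7)`.
#' @param tolerance dead band in coordination units separating float
#'   noise from signal (default 0.05).
#' @return object of class `identity_call`: `variant_label`,
#'   `delta_at_limit` (window mean), `call` (one of `"over_coordinated"`,
#'   `"under_coordinated"`, `"indeterminate"`), `magnitude`, `window`,
#'   `tolerance`, `pair_selector`.
#' @export
call_identity <- function(delta, window = c(5, 7), tolerance = 0.05) {
  stopifnot(inherits(delta, "coordination_delta"))
  if (length(window) != 2L || window[2L] <= window[1L])
    stop("window must be c(r1, r2) with r1 < r2")
  dr <- delta$bin_size
  lower <- delta$r - dr
  inside <- lower >= window[1L] - 1e-9 & delta$r <= window[2L] + 1e-9
  if (!any(inside))
    stop("window ", window[1L], "-", window[2L],
         " A outside the delta grid (max ", max(delta$r), " A)")
  m <- mean(delta$delta[inside])
  call <- if (abs(m) < tolerance) "indeterminate"
          else if (m > 0) "over_coordinated" else "under_coordinated"
  structure(
    list(variant_label = delta$variant_label,
         index_label = delta$index_label,
         pair_selector = delta$pair_selector,
         delta_at_limit = m, call = call, magnitude = abs(m),
         window = window, tolerance = tolerance),
    class = "identity_call"
  )
}

#' @export
print.identity_call <- function(x, ...) {
  gloss <- switch(x$call,
                  over_coordinated = "agonist-like",
                  under_coordinated = "antagonist-like",
                  indeterminate = "no call")
  cat(sprintf(
    "<identity_call> %s vs %s [%s]: %s (%s), mean delta %.1f-%.1f A = %+.3f\n",
    x$variant_label, x$index_label, x$pair_selector, x$call, gloss,
    x$window[1L], x$window[2L], x$delta_at_limit))
  invisible(x)
}

#' Rank identity calls
#'
#' Stable ordering by call class (over-coordinated, indeterminate,
#' under-coordinated) then descending magnitude; ties broken by label.
#'
#' @param calls list of [call_identity()] results.
#' @return data.frame with one row per call, strongest first within class.
#' @export
rank_variants <- function(calls) {
  if (length(calls) == 0L) stop("no identity calls to rank")
  stopifnot(all(vapply(calls, inherits, logical(1), "identity_call")))
  df <- do.call(rbind, lapply(calls, function(x)
    data.frame(variant = x$variant_label, call = x$call,
               delta_at_limit = x$delta_at_limit, magnitude = x$magnitude,
               stringsAsFactors = FALSE)))
  class_rank <- match(df$call, c("over_coordinated", "indeterminate",
                                 "under_coordinated"))
  ord <- order(class_rank, -df$magnitude, df$variant)
  df <- df[ord, , drop = FALSE]
  rownames(df) <- NULL
  df
}
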