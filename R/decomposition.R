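# Backbone/side-chain residue-interaction decomposition of coordination
# in a distance window (default 5-7 Angstrom).
#
# Group keys follow the "2B6S" notation: residue number + role letter
# (B = backbone, S = side chain) for each end of the pair, canonically
# ordered so (2B,6S) and (6S,2B) are the same group.

role_letter <- function(role) ifelse(role == "backbone", "B", "S")

make_group_key <- function(res_a, role_a, res_b, role_b) {
  ka <- paste0(res_a, role_a)
  kb <- paste0(res_b, role_b)
  swap <- res_a > res_b | (res_a == res_b & role_a > role_b)
  ifelse(swap, paste0(kb, ka), paste0(ka, kb))
}

parse_group_key <- function(key) {
  m <- regmatches(key, regexec("^([0-9]+)([BS])([0-9]+)([BS])$", key))[[1L]]
  if (length(m) != 5L) stop("malformed group key: ", key)
  list(res_a = as.integer(m[2L]), role_a = m[3L],
       res_b = as.integer(m[4L]), role_b = m[5L])
}

#' Coordination by residue-interaction group
#'
#' Distributes the coordination `R(r) dr` of a species pair over a
#' distance window onto backbone/side-chain residue-interaction groups:
#' every matching atom pair with distance in `[window[1], window[2])`
#' contributes `2/N` (its share of the per-atom coordination sum) to
#' exactly one group, keyed like `"2B6S"` (backbone atoms of residue 2
#' with side-chain atoms of residue 6).
#'
#' @param s a [structure_model()] with roles assigned.
#' @param selector species pair (`"C-C"`, `"C-H"`, ...) or `"total"`.
#' @param window two distances in Angstrom, default `c(5, 7)`.
#' @return object of class `interaction_group_table`: named numeric
#'   `entries` (coordination sums), plus `window`, `selector`, `n_atoms`,
#'   `label`, `residues` (residue count).
#' @export
group_coordination <- function(s, selector = "C-C", window = c(5, 7)) {
  stopifnot(inherits(s, "structure_model"))
  if (length(window) != 2L || !(window[1L] >= 0 && window[2L] > window[1L]))
    stop("window must be c(r1, r2) with 0 <= r1 < r2")
  a <- s$atoms
  if (identical(selector, "total")) {
    ia <- seq_len(nrow(a)); ib <- ia; like <- TRUE
  } else {
    sp <- toupper(strsplit(selector, "-", fixed = TRUE)[[1L]])
    if (length(sp) != 2L) stop("selector must be 'total' or like 'C-C'")
    ia <- which(a$element == sp[1L]); ib <- which(a$element == sp[2L])
    like <- sp[1L] == sp[2L]
    if (like) ib <- ia
    if (length(ia) == 0L || length(ib) == 0L || (like && length(ia) < 2L))
      stop("empty selection for selector ", selector)
  }
  xyz <- coords(s)
  xa <- xyz[ia, , drop = FALSE]; xb <- xyz[ib, , drop = FALSE]
  d2 <- outer(rowSums(xa^2), rowSums(xb^2), "+") - 2 * tcrossprod(xa, xb)
  d <- sqrt(pmax(d2, 0))
  if (like) d[lower.tri(d, diag = TRUE)] <- -1  # count unordered pairs once
  else {
    overlap <- outer(ia, ib, "==")               # same atom via both sets
    d[overlap] <- -1
  }
  hit <- which(d >= window[1L] - 1e-9 & d < window[2L] - 1e-9, arr.ind = TRUE)
  entries <- numeric(0)
  if (nrow(hit) > 0L) {
    i_at <- ia[hit[, 1L]]; j_at <- ib[hit[, 2L]]
    if (!like) {
      # unordered: drop the mirrored duplicate when both atoms match both
      # species (cannot happen for distinct elements) - kept for safety
      keep <- !duplicated(cbind(pmin(i_at, j_at), pmax(i_at, j_at)))
      i_at <- i_at[keep]; j_at <- j_at[keep]
    }
    keys <- make_group_key(a$residue_index[i_at], role_letter(a$role[i_at]),
                           a$residue_index[j_at], role_letter(a$role[j_at]))
    tab <- tapply(rep(2 / s$N, length(keys)), keys, sum)
    entries <- as.numeric(tab)
    names(entries) <- names(tab)
  }
  structure(
    list(entries = entries, window = window, selector = selector,
         n_atoms = s$N, label = s$label,
         residues = max(a$residue_index)),
    class = "interaction_group_table"
  )
}

#' @export
print.interaction_group_table <- function(x, ...) {
  cat(sprintf(
    "<interaction_group_table> %s [%s] %.1f-%.1f A: %d groups, total %.3f\n",
    x$label, x$selector, x$window[1L], x$window[2L], length(x$entries),
    sum(x$entries)))
  if (length(x$entries) > 0L) {
    top <- sort(x$entries, decreasing = TRUE)
    top <- utils::head(top, 5L)
    cat("  top groups:",
        paste(sprintf("%s=%.3f", names(top), top), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
as.data.frame.interaction_group_table <- function(x, ...) {
  if (length(x$entries) == 0L)
    return(data.frame(structure = character(), selector = character(),
                      group = character(), r1 = numeric(), r2 = numeric(),
                      coordination = numeric()))
  data.frame(structure = x$label, selector = x$selector,
             group = names(x$entries), r1 = x$window[1L], r2 = x$window[2L],
             coordination = as.numeric(x$entries))
}

#' Contribution of a substituted residue's side chain to the
#' coordination deviation
#'
#' Matches variant and index group tables group-by-group (missing groups
#' count as 0), forms the deviation `variant - index`, and reports the
#' percentage carried by groups involving the substituted residue's side
#' chain.  Emitted both as the signed ratio (which can exceed 100% when
#' other groups partially cancel) and as the share of absolute
#' deviations.
#'
#' @param variant_table,index_table [group_coordination()] tables with the
#'   same selector and window.
#' @param substituted_residue residue index whose side chain is the focus.
#' @return object of class `contribution_report`: `percent_contribution`
#'   (signed), `percent_abs`, `total_deviation`, `focus_deviation`,
#'   `degenerate` (TRUE when the total deviation is ~0),
#'   `exceeds_100` flag, labels and parameters.
#' @export
contribution_percent <- function(variant_table, index_table,
                                 substituted_residue) {
  stopifnot(inherits(variant_table, "interaction_group_table"),
            inherits(index_table, "interaction_group_table"))
  if (!identical(variant_table$selector, index_table$selector))
    stop("selector mismatch between variant and index tables")
  if (max(abs(variant_table$window - index_table$window)) > 1e-9)
    stop("window mismatch between variant and index tables")
  if (variant_table$residues != index_table$residues)
    stop("residue count mismatch between variant and index")
  keys <- union(names(variant_table$entries), names(index_table$entries))
  v <- variant_table$entries[keys]; v[is.na(v)] <- 0
  i <- index_table$entries[keys]; i[is.na(i)] <- 0
  diff <- v - i
  names(diff) <- keys
  total <- sum(diff)
  is_focus <- vapply(keys, function(k) {
    p <- parse_group_key(k)
    (p$res_a == substituted_residue && p$role_a == "S") ||
      (p$res_b == substituted_residue && p$role_b == "S")
  }, logical(1))
  focus <- sum(diff[is_focus])
  degenerate <- abs(total) < 1e-12
  pct <- if (degenerate) NA_real_ else 100 * focus / total
  # absolute-deviation share reported alongside: groups can cancel in sign
  pct_abs <- if (sum(abs(diff)) < 1e-12) NA_real_ else
    100 * sum(abs(diff[is_focus])) / sum(abs(diff))
  structure(
    list(variant_label = variant_table$label,
         index_label = index_table$label,
         selector = variant_table$selector,
         window = variant_table$window,
         substituted_residue = substituted_residue,
         focus_groups = keys[is_focus],
         focus_deviation = focus, total_deviation = total,
         percent_contribution = pct, percent_abs = pct_abs,
         degenerate = degenerate,
         exceeds_100 = !degenerate && abs(pct) > 100),
    class = "contribution_report"
  )
}

#' @export
print.contribution_report <- function(x, ...) {
  if (x$degenerate) {
    cat(sprintf("<contribution_report> %s vs %s [%s]: degenerate (zero total deviation)\n",
                x$variant_label, x$index_label, x$selector))
  } else {
    cat(sprintf(
      "<contribution_report> %s vs %s [%s] %.0f-%.0f A: residue %d side chain carries %.1f%% of the deviation (abs share %.1f%%)%s\n",
      x$variant_label, x$index_label, x$selector, x$window[1L], x$window[2L],
      x$substituted_residue, x$percent_contribution, x$percent_abs,
      if (x$exceeds_100) " [>100%: partial cancellation]" else ""))
  }
  invisible(x)
}
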