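# Logical domain of influence: R surface over the C++ breadth-first search.

as_vindex <- function(g, v, what = "node state") {
  if (is.numeric(v)) return(as.integer(v))
  i <- match(v, g$vnames)
  if (anyNA(i)) {
    stop(sprintf("unknown %s(s): %s", what, paste(v[is.na(i)], collapse = ", ")))
  }
  i
}

new_ldoi_result <- function(g, s_idx, raw) {
  members <- g$vnames[sort(raw$members)]
  # internal consistency is a structural guarantee of the truncated search;
  # assert it on every call
  stopifnot(!any(negation_of(members) %in% members))
  structure(list(
    intervention = g$vnames[sort(s_idx)],
    members = members,
    conflict = raw$conflict,
    self_contained = raw$self_contained,
    activated_composites = g$comp_names[raw$activated]
  ), class = "ldoi_result")
}

#' Logical domain of influence of a node-state set
#'
#' Runs the modified breadth-first search on the expanded network starting
#' from the sustained node states in `s`. A composite node is traversed only
#' when all of its inputs are already stabilized; any visit to the negation
#' of an intervention state is truncated (recorded in the `conflict` flag but
#' never added to the members). The LDOI of the empty set is empty. An
#' intervention state itself belongs to the members only when the search
#' re-derives it independently of its own state.
#'
#' @param g an `expanded_network` from [build_expanded()].
#' @param s character vector of virtual node names (e.g. `c("n2", "~n4")`),
#'   or a `Name=0/1` spec accepted by [parse_states()]. Must be consistent
#'   (no state together with its negation).
#' @return an object of class `ldoi_result` with elements `intervention`,
#'   `members` (virtual node names), `conflict`, `self_contained`
#'   (`s` is contained in its own LDOI) and `activated_composites`.
#' @examples
#' g <- build_expanded(parse_rules("A *= B\nB *= A"))
#' compute_ldoi(g, "A")$members
#' @export
compute_ldoi <- function(g, s) {
  stopifnot(inherits(g, "expanded_network"))
  if (length(s) == 1L && grepl("=", s, fixed = TRUE)) s <- parse_states(s)
  s <- check_consistent(s, "intervention set")
  if (length(s) == 0L) {
    return(structure(list(intervention = character(0), members = character(0),
                          conflict = FALSE, self_contained = FALSE,
                          activated_composites = character(0)),
                     class = "ldoi_result"))
  }
  s_idx <- as_vindex(g, s)
  raw <- cpp_ldoi(net_ptr(g), s_idx)
  new_ldoi_result(g, s_idx, raw)
}

#' @export
print.ldoi_result <- function(x, ...) {
  cat("LD({", paste(x$intervention, collapse = ", "), "}) = {",
      paste(x$members, collapse = ", "), "}\n", sep = "")
  if (x$conflict) cat("  (truncated: conflict with the intervention)\n")
  invisible(x)
}

#' Is an intervention set compatible?
#'
#' An intervention set is compatible when its LDOI search meets no conflict,
#' i.e. it never reaches the negation of one of its own states.
#'
#' @inheritParams compute_ldoi
#' @return logical flag.
#' @export
is_compatible <- function(g, s) {
  !compute_ldoi(g, s)$conflict
}

#' Does an intervention's LDOI cover a target?
#'
#' @inheritParams compute_ldoi
#' @param t character vector of target virtual node names (consistent).
#' @return `TRUE` iff every target state is in `compute_ldoi(g, s)$members`.
#' @export
covers <- function(g, s, t) {
  if (length(t) == 1L && grepl("=", t, fixed = TRUE)) t <- parse_states(t)
  t <- check_consistent(t, "target set")
  as_vindex(g, t, "target state")  # validate names
  all(t %in% compute_ldoi(g, s)$members)
}

#' Cache of single-state LDOIs
#'
#' Computes (and memoizes on the network object) the LDOI of every virtual
#' node, together with the greedy-function ingredients used by [grasp()]:
#' the LDOI size and the number of composite nodes partially fed by the LDOI.
#'
#' @param g an `expanded_network`.
#' @return named list (one `ldoi_result` per virtual node) with attributes
#'   `s1` (LDOI sizes) and `s2` (partially-fed composite counts).
#' @export
single_state_cache <- function(g) {
  stopifnot(inherits(g, "expanded_network"))
  cached <- g$env$cache
  if (!is.null(cached)) return(cached)
  raw <- cpp_cache(net_ptr(g))
  out <- vector("list", g$n_virtual)
  for (v in seq_len(g$n_virtual)) {
    out[[v]] <- new_ldoi_result(g, v, cpp_ldoi(net_ptr(g), v))
  }
  names(out) <- g$vnames
  attr(out, "s1") <- setNames(raw$s1, g$vnames)
  attr(out, "s2") <- setNames(raw$s2, g$vnames)
  g$env$cache <- out
  out
}
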