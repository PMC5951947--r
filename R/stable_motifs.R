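# Stable motifs of the expanded network: minimal strongly connected,
# internally consistent, composite-closed node sets. A stable motif is a
# self-sustaining partial fixed point: once its node states hold, no outside
# node can undo them.

motif_states <- function(g, members_idx) {
  v <- members_idx[members_idx <= g$n_virtual]
  sort(g$vnames[sort(v)], method = "radix")
}

#' Stable motifs of an expanded network
#'
#' Enumerates the minimal strongly connected components of the expanded
#' network that (1) contain no virtual node together with its negation and
#' (2) contain every input of every composite member. The search restricts
#' the graph to closed consistent subsets (iteratively dropping composite
#' nodes with missing inputs, branching on conflicting virtual-node pairs)
#' and recursively looks for strictly smaller motifs inside every candidate,
#' keeping only the minimal ones under state-set inclusion.
#'
#' The recursion is exponential in the worst case; this is a reporting and
#' property-testing surface, bounded by `max_nodes` model nodes.
#'
#' @param g an `expanded_network`.
#' @param max_nodes refuse models larger than this.
#' @return list of `stable_motif` objects (elements `members` -- virtual and
#'   composite node names -- and `states`, the implied node states), sorted
#'   by their state sets.
#' @export
find_stable_motifs <- function(g, max_nodes = 30L) {
  stopifnot(inherits(g, "expanded_network"))
  if (length(g$nodes) > max_nodes) {
    stop("model too large for motif enumeration; raise max_nodes deliberately")
  }
  nv <- g$n_virtual
  nc <- length(g$comp_lits)
  all_ids <- seq_len(nv + nc)  # composites are nv + 1 .. nv + nc
  ig <- expanded_igraph(g)
  # self-loop lookup for single-node SCC detection
  has_self <- logical(nv + nc)
  self_edges <- g$edges$source == g$edges$target
  if (any(self_edges)) {
    has_self[match(unique(g$edges$source[self_edges]),
                   c(g$vnames, g$comp_names))] <- TRUE
  }

  memo <- new.env(parent = emptyenv())
  found <- list()

  close_set <- function(ids) {
    repeat {
      comp_ids <- ids[ids > nv]
      drop <- comp_ids[!vapply(comp_ids, function(c)
        all(g$comp_lits[[c - nv]] %in% ids), logical(1))]
      if (length(drop) == 0L) return(ids)
      ids <- setdiff(ids, drop)
    }
  }

  explore <- function(ids) {
    ids <- close_set(sort(ids))
    if (length(ids) == 0L) return(invisible())
    key <- paste(ids, collapse = ",")
    if (!is.null(memo[[key]])) return(invisible())
    assign(key, TRUE, envir = memo)
    sub <- igraph::induced_subgraph(ig, ids)
    memb <- igraph::components(sub, mode = "strong")$membership
    sub_ids <- as.integer(match(igraph::V(sub)$name, c(g$vnames, g$comp_names)))
    for (cc in unique(memb)) {
      scc <- sub_ids[memb == cc]
      if (length(scc) == 1L && !has_self[scc]) next
      vpart <- scc[scc <= nv]
      conflict <- vpart[v_neg(vpart) %in% vpart]
      if (length(conflict) > 0L) {
        v <- min(conflict)
        explore(setdiff(scc, v))
        explore(setdiff(scc, v_neg(v)))
        next
      }
      comp_part <- scc[scc > nv]
      open_comps <- comp_part[!vapply(comp_part, function(c)
        all(g$comp_lits[[c - nv]] %in% scc), logical(1))]
      if (length(open_comps) > 0L) {
        explore(setdiff(scc, open_comps))
        next
      }
      # valid candidate: record, then look for strictly smaller motifs inside
      found[[length(found) + 1L]] <<- scc
      for (v in vpart) explore(setdiff(scc, v))
    }
    invisible()
  }

  explore(all_ids)

  if (length(found) == 0L) return(list())
  state_sets <- lapply(found, function(ids) motif_states(g, ids))
  keys <- vapply(state_sets, paste, "", collapse = ",")
  keep <- !duplicated(keys)
  found <- found[keep]
  state_sets <- state_sets[keep]
  # minimality under state-set inclusion
  minimal <- rep(TRUE, length(found))
  for (i in seq_along(found)) {
    for (j in seq_along(found)) {
      if (i != j && minimal[i] &&
          all(state_sets[[j]] %in% state_sets[[i]]) &&
          length(state_sets[[j]]) < length(state_sets[[i]])) {
        minimal[i] <- FALSE
      }
    }
  }
  found <- found[minimal]
  state_sets <- state_sets[minimal]
  ord <- order(vapply(state_sets, paste, "", collapse = ","), method = "radix")
  lapply(ord, function(i) {
    structure(list(
      members = c(g$vnames, g$comp_names)[sort(found[[i]])],
      states = state_sets[[i]]
    ), class = "stable_motif")
  })
}

#' @export
print.stable_motif <- function(x, ...) {
  cat("Stable motif: {", paste(x$states, collapse = ", "), "}\n", sep = "")
  invisible(x)
}

#' Minimal cores of a stable motif
#'
#' A core is a minimal subset of the motif's node states whose LDOI contains
#' the whole motif. Found by exhaustive subset search in increasing size,
#' pruning supersets of cores already found.
#'
#' @param g an `expanded_network`.
#' @param m a `stable_motif` of `g`.
#' @param max_size largest core size to search for.
#' @return list of character vectors (each a core).
#' @export
find_cores <- function(g, m, max_size = 3L) {
  stopifnot(inherits(m, "stable_motif"))
  states <- m$states
  cores <- list()
  for (sz in seq_len(min(max_size, length(states)))) {
    for (comb in utils::combn(states, sz, simplify = FALSE)) {
      if (any(vapply(cores, function(cr) all(cr %in% comb), logical(1)))) next
      if (all(states %in% compute_ldoi(g, comb)$members)) {
        cores[[length(cores) + 1L]] <- comb
      }
    }
  }
  cores
}

#' Is a node-state set a driver of a stable motif?
#'
#' Uses LDOI containment as the certifying sufficient condition: `s` drives
#' `m` when the motif's full state set lies in `LD(s)`. (Containment in the
#' true DOI is necessary-and-sufficient but only checkable by exhaustive
#' dynamics on small networks; oscillation-mediated stabilization is not
#' detected here.)
#'
#' @param g an `expanded_network`.
#' @param s character vector of virtual node names.
#' @param m a `stable_motif`.
#' @return logical flag.
#' @export
is_driver_set <- function(g, s, m) {
  stopifnot(inherits(m, "stable_motif"))
  all(m$states %in% compute_ldoi(g, s)$members)
}
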