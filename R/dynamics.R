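# Brute-force dynamics on small networks: synchronous / general-asynchronous
# attractors as terminal SCCs of the full state transition graph, fixed points
# by constraint propagation over the Blake forms, partial fixed points by
# three-valued evaluation, and the true domain of influence of a clamp.

norm_scheme <- function(scheme) {
  scheme <- gsub("-", "_", scheme[1], fixed = TRUE)
  match.arg(scheme, c("general_asynchronous", "synchronous", "both"))
}

state_bits <- function(ids, n) {
  out <- vapply(seq_len(n), function(j) bitwAnd(ids, as.integer(2^(j - 1))) %/%
                  as.integer(2^(j - 1)), integer(length(ids)))
  matrix(out, nrow = length(ids), ncol = n)
}

# Value of f_j on every global state, as a 0/1 vector over state ids 0..2^n-1.
node_update_column <- function(m, j, Mbits) {
  f <- m$functions[[m$nodes[j]]]
  regs <- match(f$regulators, m$nodes)
  idx <- rep(1L, nrow(Mbits))
  for (p in seq_along(regs)) {
    idx <- idx + Mbits[, regs[p]] * as.integer(2^(p - 1))
  }
  as.integer(f$table[idx])
}

#' Synchronous update of a system state
#'
#' All nodes are updated simultaneously through their regulatory functions.
#'
#' @param m a `boolean_model`.
#' @param state 0/1 vector in node order (optionally named).
#' @return the successor state (named 0/1 vector).
#' @export
synchronous_step <- function(m, state) {
  n <- length(m$nodes)
  stopifnot(length(state) == n)
  state <- as.integer(state)
  out <- integer(n)
  for (j in seq_len(n)) {
    f <- m$functions[[m$nodes[j]]]
    regs <- match(f$regulators, m$nodes)
    idx <- 1L + sum(state[regs] * 2^(seq_along(regs) - 1))
    out[j] <- as.integer(f$table[idx])
  }
  setNames(out, m$nodes)
}

terminal_components <- function(edges, n_states) {
  g <- igraph::graph_from_edgelist(edges, directed = TRUE)
  if (igraph::vcount(g) < n_states) {
    g <- igraph::add_vertices(g, n_states - igraph::vcount(g))
  }
  memb <- igraph::components(g, mode = "strong")$membership
  cross <- memb[edges[, 1]] != memb[edges[, 2]]
  nonterminal <- unique(memb[edges[, 1]][cross])
  terminal <- setdiff(unique(memb), nonterminal)
  lapply(terminal, function(cc) which(memb == cc))  # 1-based state ids
}

transition_edges <- function(m, scheme, clamp_idx, clamp_val) {
  n <- length(m$nodes)
  ids <- 0:(2^n - 1)
  Mbits <- state_bits(ids, n)
  Fcols <- matrix(0L, nrow = length(ids), ncol = n)
  for (j in seq_len(n)) {
    if (j %in% clamp_idx) {
      Fcols[, j] <- clamp_val[match(j, clamp_idx)]
    } else {
      Fcols[, j] <- node_update_column(m, j, Mbits)
    }
  }
  if (scheme == "synchronous") {
    nxt <- as.integer(Fcols %*% 2^(0:(n - 1)))
    cbind(ids + 1L, nxt + 1L)
  } else {
    from <- integer(0)
    to <- integer(0)
    for (j in seq_len(n)) {
      delta <- (Fcols[, j] - Mbits[, j]) * as.integer(2^(j - 1))
      ch <- which(delta != 0L)
      from <- c(from, ids[ch])
      to <- c(to, ids[ch] + delta[ch])
    }
    stay <- setdiff(ids, unique(from))  # states with no changing update
    rbind(cbind(from + 1L, to + 1L), cbind(stay + 1L, stay + 1L))
  }
}

attractor_from_states <- function(m, state_ids1) {
  n <- length(m$nodes)
  bits <- state_bits(state_ids1 - 1L, n)
  colnames(bits) <- m$nodes
  const <- apply(bits, 2, function(col) length(unique(col)) == 1L)
  structure(list(
    states = bits,
    stabilized = setNames(bits[1, const], m$nodes[const]),
    fixed_point = nrow(bits) == 1L
  ), class = "attractor")
}

#' @export
print.attractor <- function(x, ...) {
  cat(if (x$fixed_point) "Fixed point:" else
    sprintf("Attractor (%d states), stabilized:", nrow(x$states)),
    paste(names(x$stabilized), x$stabilized, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' Attractors of a Boolean model by exhaustive state-space search
#'
#' Builds the full state transition graph under the chosen updating scheme
#' (optionally with clamped node states) and returns its terminal strongly
#' connected components. Fixed points are identical across schemes; limit
#' cycles and complex attractors are scheme-dependent.
#'
#' @param m a `boolean_model`.
#' @param scheme `"synchronous"` or `"general_asynchronous"` (the latter:
#'   one transition per node whose update would change the state).
#' @param clamp character vector of virtual node names held fixed.
#' @param max_nodes refuse models larger than this (state space is `2^n`).
#' @return list of `attractor` objects (each with a `states` 0/1 matrix and
#'   the `stabilized` partial assignment), ordered by smallest state id.
#' @export
find_attractors <- function(m, scheme = "general_asynchronous",
                            clamp = character(), max_nodes = 16L) {
  scheme <- norm_scheme(scheme)
  stopifnot(scheme != "both")
  n <- length(m$nodes)
  if (n > max_nodes) stop("model too large for exhaustive search")
  cl <- states_to_map(check_consistent(clamp, "clamp set"))
  clamp_idx <- match(names(cl), m$nodes)
  if (anyNA(clamp_idx)) stop("unknown clamped node")
  edges <- transition_edges(m, scheme, clamp_idx, as.integer(cl))
  comps <- terminal_components(edges, 2^n)
  comps <- comps[order(vapply(comps, min, integer(1)))]
  lapply(comps, function(s) attractor_from_states(m, s))
}

# f_j evaluated with node j's own state treated as unknown, on a complete
# 0/1 state: returns 0/1 when determined either way, NA otherwise.
eval_without_self <- function(m, j, state) {
  f <- m$functions[[m$nodes[j]]]
  regs <- match(f$regulators, m$nodes)
  self <- which(regs == j)
  vals <- unique(vapply(if (length(self)) 0:1 else 0L, function(b) {
    st <- state
    if (length(self)) st[j] <- b
    idx <- 1L + sum(st[regs] * 2^(seq_along(regs) - 1))
    as.integer(f$table[idx])
  }, integer(1)))
  if (length(vals) == 1L) vals else NA_integer_
}

doi_one_scheme <- function(m, s_map, scheme, max_nodes = 16L) {
  n <- length(m$nodes)
  clamp_idx <- match(names(s_map), m$nodes)
  attrs <- find_attractors(m, scheme,
                           clamp = ifelse(s_map == 1L, names(s_map),
                                          paste0("~", names(s_map))),
                           max_nodes = max_nodes)
  all_states <- do.call(rbind, lapply(attrs, function(a) a$states))
  const <- apply(all_states, 2, function(col) length(unique(col)) == 1L)
  vals <- all_states[1, ]
  keep <- which(const)
  out <- character(0)
  for (j in keep) {
    if (j %in% clamp_idx) {
      # §-style self-inclusion exception: the clamped state is in its own DOI
      # only if the rest of the stabilized system re-derives it, i.e. f_j is
      # determined to the clamped value on every attractor state with the
      # node's own state treated as unknown.
      ok <- TRUE
      for (r in seq_len(nrow(all_states))) {
        v <- eval_without_self(m, j, all_states[r, ])
        if (is.na(v) || v != vals[j]) {
          ok <- FALSE
          break
        }
      }
      if (!ok) next
    }
    out <- c(out, if (vals[j] == 1L) m$nodes[j] else paste0("~", m$nodes[j]))
  }
  out
}

#' Brute-force domain of influence of a sustained intervention
#'
#' The DOI of a clamp is the set of node states that take the same constant
#' value in every state of every attractor of the clamped system. The clamped
#' states themselves are included only when the stabilized remainder of the
#' system re-derives them (evaluating each clamped node's rule with its own
#' state unknown). With `scheme = "both"` (the default, the conservative
#' reading of "any updating regime") the synchronous and general-asynchronous
#' results are intersected.
#'
#' @param m a `boolean_model`.
#' @param s character vector of clamped virtual node names.
#' @param scheme `"both"`, `"synchronous"` or `"general_asynchronous"`.
#' @param max_nodes size bound for the exhaustive search.
#' @return character vector of virtual node names (the stabilized states).
#' @export
brute_force_doi <- function(m, s, scheme = "both", max_nodes = 16L) {
  scheme <- norm_scheme(scheme)
  if (length(m$nodes) > max_nodes) stop("model too large for exhaustive search")
  if (length(s) == 1L && grepl("=", s, fixed = TRUE)) s <- parse_states(s)
  s <- check_consistent(s, "intervention set")
  s_map <- states_to_map(s)
  if (scheme == "both") {
    a <- doi_one_scheme(m, s_map, "synchronous", max_nodes)
    b <- doi_one_scheme(m, s_map, "general_asynchronous", max_nodes)
    intersect(a, b)
  } else {
    doi_one_scheme(m, s_map, scheme, max_nodes)
  }
}

## ---- constraint propagation over Blake forms --------------------------------

# Three-valued evaluation of a Blake DNF under a partial 0/1/NA assignment
# over all model nodes. Because the DNF holds every prime implicant, the
# three-valued result is exact: 1 iff some clause is satisfied, 0 iff every
# clause is falsified, NA otherwise.
eval_dnf3 <- function(clauses_idx, a) {
  any_na <- FALSE
  for (cl in clauses_idx) {
    vals <- a[cl[, 1L]]
    lit <- ifelse(cl[, 2L] == 1L, vals, 1L - vals)
    if (any(!is.na(lit) & lit == 0L)) next          # clause falsified
    if (anyNA(lit)) any_na <- TRUE else return(1L)  # clause satisfied
  }
  if (any_na) NA_integer_ else 0L
}

model_clauses_idx <- function(m) {
  lapply(m$nodes, function(nd) {
    lapply(m$functions[[nd]]$blake_on, function(cl) {
      neg <- startsWith(cl, "~")
      cbind(match(ifelse(neg, substring(cl, 2L), cl), m$nodes),
            as.integer(!neg))
    })
  })
}

#' Fixed points of a Boolean model
#'
#' Solves `f(x) = x` by constraint propagation over the Blake canonical forms
#' with branching on undetermined nodes, so no full `2^n` enumeration is
#' needed. Fixed points do not depend on the updating scheme.
#'
#' @param m a `boolean_model`.
#' @param max_nodes refuse models larger than this.
#' @param max_solutions stop after this many fixed points (for networks with
#'   many source nodes the count grows as `2^(#sources)`).
#' @return list of named 0/1 vectors.
#' @export
find_fixed_points <- function(m, max_nodes = 20L, max_solutions = Inf) {
  n <- length(m$nodes)
  if (n == 0L) return(list())
  if (n > max_nodes) stop("model too large; raise max_nodes deliberately")
  clauses <- model_clauses_idx(m)
  sols <- list()

  propagate <- function(a) {
    repeat {
      changed <- FALSE
      for (j in seq_len(n)) {
        v <- eval_dnf3(clauses[[j]], a)
        if (!is.na(v)) {
          if (!is.na(a[j])) {
            if (a[j] != v) return(NULL)
          } else {
            a[j] <- v
            changed <- TRUE
          }
        }
      }
      if (!changed) return(a)
    }
  }
  recurse <- function(a) {
    if (length(sols) >= max_solutions) return()
    a <- propagate(a)
    if (is.null(a)) return()
    j <- which(is.na(a))[1]
    if (is.na(j)) {
      sols[[length(sols) + 1L]] <<- setNames(a, m$nodes)
      return()
    }
    for (v in 0:1) {
      a2 <- a
      a2[j] <- v
      recurse(a2)
    }
  }
  recurse(rep(NA_integer_, n))
  sols
}

#' Is a partial assignment a partial fixed point?
#'
#' A proper subset of nodes whose states are reproduced by their update
#' functions regardless of the states of the remaining nodes, checked by
#' exact three-valued evaluation of the Blake forms.
#'
#' @param m a `boolean_model`.
#' @param p named 0/1 vector assigning a proper, nonempty subset of nodes.
#' @return logical flag.
#' @export
is_partial_fixed_point <- function(m, p) {
  n <- length(m$nodes)
  idx <- match(names(p), m$nodes)
  if (anyNA(idx)) stop("unknown node in partial assignment")
  if (length(p) == 0L) stop("empty assignment")
  if (length(p) >= n) stop("a partial fixed point must be a proper subset of nodes")
  clauses <- model_clauses_idx(m)
  a <- rep(NA_integer_, n)
  a[idx] <- as.integer(p)
  for (j in idx) {
    v <- eval_dnf3(clauses[[j]], a)
    if (is.na(v) || v != a[j]) return(FALSE)
  }
  TRUE
}
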