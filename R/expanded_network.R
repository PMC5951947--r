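# The expanded network: one virtual node per node state (n_i for ON, ~n_i for
# OFF), plus a composite node for every AND clause (>= 2 literals) of the
# Blake canonical form of each rule and of its negation. Every edge is
# positive; all polarity lives in the virtual-node identities.

## ---- virtual node helpers ---------------------------------------------------
# Internally virtual nodes are 1-based indices: node i ON -> 2i-1, OFF -> 2i.

v_on <- function(i) 2L * i - 1L
v_off <- function(i) 2L * i

v_neg <- function(idx) idx + ifelse(idx %% 2L == 1L, 1L, -1L)

v_names_for <- function(nodes) {
  as.vector(rbind(nodes, paste0("~", nodes)))
}

lit_to_index <- function(lits, nodes) {
  neg <- startsWith(lits, "~")
  nm <- ifelse(neg, substring(lits, 2L), lits)
  i <- match(nm, nodes)
  if (anyNA(i)) stop("unknown node(s): ", paste(nm[is.na(i)], collapse = ", "))
  ifelse(neg, v_off(i), v_on(i))
}

#' Negation of a virtual node
#'
#' Flips the state of a virtual node name: `"X"` (X = 1) becomes `"~X"`
#' (X = 0) and vice versa. An involution.
#'
#' @param v character vector of virtual node names.
#' @return character vector of the complementary virtual nodes.
#' @examples
#' negation_of(c("n3", "~n0"))
#' @export
negation_of <- function(v) {
  neg <- startsWith(v, "~")
  ifelse(neg, substring(v, 2L), paste0("~", v))
}

#' Parse a node-state specification
#'
#' Converts a comma-separated specification like `"n1=1,n0=0"` (or a character
#' vector of such items) into virtual node names (`"n1"`, `"~n0"`).
#'
#' @param spec character; items of the form `Name=0` or `Name=1`.
#' @return character vector of virtual node names.
#' @export
parse_states <- function(spec) {
  items <- trimws(unlist(strsplit(spec, ",", fixed = TRUE)))
  items <- items[items != ""]
  m <- regmatches(items, regexec("^([A-Za-z0-9_]+)\\s*=\\s*([01])$", items))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad)) stop("invalid node-state item(s): ", paste(items[bad], collapse = ", "))
  vapply(m, function(x) if (x[3] == "1") x[2] else paste0("~", x[2]), "")
}

states_to_map <- function(vnames) {
  neg <- startsWith(vnames, "~")
  setNames(as.integer(!neg), ifelse(neg, substring(vnames, 2L), vnames))
}

check_consistent <- function(vnames, what = "node state set") {
  if (anyDuplicated(vnames)) vnames <- unique(vnames)
  if (any(negation_of(vnames) %in% vnames)) {
    stop(sprintf("inconsistent %s: contains a node state and its negation", what))
  }
  vnames
}

## ---- construction -----------------------------------------------------------

#' Build the expanded network of a Boolean model
#'
#' For each node `i`, the in-edges of the virtual node `n_i` encode the Blake
#' canonical form of its rule and the in-edges of `~n_i` encode the Blake
#' canonical form of the negated rule. One-literal prime implicants become
#' direct virtual-to-virtual edges; multi-literal implicants become a
#' composite AND node fed by its literals. Composite nodes are deduplicated
#' globally by literal set. Source nodes carry explicit self-edges on both of
#' their virtual nodes. The construction is deterministic: the same model
#' always yields identical node and edge sets.
#'
#' @param m a `boolean_model`.
#' @return an object of class `expanded_network`.
#' @export
build_expanded <- function(m) {
  stopifnot(inherits(m, "boolean_model"))
  nodes <- m$nodes
  n <- length(nodes)
  nv <- 2L * n
  vnames <- v_names_for(nodes)

  vv_out <- vector("list", nv)   # virtual -> virtual
  vc_out <- vector("list", nv)   # virtual -> composite (indices)
  for (i in seq_len(nv)) {
    vv_out[[i]] <- integer(0)
    vc_out[[i]] <- integer(0)
  }
  comp_lits <- list()            # composite -> sorted virtual indices
  comp_key <- new.env(parent = emptyenv())
  edges_src <- character(0)
  edges_dst <- character(0)

  comp_name <- function(lits) paste(sort(vnames[lits], method = "radix"), collapse = "&")

  add_clause <- function(clause, target_v) {
    lits <- sort(lit_to_index(clause, nodes))
    if (length(lits) == 1L) {
      vv_out[[lits]] <<- c(vv_out[[lits]], target_v)
      edges_src <<- c(edges_src, vnames[lits])
      edges_dst <<- c(edges_dst, vnames[target_v])
    } else {
      key <- paste(lits, collapse = ",")
      cid <- comp_key[[key]]
      if (is.null(cid)) {
        cid <- length(comp_lits) + 1L
        comp_lits[[cid]] <<- lits
        assign(key, cid, envir = comp_key)
        for (l in lits) {
          vc_out[[l]] <<- c(vc_out[[l]], cid)
          edges_src <<- c(edges_src, vnames[l])
          edges_dst <<- c(edges_dst, comp_name(lits))
        }
      }
      comp_out[[cid]] <<- c(if (cid <= length(comp_out)) comp_out[[cid]] else integer(0),
                            target_v)
      edges_src <<- c(edges_src, comp_name(lits))
      edges_dst <<- c(edges_dst, vnames[target_v])
    }
  }
  comp_out <- list()

  for (i in seq_len(n)) {
    f <- m$functions[[nodes[i]]]
    for (cl in f$blake_on) add_clause(cl, v_on(i))
    for (cl in f$blake_off) add_clause(cl, v_off(i))
  }

  comp_names <- vapply(comp_lits, comp_name, "")
  g <- structure(list(
    model = m,
    nodes = nodes,
    vnames = vnames,
    n_virtual = nv,
    comp_lits = comp_lits,
    comp_names = comp_names,
    vv_out = vv_out,
    vc_out = vc_out,
    comp_out = comp_out,
    edges = data.frame(source = edges_src, target = edges_dst,
                       stringsAsFactors = FALSE),
    env = new.env(parent = emptyenv())
  ), class = "expanded_network")
  g
}

# Cached external pointer to the C++ adjacency structure (rebuilt after
# serialization, when the pointer goes stale).
net_ptr <- function(g) {
  p <- g$env$ptr
  if (is.null(p) || !cpp_net_ok(p)) {
    p <- cpp_net_build(g$n_virtual, g$vv_out, g$vc_out, g$comp_lits, g$comp_out)
    g$env$ptr <- p
  }
  p
}

#' Edge list of an expanded network
#'
#' @param g an `expanded_network`.
#' @return data frame with `source` and `target` columns; composite nodes are
#'   named by their sorted literal sets joined with `&` (e.g. `~n0&~n1`).
#' @export
expanded_edgelist <- function(g) {
  stopifnot(inherits(g, "expanded_network"))
  g$edges
}

#' @rdname expanded_edgelist
#' @param path output path; one `source<TAB>target` line per edge.
#' @export
write_expanded <- function(g, path) {
  writeLines(paste(g$edges$source, g$edges$target, sep = "\t"), path)
  invisible(path)
}

#' @export
print.expanded_network <- function(x, ...) {
  cat("Expanded network:", x$n_virtual, "virtual nodes,",
      length(x$comp_lits), "composite nodes,", nrow(x$edges), "edges\n")
  invisible(x)
}

# igraph view (virtual + composite vertices), used by stable motif search.
expanded_igraph <- function(g) {
  ig <- g$env$igraph
  if (is.null(ig)) {
    verts <- c(g$vnames, g$comp_names)
    ig <- igraph::graph_from_data_frame(g$edges, directed = TRUE,
                                        vertices = data.frame(name = verts))
    g$env$igraph <- ig
  }
  ig
}
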