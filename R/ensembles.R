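# Random Boolean network ensembles: Erdos-Renyi directed topologies with
# nested canalizing or effective (irreducible) rules, admissible target
# sampling, and the ensemble benchmark harness.

#' Random directed Erdos-Renyi graph
#'
#' Draws `m` distinct directed edges uniformly over ordered node pairs
#' without self-loops. Every node left with in-degree 0 then receives an
#' identity self-edge and becomes a source node, so that every node can carry
#' a non-constant rule.
#'
#' @param n number of nodes.
#' @param m number of (non-self) directed edges; `0 < m <= n(n-1)`.
#' @return list with `n`, `edges` (2-column matrix, from/to node indices,
#'   including the repair self-edges) and `source_nodes` (indices repaired).
#' @export
random_er_digraph <- function(n, m) {
  stopifnot(n >= 2L)
  total <- n * (n - 1L)
  if (m < 1L || m > total) stop("infeasible edge count m")
  ids <- sample.int(total, m) - 1L
  from <- ids %/% (n - 1L)
  rest <- ids %% (n - 1L)
  to <- ifelse(rest >= from, rest + 1L, rest)  # skip the diagonal
  edges <- cbind(from = from + 1L, to = as.integer(to) + 1L)
  indeg0 <- setdiff(seq_len(n), unique(edges[, 2L]))
  if (length(indeg0) > 0L) {
    edges <- rbind(edges, cbind(from = indeg0, to = indeg0))
  }
  list(n = n, edges = edges, source_nodes = indeg0)
}

#' Nested canalizing Boolean function
#'
#' Builds the function determined by canalizing input values
#' `I = (I_1, ..., I_k)` and outputs `O = (O_1, ..., O_k)` over regulators in
#' priority order: the output is `O_p` for the first `p` with `i_p = I_p`,
#' and `NOT O_k` when every input misses its canalizing value. Always
#' non-constant and essential in every input.
#'
#' @param regulators regulator names in canalizing priority order.
#' @param input_seq,output_seq 0/1 vectors of length `length(regulators)`.
#' @param node optional regulated node name.
#' @return a [boolean_function()].
#' @export
nested_canalizing_function <- function(regulators, input_seq, output_seq,
                                       node = NULL) {
  k <- length(regulators)
  stopifnot(length(input_seq) == k, length(output_seq) == k, k >= 1L)
  M <- assignment_matrix(regulators)
  tab <- logical(nrow(M))
  for (r in seq_len(nrow(M))) {
    o <- NA
    for (p in seq_len(k)) {
      if (as.integer(M[r, p]) == input_seq[p]) {
        o <- output_seq[p] == 1
        break
      }
    }
    if (is.na(o)) o <- output_seq[k] != 1
    tab[r] <- o
  }
  boolean_function(regulators, tab, node = node)
}

#' Random effective (irreducible) Boolean function
#'
#' Rejection-samples a uniform truth table over `k` inputs until it is
#' non-constant and every input is essential (flipping it changes the output
#' in at least one context), so the rule is consistent with its topology.
#'
#' @param regulators regulator names.
#' @param node optional regulated node name.
#' @return a [boolean_function()].
#' @export
effective_function <- function(regulators, node = NULL) {
  k <- length(regulators)
  stopifnot(k >= 1L)
  repeat {
    tab <- sample(c(FALSE, TRUE), 2^k, replace = TRUE)
    if (all(tab) || !any(tab)) next
    if (all_inputs_essential(tab, k)) {
      return(boolean_function(regulators, tab, node = node))
    }
  }
}

all_inputs_essential <- function(tab, k) {
  r <- 0:(2^k - 1)
  for (j in seq_len(k)) {
    b <- as.integer(2^(j - 1))
    lo <- r[bitwAnd(r, b) == 0L]
    if (!any(tab[lo + 1L] != tab[lo + b + 1L])) return(FALSE)
  }
  TRUE
}

#' Generate a random Boolean network model
#'
#' Topology from [random_er_digraph()]; each node's rule is generated over
#' its in-neighbors, either nested canalizing (random canalizing input and
#' output sequences over a random regulator order) or effective
#' (rejection-sampled irreducible truth table). Nodes repaired to in-degree 1
#' get the identity rule and are source nodes. Reproducible from the current
#' RNG state.
#'
#' @param n number of nodes.
#' @param m number of directed edges.
#' @param rule_type `"nested_canalizing"` or `"effective"`.
#' @return a `boolean_model` with nodes `n1 ... n<n>`.
#' @export
generate_model <- function(n, m, rule_type = c("nested_canalizing", "effective")) {
  rule_type <- match.arg(rule_type)
  topo <- random_er_digraph(n, m)
  nodes <- paste0("n", seq_len(n))
  functions <- vector("list", n)
  names(functions) <- nodes
  for (j in seq_len(n)) {
    regs <- sort(unique(topo$edges[topo$edges[, 2L] == j, 1L]))
    if (j %in% topo$source_nodes) {
      functions[[j]] <- boolean_function(nodes[j], c(FALSE, TRUE), node = nodes[j])
    } else if (rule_type == "nested_canalizing") {
      regs <- regs[sample.int(length(regs))]
      functions[[j]] <- nested_canalizing_function(
        nodes[regs],
        input_seq = sample(0:1, length(regs), replace = TRUE),
        output_seq = sample(0:1, length(regs), replace = TRUE),
        node = nodes[j])
    } else {
      functions[[j]] <- effective_function(nodes[regs], node = nodes[j])
    }
  }
  new_boolean_model(nodes, functions)
}

## ---- admissible targets -----------------------------------------------------

# Partial fixed points available without full state-space search: the member
# set of every conflict-free self-contained single-state LDOI is one (the
# intervention sustains itself, so the clamp is redundant in steady state),
# plus fixed points from the constraint-propagation solver (capped, since
# source nodes double the fixed-point count).
partial_fixed_point_pool <- function(m, g = build_expanded(m), fp_cap = 64L) {
  pool <- list()
  cache <- single_state_cache(g)
  for (res in cache) {
    if (res$self_contained && !res$conflict && length(res$members) >= 2L) {
      pool[[length(pool) + 1L]] <- states_to_map(res$members)
    }
  }
  fps <- tryCatch(
    find_fixed_points(m, max_nodes = length(m$nodes), max_solutions = fp_cap),
    error = function(e) list())
  pool <- c(pool, fps)
  keys <- vapply(pool, function(p) paste(names(p), p, sep = "=", collapse = ","), "")
  pool[!duplicated(keys)]
}

#' Sample admissible target sets
#'
#' Draws target node-state sets satisfying the two admissibility criteria:
#' (i) the set is a subset of a (partial) fixed point, and (ii) at least one
#' target node has a regulator outside the target set in the original
#' network (so the targets are not source nodes only and do not form a motif
#' without incoming edges).
#'
#' @param m a `boolean_model`.
#' @param count maximum number of target sets to return.
#' @param sizes allowed target sizes (default 2 and 3).
#' @param g optional prebuilt `expanded_network` of `m`.
#' @param fp_cap cap on enumerated fixed points.
#' @return list of character vectors of virtual node names (possibly fewer
#'   than `count`; empty with a warning when no admissible target exists).
#' @export
sample_admissible_targets <- function(m, count, sizes = c(2L, 3L),
                                      g = build_expanded(m), fp_cap = 64L) {
  pool <- partial_fixed_point_pool(m, g, fp_cap)
  pool <- pool[vapply(pool, length, integer(1)) >= min(sizes)]
  if (length(pool) == 0L) {
    warning("no admissible target exists (no usable partial fixed point)")
    return(list())
  }
  regs_of <- lapply(m$nodes, function(nd) m$functions[[nd]]$regulators)
  names(regs_of) <- m$nodes
  targets <- list()
  seen <- character(0)
  tries <- 0L
  max_tries <- 60L * count
  while (length(targets) < count && tries < max_tries) {
    tries <- tries + 1L
    pfp <- pool[[sample.int(length(pool), 1L)]]
    ok_sizes <- sizes[sizes <= length(pfp)]
    if (length(ok_sizes) == 0L) next
    sz <- ok_sizes[sample.int(length(ok_sizes), 1L)]
    pick <- sample(names(pfp), sz)
    # every target node must be reachable from outside the set; in particular
    # a source-node state (only regulated by itself) can never be driven by
    # any other intervention, so it is inadmissible as a target
    accessible <- all(vapply(pick, function(nd)
      length(setdiff(regs_of[[nd]], pick)) > 0L, logical(1)))
    if (!accessible) next
    tgt <- ifelse(pfp[pick] == 1L, pick, paste0("~", pick))
    tgt <- sort(tgt, method = "radix")
    key <- paste(tgt, collapse = ",")
    if (key %in% seen) next
    seen <- c(seen, key)
    targets[[length(targets) + 1L]] <- tgt
  }
  if (length(targets) == 0L) warning("no admissible target found")
  targets
}

## ---- ensemble harness -------------------------------------------------------

#' Ensemble experiment specification
#'
#' @param network_count number of random networks.
#' @param n_range inclusive range of network sizes (drawn uniformly).
#' @param k_range inclusive range of mean in-degrees (drawn uniformly;
#'   the edge count is `round(k * n)`).
#' @param rule_type `"nested_canalizing"` or `"effective"`.
#' @param targets_per_network admissible target sets sampled per network.
#' @param target_sizes allowed target sizes.
#' @param max_itr,score_index GRASP settings per target.
#' @param seed master seed; per-network seeds are derived from it and logged.
#' @return list of class `ensemble_spec`.
#' @export
ensemble_spec <- function(network_count = 50L, n_range = c(15L, 50L),
                          k_range = c(1, 2),
                          rule_type = c("nested_canalizing", "effective"),
                          targets_per_network = 10L, target_sizes = c(2L, 3L),
                          max_itr = 500L, score_index = 1L, seed = 1L) {
  structure(list(network_count = as.integer(network_count),
                 n_range = as.integer(n_range), k_range = as.numeric(k_range),
                 rule_type = match.arg(rule_type),
                 targets_per_network = as.integer(targets_per_network),
                 target_sizes = as.integer(target_sizes),
                 max_itr = as.integer(max_itr),
                 score_index = as.integer(score_index),
                 seed = as.integer(seed)),
            class = "ensemble_spec")
}

#' Run a random-ensemble target control experiment
#'
#' Generates the networks, samples admissible targets on each, runs GRASP per
#' (network, target) pair, and tabulates the number of distinct locally
#' minimal solutions and the success flag. Fully reproducible from the spec.
#'
#' @param spec an [ensemble_spec()].
#' @return object of class `ensemble_result`: a list with `table` (one row
#'   per network-target pair: network id, size, edges, seed, target,
#'   `n_solutions`, `success`, `elapsed`) and `summary` (mean solution count,
#'   success rate, number of networks without admissible targets).
#' @export
run_ensemble_experiment <- function(spec) {
  stopifnot(inherits(spec, "ensemble_spec"))
  set.seed(spec$seed)
  net_seeds <- sample.int(.Machine$integer.max, spec$network_count)
  rows <- list()
  skipped <- 0L
  for (b in seq_len(spec$network_count)) {
    set.seed(net_seeds[b])
    n <- sample(spec$n_range[1]:spec$n_range[2], 1L)
    kbar <- runif(1L, spec$k_range[1], spec$k_range[2])
    m_edges <- max(1L, as.integer(round(kbar * n)))
    model <- generate_model(n, m_edges, spec$rule_type)
    g <- build_expanded(model)
    targets <- sample_admissible_targets(model, spec$targets_per_network,
                                         spec$target_sizes, g = g)
    if (length(targets) == 0L) {
      skipped <- skipped + 1L
      next
    }
    for (ti in seq_along(targets)) {
      cfg <- grasp_config(max_itr = spec$max_itr,
                          score_index = spec$score_index,
                          seed = net_seeds[b] %% 1000003L + ti)
      t0 <- proc.time()[["elapsed"]]
      sols <- grasp(g, targets[[ti]], cfg)
      rows[[length(rows) + 1L]] <- data.frame(
        network = b, n = n, m_edges = m_edges, seed = net_seeds[b],
        target = paste(targets[[ti]], collapse = ","),
        n_solutions = length(sols),
        success = length(sols) > 0L,
        elapsed = proc.time()[["elapsed"]] - t0,
        stringsAsFactors = FALSE)
    }
  }
  tab <- if (length(rows) > 0L) do.call(rbind, rows) else
    data.frame(network = integer(0), n = integer(0), m_edges = integer(0),
               seed = integer(0), target = character(0),
               n_solutions = integer(0), success = logical(0),
               elapsed = numeric(0))
  structure(list(
    table = tab,
    summary = list(
      pairs = nrow(tab),
      mean_solutions = if (nrow(tab) > 0L) mean(tab$n_solutions) else NA_real_,
      success_rate = if (nrow(tab) > 0L) mean(tab$success) else NA_real_,
      networks_skipped = skipped),
    spec = spec
  ), class = "ensemble_result")
}

#' @export
print.ensemble_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf("Ensemble (%s): %d pairs, mean %.2f distinct solutions, success rate %.3f (%d networks without targets)\n",
              x$spec$rule_type, s$pairs, s$mean_solutions, s$success_rate,
              s$networks_skipped))
  invisible(x)
}
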