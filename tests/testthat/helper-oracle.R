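# Independent oracles. These deliberately avoid the package's Blake-form and
# expanded-network machinery: they work directly on the stored truth tables
# by enumerating completions, so they can serve as ground truth for the
# graph-based implementations.

# Three-valued evaluation of node `nd`'s rule under partial assignment `a`
# (named 0/1/NA over all nodes), by enumerating completions of the unknown
# regulators. With self_unknown = TRUE the node's own state is treated as
# unknown regardless of `a`.
oracle_eval3 <- function(m, nd, a, self_unknown = FALSE) {
  f <- m$functions[[nd]]
  regs <- f$regulators
  av <- a[regs]
  if (self_unknown) av[regs == nd] <- NA_integer_
  unk <- which(is.na(av))
  if (length(unk) == 0L) {
    idx <- 1L + sum(as.integer(av) * 2^(seq_along(regs) - 1))
    return(as.integer(f$table[idx]))
  }
  vals <- integer(0)
  for (b in 0:(2^length(unk) - 1)) {
    av2 <- as.integer(av)
    for (p in seq_along(unk)) {
      av2[unk[p]] <- bitwAnd(b, as.integer(2^(p - 1))) %/% as.integer(2^(p - 1))
    }
    idx <- 1L + sum(av2 * 2^(seq_along(regs) - 1))
    vals <- unique(c(vals, as.integer(f$table[idx])))
    if (length(vals) > 1L) return(NA_integer_)
  }
  vals
}

# The three-valued logical steady state under sustained clamps: iterated
# constant substitution until fixpoint. Returns members (virtual node names,
# with clamped states included only when re-derived with their own state
# unknown) and the conflict flag (some clamped node's rule settles on the
# opposite value).
oracle_ldoi <- function(m, s) {
  a <- setNames(rep(NA_integer_, length(m$nodes)), m$nodes)
  neg <- startsWith(s, "~")
  cl_nodes <- ifelse(neg, substring(s, 2L), s)
  a[cl_nodes] <- as.integer(!neg)
  repeat {
    changed <- FALSE
    for (nd in m$nodes) {
      if (nd %in% cl_nodes || !is.na(a[nd])) next
      v <- oracle_eval3(m, nd, a)
      if (!is.na(v)) {
        a[nd] <- v
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  members <- character(0)
  conflict <- FALSE
  for (nd in m$nodes) {
    if (nd %in% cl_nodes) {
      full <- oracle_eval3(m, nd, a)
      if (!is.na(full) && full != a[nd]) conflict <- TRUE
      v <- oracle_eval3(m, nd, a, self_unknown = TRUE)
      if (!is.na(v) && v == a[nd]) {
        members <- c(members, if (a[nd] == 1L) nd else paste0("~", nd))
      }
    } else if (!is.na(a[nd])) {
      members <- c(members, if (a[nd] == 1L) nd else paste0("~", nd))
    }
  }
  list(members = sort(members, method = "radix"), conflict = conflict)
}

# All prime implicants of a truth table by direct enumeration: every
# non-contradictory clause over the regulators is tested for implicanthood
# (all satisfying rows map to 1) and primality (no proper subclause is an
# implicant). Only usable for small k.
oracle_prime_implicants <- function(regulators, table) {
  k <- length(regulators)
  rows <- 0:(2^k - 1)
  bit <- function(r, j) bitwAnd(r, as.integer(2^(j - 1))) %/% as.integer(2^(j - 1))
  clause_rows <- function(lits) {
    keep <- rep(TRUE, length(rows))
    for (j in seq_len(k)) {
      if (lits[j] == 1L) keep <- keep & (bit(rows, j) == 1L)
      if (lits[j] == 2L) keep <- keep & (bit(rows, j) == 0L)
    }
    rows[keep]
  }
  # lits: 0 = absent, 1 = positive, 2 = negative, encoded base 3
  all_clauses <- list()
  for (code in 1:(3^k - 1)) {
    lits <- integer(k)
    cc <- code
    for (j in seq_len(k)) {
      lits[j] <- cc %% 3L
      cc <- cc %/% 3L
    }
    if (all(table[clause_rows(lits) + 1L])) {
      all_clauses[[length(all_clauses) + 1L]] <- lits
    }
  }
  is_sub <- function(a, b) all(a == 0L | a == b) && any(a != b)
  prime <- vapply(all_clauses, function(cl)
    !any(vapply(all_clauses, function(other) is_sub(other, cl), logical(1))),
    logical(1))
  keep <- all_clauses[prime]
  out <- lapply(keep, function(lits) {
    sort(unlist(lapply(seq_len(k), function(j)
      if (lits[j] == 1L) regulators[j]
      else if (lits[j] == 2L) paste0("~", regulators[j]))), method = "radix")
  })
  out[order(vapply(out, paste, "", collapse = "&"), method = "radix")]
}

# Direct implementation of the nested canalizing hierarchy, row by row.
oracle_ncf_value <- function(input_seq, output_seq, inputs) {
  for (p in seq_along(input_seq)) {
    if (inputs[p] == input_seq[p]) return(output_seq[p])
  }
  1L - output_seq[length(output_seq)]
}

# Exhaustive enumeration of all minimal covering intervention sets of size
# <= 2 (candidates exclude the target states and their negations).
oracle_small_solutions <- function(g, t) {
  vn <- g$vnames
  cand <- setdiff(vn, c(t, negation_of(t)))
  singles <- cand[vapply(cand, function(v)
    all(t %in% compute_ldoi(g, v)$members), logical(1))]
  out <- lapply(singles, identity)
  if (length(cand) >= 2L) {
    for (pair in utils::combn(cand, 2L, simplify = FALSE)) {
      if (negation_of(pair[1]) == pair[2]) next
      if (pair[1] %in% singles || pair[2] %in% singles) next
      if (all(t %in% compute_ldoi(g, pair)$members)) {
        out[[length(out) + 1L]] <- sort(pair, method = "radix")
      }
    }
  }
  out
}

sol_key <- function(x) paste(sort(x, method = "radix"), collapse = ",")
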