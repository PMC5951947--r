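# Quine-McCluskey prime implicant generation.
#
# Implicants are (bits, mask) pairs over k variables: mask bit j set means
# variable j is fixed in the implicant, and then bit j of `bits` is its value.
# The first (combining) phase of Quine-McCluskey yields exactly the set of all
# prime implicants, i.e. the Blake canonical form of the function.

bit_positions <- function(mask) {
  out <- integer(0)
  b <- 1L
  while (b <= mask) {
    if (bitwAnd(mask, b) != 0L) out <- c(out, b)
    b <- b * 2L
  }
  out
}

# table: logical vector of length 2^k; row r corresponds to the assignment
# where variable j has value bit (j-1) of (r-1) (variable 1 fastest-varying).
qm_prime_implicants <- function(table, k) {
  stopifnot(length(table) == 2^k)
  minterms <- which(table) - 1L
  if (length(minterms) == 0L || length(minterms) == 2^k) {
    stop("constant function has no prime implicants")
  }
  full_mask <- as.integer(2^k - 1)
  cur_bits <- as.integer(minterms)
  cur_mask <- rep(full_mask, length(minterms))
  primes_bits <- integer(0)
  primes_mask <- integer(0)

  while (length(cur_bits) > 0L) {
    combined <- logical(length(cur_bits))
    nb <- integer(0)
    nm <- integer(0)
    for (msk in unique(cur_mask)) {
      idx <- which(cur_mask == msk)
      bits <- cur_bits[idx]
      for (b in bit_positions(msk)) {
        lo <- which(bitwAnd(bits, b) == 0L)
        if (length(lo) == 0L) next
        mtch <- match(bits[lo] + b, bits)
        ok <- !is.na(mtch)
        if (any(ok)) {
          combined[idx[lo[ok]]] <- TRUE
          combined[idx[mtch[ok]]] <- TRUE
          nb <- c(nb, bits[lo[ok]])
          nm <- c(nm, rep(msk - b, sum(ok)))
        }
      }
    }
    primes_bits <- c(primes_bits, cur_bits[!combined])
    primes_mask <- c(primes_mask, cur_mask[!combined])
    if (length(nb) > 0L) {
      key <- nb * (full_mask + 1) + nm
      keep <- !duplicated(key)
      cur_bits <- nb[keep]
      cur_mask <- nm[keep]
    } else {
      cur_bits <- integer(0)
      cur_mask <- integer(0)
    }
  }
  cbind(bits = primes_bits, mask = primes_mask)
}

# Convert prime implicants to a canonical clause list. Each clause is a sorted
# character vector of literals "x" (positive) / "~x" (negative); clauses are
# sorted lexicographically so the result is independent of input order.
implicants_to_clauses <- function(pis, vars) {
  clauses <- lapply(seq_len(nrow(pis)), function(i) {
    bits <- pis[i, "bits"]
    mask <- pis[i, "mask"]
    lits <- character(0)
    for (j in seq_along(vars)) {
      b <- as.integer(2^(j - 1))
      if (bitwAnd(mask, b) != 0L) {
        lits <- c(lits, if (bitwAnd(bits, b) != 0L) vars[j] else paste0("~", vars[j]))
      }
    }
    sort(lits, method = "radix")
  })
  keys <- vapply(clauses, paste, "", collapse = "&")
  clauses <- clauses[!duplicated(keys)]
  clauses[order(vapply(clauses, paste, "", collapse = "&"), method = "radix")]
}

eval_clause_row <- function(clause, assignment) {
  # assignment: named logical vector; returns logical
  for (lit in clause) {
    neg <- startsWith(lit, "~")
    nm <- if (neg) substring(lit, 2L) else lit
    val <- assignment[[nm]]
    if (neg) val <- !val
    if (!val) return(FALSE)
  }
  TRUE
}

eval_dnf_row <- function(clauses, assignment) {
  for (cl in clauses) if (eval_clause_row(cl, assignment)) return(TRUE)
  FALSE
}
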