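# Parsing, validation and serialization of Boolean network models.
#
# Rule file dialect: one rule per line, `NodeName *= expression`, where the
# expression combines node names with and/or/not (case-insensitive; the symbols
# & | ! are also accepted), with parentheses, NOT > AND > OR precedence.
# `#` starts a comment. Node names match [A-Za-z0-9_]+.

## ---- tokenizer / recursive-descent parser ----------------------------------

tokenize_expr <- function(text, line_no) {
  pat <- "[A-Za-z0-9_]+|\\(|\\)|&&|\\|\\||&|\\||!"
  m <- gregexpr(pat, text)[[1]]
  toks <- regmatches(text, gregexpr(pat, text))[[1]]
  # verify nothing but tokens and whitespace
  stripped <- gsub(pat, "", text)
  if (grepl("[^[:space:]]", stripped)) {
    stop(sprintf("line %d: unexpected character(s) in expression: '%s'",
                 line_no, trimws(stripped)), call. = FALSE)
  }
  out <- character(length(toks))
  for (i in seq_along(toks)) {
    tk <- toks[i]
    low <- tolower(tk)
    out[i] <- switch(low,
      "and" = "AND", "&" = "AND", "&&" = "AND",
      "or"  = "OR",  "|" = "OR",  "||" = "OR",
      "not" = "NOT", "!" = "NOT",
      "(" = "(", ")" = ")",
      tk)
  }
  out
}

# Grammar: expr := term (OR term)* ; term := factor (AND factor)* ;
# factor := NOT factor | '(' expr ')' | name
parse_expr_tokens <- function(tokens, line_no) {
  pos <- 1L
  peek <- function() if (pos <= length(tokens)) tokens[pos] else NA_character_
  advance <- function() {
    tk <- peek()
    pos <<- pos + 1L
    tk
  }
  fail <- function(msg) stop(sprintf("line %d: %s", line_no, msg), call. = FALSE)

  parse_factor <- function() {
    tk <- peek()
    if (is.na(tk)) fail("unexpected end of expression")
    if (tk == "NOT") {
      advance()
      list(op = "not", arg = parse_factor())
    } else if (tk == "(") {
      advance()
      e <- parse_or()
      if (!identical(peek(), ")")) fail("missing closing parenthesis")
      advance()
      e
    } else if (tk %in% c(")", "AND", "OR")) {
      fail(sprintf("unexpected '%s'", tk))
    } else {
      advance()
      list(op = "var", name = tk)
    }
  }
  parse_and <- function() {
    args <- list(parse_factor())
    while (identical(peek(), "AND")) {
      advance()
      args <- c(args, list(parse_factor()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "and", args = args)
  }
  parse_or <- function() {
    args <- list(parse_and())
    while (identical(peek(), "OR")) {
      advance()
      args <- c(args, list(parse_and()))
    }
    if (length(args) == 1L) args[[1]] else list(op = "or", args = args)
  }

  e <- parse_or()
  if (!is.na(peek())) fail(sprintf("trailing token '%s'", peek()))
  e
}

ast_vars <- function(ast) {
  switch(ast$op,
    var = ast$name,
    not = ast_vars(ast$arg),
    and = ,
    or = unique(unlist(lapply(ast$args, ast_vars))))
}

# Vectorized evaluation over a logical matrix with one column per variable.
ast_eval <- function(ast, M) {
  switch(ast$op,
    var = M[, ast$name],
    not = !ast_eval(ast$arg, M),
    and = Reduce(`&`, lapply(ast$args, ast_eval, M = M)),
    or  = Reduce(`|`, lapply(ast$args, ast_eval, M = M)))
}

# Truth table over `vars` in order; row r: var j = bit (j-1) of (r-1).
assignment_matrix <- function(vars) {
  k <- length(vars)
  r <- 0:(2^k - 1)
  M <- vapply(seq_len(k), function(j) bitwAnd(r, as.integer(2^(j - 1))) != 0L,
              logical(2^k))
  M <- matrix(M, nrow = 2^k, ncol = k, dimnames = list(NULL, vars))
  M
}

## ---- BooleanFunction --------------------------------------------------------

#' Construct a Boolean regulatory function from a truth table
#'
#' Programmatic alternative to the rule-file dialect. The truth table row
#' order follows the convention that regulator `j` carries bit `j-1` of the
#' zero-based row index (the first regulator varies fastest).
#'
#' Regulators that turn out to be inessential (absent from every prime
#' implicant) are dropped with a warning; constant functions are rejected.
#'
#' @param regulators character vector of regulator node names.
#' @param table logical (or 0/1) vector of length `2^length(regulators)`.
#' @param node optional name of the regulated node (used in messages).
#' @return an object of class `boolean_function` with elements `regulators`,
#'   `table`, and the Blake canonical forms `blake_on` (of f) and `blake_off`
#'   (of NOT f), each a list of sorted literal clauses.
#' @export
boolean_function <- function(regulators, table, node = NULL) {
  table <- as.logical(table)
  k <- length(regulators)
  if (anyDuplicated(regulators)) stop("duplicated regulator names")
  if (length(table) != 2^k) stop("truth table length must be 2^k")
  if (all(table) || !any(table)) {
    stop(sprintf("constant function%s is not allowed",
                 if (is.null(node)) "" else paste0(" for node '", node, "'")))
  }
  pis <- qm_prime_implicants(table, k)
  essential <- logical(k)
  for (j in seq_len(k)) {
    essential[j] <- any(bitwAnd(pis[, "mask"], as.integer(2^(j - 1))) != 0L)
  }
  if (!all(essential)) {
    dropped <- regulators[!essential]
    warning(sprintf("dropping inessential regulator(s)%s: %s",
                    if (is.null(node)) "" else paste0(" of '", node, "'"),
                    paste(dropped, collapse = ", ")), call. = FALSE)
    keep <- which(essential)
    # project the table onto the essential regulators (inessential vars at 0)
    r <- 0:(2^length(keep) - 1)
    idx <- rep(0L, length(r))
    for (p in seq_along(keep)) {
      idx <- idx + bitwAnd(r, as.integer(2^(p - 1))) %/% as.integer(2^(p - 1)) *
        as.integer(2^(keep[p] - 1))
    }
    out <- boolean_function(regulators[keep], table[idx + 1L], node = node)
    attr(out, "dropped") <- dropped
    return(out)
  }
  neg_pis <- qm_prime_implicants(!table, k)
  structure(list(
    regulators = regulators,
    table = table,
    blake_on = implicants_to_clauses(pis, regulators),
    blake_off = implicants_to_clauses(neg_pis, regulators)
  ), class = "boolean_function")
}

#' Blake canonical form of a Boolean function
#'
#' Returns the disjunction of all prime implicants of `f` (or of NOT `f`),
#' as computed by the Quine-McCluskey algorithm. Literals within a clause and
#' clauses within the result are sorted, so the output is canonical.
#'
#' @param f a `boolean_function`.
#' @param negate if `TRUE`, return the Blake canonical form of NOT `f`.
#' @return a list of clauses; each clause is a sorted character vector of
#'   literals (`"x"` for x = 1, `"~x"` for x = 0).
#' @export
to_blake_dnf <- function(f, negate = FALSE) {
  stopifnot(inherits(f, "boolean_function"))
  if (negate) f$blake_off else f$blake_on
}

is_identity_source <- function(node, f) {
  length(f$regulators) == 1L && f$regulators == node &&
    identical(f$table, c(FALSE, TRUE))
}

#' @export
print.boolean_function <- function(x, ...) {
  cat(format_dnf(x$blake_on), "\n")
  invisible(x)
}

## ---- BooleanModel -----------------------------------------------------------

new_boolean_model <- function(nodes, functions, dropped = list()) {
  structure(list(
    nodes = nodes,
    functions = functions,
    source_nodes = nodes[vapply(nodes, function(n)
      is_identity_source(n, functions[[n]]), logical(1))],
    dropped_regulators = dropped
  ), class = "boolean_model")
}

#' Parse a Boolean network model from rule text
#'
#' One rule per line in the form `NodeName *= expression`; `#` starts a
#' comment and blank lines are ignored. Every name used in an expression must
#' itself have a rule. A node whose rule is the identity on its own state
#' (`A *= A`) is a source node. Constant rules (tautologies/contradictions)
#' are rejected; inessential regulators are dropped with a warning.
#'
#' @param text character scalar (or vector of lines) with the rule file
#'   content.
#' @return an object of class `boolean_model` with elements `nodes` (ordered
#'   names), `functions` (named list of [boolean_function()] objects),
#'   `source_nodes`, and `dropped_regulators`.
#' @seealso [read_rules()], [format_rules()], [validate_model()]
#' @examples
#' m <- parse_rules("A *= B\nB *= A")
#' m$nodes
#' @export
parse_rules <- function(text) {
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- sub("#.*$", "", lines)
  nodes <- character(0)
  asts <- list()
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (ln == "") next
    m <- regmatches(ln, regexec("^([A-Za-z0-9_]+)\\s*\\*=\\s*(.+)$", ln))[[1]]
    if (length(m) == 0L) {
      stop(sprintf("line %d: expected 'NodeName *= expression', got '%s'", i, ln),
           call. = FALSE)
    }
    node <- m[2]
    if (node %in% nodes) {
      stop(sprintf("line %d: duplicate rule for node '%s'", i, node), call. = FALSE)
    }
    toks <- tokenize_expr(m[3], i)
    if (length(toks) == 0L) stop(sprintf("line %d: empty expression", i), call. = FALSE)
    asts[[node]] <- parse_expr_tokens(toks, i)
    nodes <- c(nodes, node)
  }
  for (node in nodes) {
    bad <- setdiff(ast_vars(asts[[node]]), nodes)
    if (length(bad) > 0L) {
      stop(sprintf("rule for '%s' uses undeclared regulator(s): %s",
                   node, paste(bad, collapse = ", ")), call. = FALSE)
    }
  }
  functions <- list()
  dropped <- list()
  for (node in nodes) {
    vars <- ast_vars(asts[[node]])
    M <- assignment_matrix(vars)
    tab <- ast_eval(asts[[node]], M)
    if (all(tab) || !any(tab)) {
      stop(sprintf("rule for '%s' is a constant function", node), call. = FALSE)
    }
    f <- boolean_function(vars, tab, node = node)
    if (!is.null(attr(f, "dropped"))) dropped[[node]] <- attr(f, "dropped")
    functions[[node]] <- f
  }
  new_boolean_model(nodes, functions, dropped)
}

#' Read a Boolean network model from a rule file
#' @param path path to a rule file in the `parse_rules()` dialect.
#' @return a `boolean_model`.
#' @export
read_rules <- function(path) {
  parse_rules(readLines(path, warn = FALSE))
}

format_dnf <- function(clauses) {
  fmt_cl <- function(cl) {
    lits <- ifelse(startsWith(cl, "~"),
                   paste("not", substring(cl, 2L)), cl)
    s <- paste(lits, collapse = " and ")
    if (length(cl) > 1L) paste0("(", s, ")") else s
  }
  paste(vapply(clauses, fmt_cl, ""), collapse = " or ")
}

#' Serialize a Boolean network model to rule text
#'
#' Rules are written from the Blake canonical form of each function, in the
#' same dialect that [parse_rules()] reads, so the round trip preserves the
#' logic (up to equivalent rewriting).
#'
#' @param m a `boolean_model`.
#' @return character vector of rule lines.
#' @export
format_rules <- function(m) {
  vapply(m$nodes, function(n)
    paste(n, "*=", format_dnf(m$functions[[n]]$blake_on)), "")
}

#' @rdname format_rules
#' @param path output file path.
#' @export
write_rules <- function(m, path) {
  writeLines(format_rules(m), path)
  invisible(path)
}

#' Diagnostic report for a Boolean network model
#'
#' Lists source nodes, regulators dropped as inessential at parse time, and
#' the mean in-degree (essential regulators per node). Purely informational;
#' never raises.
#'
#' @param m a `boolean_model`.
#' @return a list of class `model_report` with elements `n_nodes`,
#'   `source_nodes`, `dropped_regulators`, `n_regulations`, `mean_in_degree`.
#' @export
validate_model <- function(m) {
  stopifnot(inherits(m, "boolean_model"))
  n_reg <- sum(vapply(m$functions, function(f) length(f$regulators), integer(1)))
  structure(list(
    n_nodes = length(m$nodes),
    source_nodes = m$source_nodes,
    dropped_regulators = m$dropped_regulators,
    n_regulations = n_reg,
    mean_in_degree = if (length(m$nodes) > 0L) n_reg / length(m$nodes) else NA_real_
  ), class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat("Boolean model:", x$n_nodes, "nodes,", x$n_regulations, "regulations",
      sprintf("(mean in-degree %.3g)\n", x$mean_in_degree))
  if (length(x$source_nodes) > 0L)
    cat("  source nodes:", paste(x$source_nodes, collapse = ", "), "\n")
  if (length(x$dropped_regulators) > 0L)
    cat("  inessential regulators dropped for:",
        paste(names(x$dropped_regulators), collapse = ", "), "\n")
  invisible(x)
}

#' @export
print.boolean_model <- function(x, ...) {
  cat("Boolean network model with", length(x$nodes), "nodes\n")
  for (ln in head(format_rules(x), 20L)) cat(" ", ln, "\n")
  if (length(x$nodes) > 20L) cat("  ...\n")
  invisible(x)
}
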