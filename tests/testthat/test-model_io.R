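test_that("rule parsing handles the worked example and flags sources", {
  m <- fig1_model()
  expect_s3_class(m, "boolean_model")
  expect_equal(m$nodes, paste0("n", 0:4))
  expect_equal(to_blake_dnf(m$functions$n0), list("~n3"))
  expect_equal(length(m$source_nodes), 0L)

  src <- parse_rules("A *= A")
  expect_equal(src$source_nodes, "A")

  f2a <- parse_rules(fig2a_rules)
  expect_equal(f2a$source_nodes, "A")
})

test_that("parse errors carry useful diagnostics", {
  expect_error(parse_rules("X *= Y or not Y\nY *= X"), "constant")
  expect_error(parse_rules("A *= B"), "undeclared")
  expect_error(parse_rules("A *= A\nA *= not A"), "duplicate")
  expect_error(parse_rules("A *= and A"), "unexpected")
  expect_error(parse_rules("A == B"), "expected")
  expect_error(parse_rules("A *= (B\nB *= B"), "parenthesis")
})

test_that("comments, case-insensitive keywords and symbols are accepted", {
  m <- parse_rules("# a comment\nA *= NOT b  # trailing\nb *= !A")
  expect_equal(to_blake_dnf(m$functions$A), list("~b"))
  expect_equal(to_blake_dnf(m$functions$b), list("~A"))
})

test_that("Blake canonical form matches the reference examples", {
  # (A AND B) OR (A AND C) is already a disjunction of prime implicants
  f <- parse_rules("A *= A\nB *= B\nC *= C\nD *= (A and B) or (A and C)")$functions$D
  expect_equal(to_blake_dnf(f), list(c("A", "B"), c("A", "C")))

  # negation of f4 = n0 OR n1 is the single AND clause ~n0 AND ~n1
  f4 <- fig1_model()$functions$n4
  expect_equal(to_blake_dnf(f4, negate = TRUE), list(c("~n0", "~n1")))

  # XOR given as a truth table
  fx <- boolean_function(c("A", "B"), c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(to_blake_dnf(fx), list(c("A", "~B"), c("B", "~A")))
})

test_that("Blake form is equivalent to the truth table and prime for random functions", {
  set.seed(41)
  vars <- c("a", "b", "c", "d", "e")
  for (rep in 1:25) {
    k <- sample(2:5, 1)
    tab <- sample(c(FALSE, TRUE), 2^k, replace = TRUE)
    if (all(tab) || !any(tab)) next
    f <- suppressWarnings(boolean_function(vars[1:k], tab))
    kk <- length(f$regulators)
    M <- matrix(FALSE, nrow = 2^kk, ncol = kk, dimnames = list(NULL, f$regulators))
    for (j in seq_len(kk)) M[, j] <- bitwAnd(0:(2^kk - 1), 2^(j - 1)) > 0
    on_vals <- apply(M, 1, function(row) eval_row <- {
      any(vapply(f$blake_on, function(cl) {
        all(vapply(cl, function(lit) {
          if (startsWith(lit, "~")) !row[[substring(lit, 2)]] else row[[lit]]
        }, logical(1)))
      }, logical(1)))
    })
    expect_equal(on_vals, unname(f$table))
    off_vals <- apply(M, 1, function(row) {
      any(vapply(f$blake_off, function(cl) {
        all(vapply(cl, function(lit) {
          if (startsWith(lit, "~")) !row[[substring(lit, 2)]] else row[[lit]]
        }, logical(1)))
      }, logical(1)))
    })
    expect_equal(off_vals, !unname(f$table))  # negate=TRUE is the complement
    # clause set equals the independent prime implicant enumeration
    expect_equal(f$blake_on, oracle_prime_implicants(f$regulators, f$table))
  }
})

test_that("inessential regulators are dropped with a warning", {
  expect_warning(
    m <- parse_rules("A *= A\nB *= B\nC *= A or (B and not B)"),
    "inessential")
  expect_equal(m$functions$C$regulators, "A")
  expect_equal(m$dropped_regulators$C, "B")
})

test_that("serialization round-trips to a logically equivalent model", {
  set.seed(77)
  for (rep in 1:10) {
    m <- random_test_model(sample(4:8, 1),
                           rule_type = sample(c("nested_canalizing", "effective"), 1))
    m2 <- parse_rules(format_rules(m))
    expect_equal(m2$nodes, m$nodes)
    for (nd in m$nodes) {
      # the reparsed function may list regulators in a different order; the
      # canonical Blake form is representation-independent, so equality there
      # is logical equivalence
      expect_setequal(m2$functions[[nd]]$regulators, m$functions[[nd]]$regulators)
      expect_equal(m2$functions[[nd]]$blake_on, m$functions[[nd]]$blake_on)
      expect_equal(m2$functions[[nd]]$blake_off, m$functions[[nd]]$blake_off)
    }
  }
})

test_that("validate_model reports sources and mean in-degree", {
  rep1 <- validate_model(fig1_model())
  expect_equal(rep1$n_nodes, 5L)
  expect_equal(length(rep1$source_nodes), 0L)
  # the five reference rules carry 8 essential regulations in total
  expect_equal(rep1$mean_in_degree, 8 / 5)

  rep2 <- validate_model(parse_rules(fig2a_rules))
  expect_equal(rep2$source_nodes, "A")

  rep0 <- validate_model(parse_rules(""))
  expect_equal(rep0$n_nodes, 0L)
  expect_true(is.na(rep0$mean_in_degree))
})
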