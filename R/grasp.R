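# Two-phase greedy randomized adaptive search for target control:
# randomized greedy construction (restricted candidate list thresholded at
# G_min + alpha (G_max - G_min)) followed by a redundancy-removing local
# search, repeated max_itr times; distinct locally minimal solutions are
# collected. The inner loops run in C++ on R's own RNG stream, so a seed
# fixes the whole solution list.

#' GRASP configuration
#'
#' @param max_itr number of independent construction + local-search rounds.
#' @param score_index greedy function: 1 = LDOI size, 2 = partially-fed
#'   composite count, 3 = their sum, 4 = LDOI size sign-flipped when the LDOI
#'   conflicts with the target, 5 = LDOI size shifted down by the largest
#'   single-state LDOI when it conflicts.
#' @param forbidden virtual node names never allowed in a solution.
#' @param seed RNG seed (`NULL` leaves the current RNG state untouched).
#' @return list of class `grasp_config`.
#' @export
grasp_config <- function(max_itr = 500L, score_index = 4L,
                         forbidden = character(), seed = NULL) {
  stopifnot(max_itr >= 1L, score_index %in% 1:5)
  structure(list(max_itr = as.integer(max_itr),
                 score_index = as.integer(score_index),
                 forbidden = forbidden, seed = seed),
            class = "grasp_config")
}

#' Greedy score of a candidate node state
#'
#' @param g an `expanded_network`.
#' @param v a virtual node name.
#' @param t target set (virtual node names); only used by the penalized
#'   scores 4 and 5.
#' @param score_index one of 1..5 (see [grasp_config()]).
#' @return numeric score.
#' @export
greedy_score <- function(g, v, t = character(), score_index = 1L) {
  stopifnot(score_index %in% 1:5)
  t <- check_consistent(t, "target set")
  scores <- cpp_scores(net_ptr(g), as_vindex(g, t, "target state"),
                       as.integer(score_index))
  setNames(scores, g$vnames)[[as_vindex(g, v)]]
}

#' Restricted candidate list
#'
#' Keeps the candidates whose score reaches
#' `G_pass = G_min + alpha * (G_max - G_min)`.
#'
#' @param scores named numeric vector of greedy scores.
#' @param alpha numeric in `[0, 1]`.
#' @return names of the qualifying candidates (never empty: the maximum
#'   always qualifies).
#' @export
make_rcl <- function(scores, alpha) {
  if (length(scores) == 0L) stop("empty candidate list")
  stopifnot(alpha >= 0, alpha <= 1)
  gpass <- min(scores) + alpha * (max(scores) - min(scores))
  names(scores)[scores >= gpass]
}

target_check <- function(g, t) {
  if (length(t) == 1L && grepl("=", t, fixed = TRUE)) t <- parse_states(t)
  t <- check_consistent(t, "target set")
  if (length(t) == 0L) stop("empty target set")
  as_vindex(g, t, "target state")
  t
}

#' Construct one greedy randomized candidate solution
#'
#' Starting from the candidate list of all virtual nodes except the target
#' states, their negations and any forbidden states, repeatedly draws a node
#' from the restricted candidate list (one `alpha` per call) and adds it to
#' the trial solution until the solution's LDOI covers the target; after each
#' addition the chosen node, its negation and every state in the trial
#' solution's LDOI are removed from the candidates. Returns `character(0)`
#' when the candidates are exhausted without covering the target.
#'
#' @param g an `expanded_network`.
#' @param t target set (virtual node names or a `Name=0/1` spec).
#' @param cfg a [grasp_config()].
#' @param protected node states placed in the solution up front and excluded
#'   from candidacy (damage-mitigation mode).
#' @return character vector of virtual node names (possibly empty).
#' @export
construct_solution <- function(g, t, cfg = grasp_config(), protected = character()) {
  t <- target_check(g, t)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  res <- cpp_construct(net_ptr(g), as_vindex(g, t),
                       as_vindex(g, cfg$forbidden),
                       as_vindex(g, check_consistent(protected)),
                       cfg$score_index)
  g$vnames[res]
}

#' Redundancy-removing local search
#'
#' Randomized removal passes over the nodes of a covering solution, removing
#' each node whose removal keeps the target covered, repeated until no node
#' can be removed (because the truncation rule makes the LDOI non-monotone,
#' a removal can re-enable an earlier one). Protected nodes are never
#' removed. The result is locally minimal.
#'
#' @param g an `expanded_network`.
#' @param t target set.
#' @param s covering intervention set (`covers(g, s, t)` must hold).
#' @param protected subset of `s` that must stay.
#' @return a `grasp_solution`: list with `interventions`, `ldoi`, and
#'   `iteration_found` (`NA` here).
#' @export
local_search <- function(g, t, s, protected = character()) {
  t <- target_check(g, t)
  s <- check_consistent(s, "intervention set")
  stopifnot(all(protected %in% s))
  if (!covers(g, s, t)) stop("local_search requires a covering solution")
  res <- cpp_local_search(net_ptr(g), as_vindex(g, t), as_vindex(g, s),
                          as_vindex(g, protected))
  new_solution(g, g$vnames[res], NA_integer_)
}

new_solution <- function(g, interventions, iteration) {
  structure(list(
    interventions = interventions,
    ldoi = compute_ldoi(g, interventions),
    iteration_found = iteration
  ), class = "grasp_solution")
}

#' @export
print.grasp_solution <- function(x, ...) {
  cat("{", paste(x$interventions, collapse = ", "), "}  |LDOI| = ",
      length(x$ldoi$members), "\n", sep = "")
  invisible(x)
}

grasp_run <- function(g, t, cfg, protected = character()) {
  t <- target_check(g, t)
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  raw <- cpp_grasp(net_ptr(g), as_vindex(g, t),
                   as_vindex(g, cfg$forbidden), as_vindex(g, protected),
                   cfg$max_itr, cfg$score_index)
  sols <- lapply(seq_along(raw$solutions), function(i)
    new_solution(g, g$vnames[raw$solutions[[i]]], raw$iteration[i]))
  # soundness is asserted on every return
  stopifnot(all(vapply(sols, function(s) all(t %in% s$ldoi$members), logical(1))))
  sols
}

#' GRASP target control
#'
#' Runs `cfg$max_itr` independent greedy randomized constructions, each
#' followed by a local search, and returns the distinct locally minimal
#' intervention sets found whose LDOI covers the target. Reproducible under
#' a fixed `cfg$seed`. An empty list means no solution was found (which,
#' for admissible targets, is rare but possible).
#'
#' @param g an `expanded_network`.
#' @param t target set (virtual node names or a `Name=0/1` spec).
#' @param cfg a [grasp_config()].
#' @return list of `grasp_solution` objects (deterministic order).
#' @examples
#' m <- parse_rules("A *= B\nB *= A")
#' g <- build_expanded(m)
#' sols <- grasp(g, "A", grasp_config(max_itr = 50, seed = 1))
#' @export
grasp <- function(g, t, cfg = grasp_config()) {
  grasp_run(g, t, cfg)
}

#' Damage mitigation as target control
#'
#' Solves the target control problem in the presence of a permanently damaged
#' node state: the solution is initialized with the damage, the damage is
#' forbidden from removal in the local search, and every returned intervention
#' set contains it. With empty damage this reduces to [grasp()].
#'
#' @param g an `expanded_network`.
#' @param t target set.
#' @param damage damaged node states (consistent; disjoint from `t`).
#' @param cfg a [grasp_config()].
#' @return list of `grasp_solution` objects, each containing `damage`.
#' @export
mitigate_damage <- function(g, t, damage, cfg = grasp_config()) {
  t <- target_check(g, t)
  damage <- check_consistent(damage, "damage set")
  if (length(intersect(damage, t)) > 0L) stop("damage must be disjoint from the target")
  if (any(negation_of(t) %in% damage)) {
    warning("damage conflicts with the target; no solution can cover it")
    return(list())
  }
  grasp_run(g, t, cfg, protected = damage)
}
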