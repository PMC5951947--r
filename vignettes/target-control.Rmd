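---
title: "Target control of Boolean networks with the logical domain of influence"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Target control of Boolean networks with the logical domain of influence}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A Boolean network assigns each node $i$ a state $\sigma_i \in \{0,1\}$ and an
update rule $\sigma_i(t+1) = f_i(\sigma_{i_1}, \dots, \sigma_{i_k})$ over its
regulators. Rules must not be constant; a *source node* is a node whose rule
is the identity on its own state, the standard encoding of a sustained
external signal. We model two update schemes: synchronous (all nodes at
once) and general asynchronous (one uniformly chosen node per step). Fixed
points are scheme-independent; limit cycles and complex attractors are not.

`parse_rules()` reads the plain-text dialect `name *= expr` (and/or/not,
parentheses, `#` comments). Each rule is converted at parse time to its
truth table and then to the *Blake canonical form* — the disjunction of all
prime implicants, computed by the first (combining) phase of
Quine–McCluskey — for the rule and for its negation. Regulators absent from
every prime implicant are inessential; we drop them with a warning rather
than reject the model, since curated models occasionally carry them. Literal
and clause ordering is canonicalized (radix sort), so the downstream graph
never depends on the order in which rules were written.

## The expanded network

The expanded network has two virtual nodes per model node ($n_i$ for ON,
$\sim\! n_i$ for OFF) and one composite node per multi-literal prime
implicant; single-literal implicants become direct edges. The in-edges of
$n_i$ encode Blake$(f_i)$ and those of $\sim\! n_i$ encode
Blake$(\lnot f_i)$, so every edge is a positive ("sufficient") relationship
and every composite is a conjunction ("necessary") gate. Composite nodes are
deduplicated globally by their literal set — two rules sharing an AND clause
share the gate — which shrinks the graph and changes nothing in the
propagation semantics. Source nodes carry explicit self-edges on both of
their virtual nodes.

## The logical domain of influence

`compute_ldoi()` runs a modified breadth-first search from the intervention
states $S$: a virtual node is stabilized when reached; a composite is
traversed only once *all* its inputs are stabilized (tracked by a pending
count per gate, giving the $O(N_{ex} + E_{ex})$ contract); and any arrival
at the negation of an intervention state is *truncated* — flagged as a
conflict, never added, never expanded. Sets with a conflict are
*incompatible*; for compatible sets the union bound
$\bigcup_i \mathrm{LD}(v_i) \subseteq \mathrm{LD}(\cup_i v_i)$ holds.

One convention deserves care: when does an intervention state belong to its
*own* LDOI? We count a re-visit only when it arrives through an edge that
does not depend on the state itself — a different virtual node, or a
composite not containing it. A source node's self-loop therefore does not
put the source state into its own LDOI. This is exactly the three-valued
steady-state reading: a clamped node joins the members iff its rule is
determined to the clamped value with its own state treated as unknown. The
test suite checks the equivalence of the BFS with an independent
constant-substitution oracle on hundreds of random networks.

The same convention settles self-inclusion for the brute-force DOI
(`brute_force_doi()`): a clamped state is in its own DOI iff its rule
evaluates to the clamped value on every attractor state of the clamped
system with its own state unknown. A literal "release the clamp and re-run"
test would wrongly include every source node in its own DOI. By default the
DOI requires constancy under both update schemes (the conservative reading
of "any updating regime"); per-scheme results are available, and the
scheme-dependent divergence between DOI and LDOI — stabilization through
inconsistent feedback or through an oscillation — is exercised by the
worked examples in the tests.

## Stable motifs

A stable motif is a minimal strongly connected subgraph of the expanded
network that contains no virtual node together with its negation and
contains every input of each of its composite members; its virtual members
read out a self-sustaining partial fixed point. The enumeration restricts
the graph to closed consistent subsets (iteratively deleting composites with
missing inputs, branching on conflicting pairs), takes strongly connected
components with igraph, and recursively searches every valid component for
strictly smaller motifs, keeping the minimal ones under state-set inclusion.
Single source states are (trivial) motifs. The recursion is memoized but
exponential in the worst case; it is a reporting and property-testing
surface, bounded at 30 model nodes by default (`max_nodes`). Motif *cores*
(minimal subsets whose LDOI contains the motif) come from exhaustive subset
search in increasing size with superset pruning; `is_driver_set()` uses
LDOI containment, a sufficient condition — oscillation-mediated motif
stabilization is only visible to the dynamics oracle.

## GRASP target control

A solution is an intervention set whose LDOI covers the target; it certifies
target control from every initial condition. Each of `max_itr` (default
500) independent rounds draws one $\alpha \sim U(0,1)$, scores every
candidate with the chosen greedy function, and repeatedly picks uniformly
from the restricted candidate list
$\{v : G(v) \ge G_{\min} + \alpha (G_{\max} - G_{\min})\}$, recomputing the
bounds over the current candidates. After each addition the chosen state,
its negation, and every state in the trial solution's LDOI leave the
candidate list. Candidates never include the target states or their
negations, nor anything in `forbidden`.

The five greedy functions are: (1) $|\mathrm{LD}(v)|$; (2) the number of
composite gates partially fed by $\mathrm{LD}(v) \cup \{v\}$ — we read
"nearest-neighbor composites" as gates receiving at least one input but not
fully activated, rewarding candidates that help complete AND gates; (3)
their sum; (4) score 1 sign-flipped and (5) score 1 shifted down by the
largest single-state LDOI, both applied when $\mathrm{LD}(v)$ contains the
negation of a target state. The penalized scores matter: with score 1, a
needed state whose LDOI is empty (typically a source state feeding an AND
gate) is the strict minimum scorer and can essentially never enter the
candidate list while better-scoring states remain, so some targets are
systematically unreachable; score 4 pushes the *conflicting* states below
zero and rescues exactly these cases. Score 4 is the default.

The local search randomizes the removal order once and then repeats removal
passes until no node can be dropped without losing coverage. A single pass —
a plausible alternative reading — does not guarantee local minimality,
because the truncation rule makes the LDOI non-monotone in the intervention
set: removing one node can make an earlier node removable. Descending to a
local optimum is the canonical GRASP local-search contract and is what makes
the returned solutions locally minimal, a property the test suite asserts
for every returned solution. Distinct solutions are collected across rounds
by exact set equality.

`mitigate_damage()` treats a permanent damage as part of the intervention:
the construction starts from the damaged states and the local search never
removes them, so every solution contains the damage and its LDOI (damage
included) covers the target. Damage holding the negation of a target state
is rejected up front — truncation makes coverage impossible.

All stochastic steps consume R's own RNG stream (also inside the C++
loops), so a seed fixes the entire solution list.

## Random ensembles

The generator emulates sparse regulatory networks: directed Erdős–Rényi
graphs with $m$ distinct non-self edges drawn uniformly over ordered pairs,
$n$ between 15 and 50 and mean in-degree between 1 and 2 by default. Nodes
left without regulators get an identity self-rule and become source nodes —
rules may not be constant, and a free input signal is the natural repair.
Rules are either *nested canalizing* (random canalizing input and output
sequences over a random regulator order, following the standard hierarchy;
always non-constant and essential in every input) or *effective* (truth
tables rejection-sampled until non-constant with every input essential).

Admissible targets satisfy two criteria: (i) the target is a subset of a
(partial) fixed point — drawn from conflict-free self-contained single-state
LDOIs, which certify partial fixed points cheaply, plus fixed points from a
constraint-propagation solver capped at 64 solutions (source nodes double
the fixed-point count, so exhaustive enumeration is hopeless at $n = 50$);
and (ii) *every* target node has a regulator outside the target set. We read
the accessibility criterion node-wise because a source-node state can never
be covered by any other intervention — its only in-edge is its own
self-loop, and as a target it is barred from candidacy — so the looser
set-wise reading would make a large fraction of "admissible" targets
provably unsolvable, inconsistent with the near-perfect success rate the
method is known to achieve.

What the generator does not emulate: scale-free degree structure, the
enrichment of biological rule repertoires beyond canalization, or
multi-level nodes. Passing ensemble tests therefore speak to the algorithm's
behavior on sparse random logic, not to any particular curated model.

## Numerical choices and problem sizes

Canonical radix sorting everywhere (clauses, literals, solution sets) keeps
results locale- and input-order-independent. The dynamics oracle enumerates
$2^n$ states and is bounded at 16 nodes (the property suites use 8–12);
fixed-point solving by three-valued propagation over the Blake forms with
branching handles $n = 50$ sparse networks easily. The test suites run
roughly 200 random networks for the LDOI/DOI/motif properties and
30–50-network ensembles with 10 targets each and 500 GRASP iterations per
target for the benchmark statistics; the whole suite completes in a few
minutes on one CPU.

## Known limitations

The LDOI is a sufficient certificate: interventions that control a target
only through oscillations or mutually inconsistent feedback are invisible to
it (the dynamics oracle exposes such cases on small networks). GRASP bounds
the optimum from above and enumerates many, not provably all, minimal
solutions — under any single greedy score the restricted candidate list has
systematic blind spots, so exhaustive small-solution recovery requires
pooling runs across the greedy functions, as the test suite does.
Mean distinct-solution counts on random ensembles depend on ensemble details
(degree distribution, target sampling) that admit a range of reasonable
choices; the effective-rule ensemble here yields means around 19–23 rather
than the high-20s, while the nested-canalizing ensemble and the success-rate
behavior match expectations.
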