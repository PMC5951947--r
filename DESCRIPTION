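Package: booldoi
Title: Target Control of Boolean Networks via the Logical Domain of Influence
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for target control of Boolean network models of biomolecular
    systems. Regulatory rules are parsed from a plain-text dialect, converted to
    Blake canonical form (all prime implicants, via Quine-McCluskey), and
    assembled into the expanded network of virtual (node, state) nodes and
    composite AND nodes. The logical domain of influence (LDOI) of a sustained
    intervention is computed by a truncated breadth-first search on that graph,
    and minimal sustained-intervention sets whose LDOI covers a target node-state
    set are found with a two-phase greedy randomized adaptive search procedure
    (GRASP), including a damage-mitigation mode. Also included: stable motif
    identification with cores and driver sets, a brute-force dynamics oracle
    (attractors, fixed points, true domains of influence) for small networks,
    and a random Boolean network ensemble harness with Erdos-Renyi topologies
    and nested canalizing or effective rules.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
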