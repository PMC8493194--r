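Package: crnscape
Title: Exploration of DNA Self-Assembly Reaction Networks
Version: 0.1.0
Authors@R: person("crnscape", "developers", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools to explore the space of chemical reaction networks (CRNs)
    that arise from small sets of DNA strands interacting at the domain level.
    Provides a kernel-notation data model for multistranded, pseudoknot-free
    complexes, exhaustive (n, m) strand libraries, a domain-level reaction
    enumerator (hybridization, dissociation, three- and four-way branch
    migration) with resting/transient condensation, a MAP-Elites
    quality-diversity search over strand subsets, a pluggable
    minimum-free-energy folding oracle with domain-level well-formedness
    checks, sequence optimization by elitist genetic algorithm or random
    search, and network-science analyses (density, assortativity, power-law
    degree fits, clustering, global reaching centrality, flow hierarchy,
    centralities) of the resulting reaction graphs.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    Biostrings,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
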