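Package: retromotif
Title: Motif-Based Autoregressive Graph Generation for Single-Step
    Retrosynthesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Single-step retrosynthesis prediction as autoregressive
    molecular-graph generation. Atom-mapped reactions are decomposed into
    transformation paths: reaction-center edits (bond order changes and
    removals, hydrogen/charge changes) that turn a product into synthons,
    followed by attachment of motifs drawn from a vocabulary extracted from
    training reactants under ring-aware cutting rules and organised in
    junction trees. A graph-transformer encoder with edge-feature-biased
    attention and a GRU decoder with five prediction heads (action, edit
    target, edit type, motif, interface) are trained teacher-forced to emit
    such paths; beam search decodes unmapped products into ranked reactant
    sets scored by log-likelihood, evaluated by Top-k canonical-SMILES
    accuracy. Includes a deterministic synthetic-reaction generator so the
    whole pipeline is testable without external data. Canonical SMILES are
    produced through OpenBabel.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    tibble,
    utils,
    withr
Suggests:
    ggplot2,
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: OpenBabel (the 'obabel' executable on PATH)
Config/testthat/edition: 3
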