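Package: dualguide
Title: Design and Analysis of Dual-Guide CRISPRi Genetic Modifier Screens
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for pooled dual-sgRNA CRISPRi modifier screens, in which a
    fixed "anchor" guide establishes a sensitized genetic background and a
    genome-wide variable guide identifies modifiers of a FACS reporter
    phenotype. Covers in-silico dual-guide library construction (annealing
    oligo design, restriction-site attrition, coverage arithmetic), a
    synthetic-data generator for reporter sorting screens built on a
    two-pathway redundancy flux model, exact-match guide counting from reads,
    the guide-to-gene scoring chain (count filtering, control-normalized log2
    enrichment, strongest-k gene phenotypes, Mann-Whitney tests against
    non-targeting controls, discriminant ranking), and anchored-versus-control
    screen comparison that classifies genes as synthetic, same-pathway, or
    orthogonal interactors.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
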