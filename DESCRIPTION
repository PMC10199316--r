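Package: flexalign
Title: Flexible RMSD-Bounded Alignment of Nucleic Acid 3D Structures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Two customizable heuristics for flexible, sequence-dependent or
    sequence-independent alignment of RNA and DNA tertiary structures under a
    hard user-defined RMSD ceiling: GEOS, a geometric kernel search with greedy
    extension, and GENS, a genetic algorithm over residue-assignment
    chromosomes. Structures are reduced to a 3-bead coarse-grained model
    (phosphate, ribose, base pseudoatoms at group geometric centers) and both
    heuristics return the longest alignment whose bead-level RMSD after optimal
    rigid superposition does not exceed the threshold. Includes PDB/mmCIF input
    and output, a deterministic synthetic-structure generator for testing, an
    exhaustive alignment oracle for toy instances, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
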