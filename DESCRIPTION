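Package: coldcurve
Title: Protein Stability Curves, Cold Denaturation and Contact-Persistence Networks
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for two-state protein folding thermodynamics with explicit
    cold denaturation. Fits the constant-heat-capacity Gibbs-Helmholtz model,
    with linear folded/unfolded baselines, to circular-dichroism thermograms
    that show both cold and heat transitions, and derives the full stability
    curve: melting temperature, cold-denaturation temperature, temperature of
    maximal stability, unfolding entropy and equilibrium folded fraction.
    Also builds persistence-weighted residue-residue interaction networks from
    molecular-dynamics trajectory snapshots (multi-model PDB or precomputed
    distance tables), restricting nodes to residues charged in at least one
    sequence of an orthologue alignment and filtering contacts by the fraction
    of frames spent within a distance threshold. Includes deterministic
    synthetic-data generators (thermograms, toy trajectories, alignments) so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    bio3d,
    igraph,
    jsonlite,
    minpack.lm
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
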