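Package: pkadirect
Title: Direct-Approach DFT pKa Determination for Substituted Benzoic Acids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for computing aqueous pKa of substituted benzoic acids by the
    thermodynamic "direct approach": the deprotonation reaction by hydroxide is
    modelled explicitly with two water molecules at the reaction center and a
    continuum solvent, and pKa is obtained from the reaction Gibbs free energy
    anchored to the pKa of water. Includes a micro-solvated cluster builder, a
    pluggable quantum-chemistry engine contract with a Gaussian-dialect log
    parser, input-deck writer and a deterministic mock engine, reaction-center
    geometry diagnostics (hydrogen-bond lengths, carboxyl-ring dihedrals), and
    functional-benchmarking statistics (MAE, calculated-versus-reference
    regression, computational-cost accounting) with table renderers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ChemmineR,
    ChemmineOB,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
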