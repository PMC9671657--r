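Package: acr3kit
Title: Comparative Sequence and Structure Analysis of Acr3-Family Arsenite Transporters
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A reusable pipeline for comparative characterization of
    homologous membrane-transporter families, developed around the Acr3
    arsenite-efflux permease. Provides codon-level selection statistics
    (Nei-Gojobori dN/dS), pairwise-identity matrices with classical MDS
    ordination and neighbor-joining trees, hydropathy-based transmembrane
    topology with compartment assignment, secondary structure and
    discontinuous-helix detection from coordinates, alpha-carbon contact
    maps and aligned contact-map differencing, residue interaction
    networks, geometric hydrogen-bond detection, and a simplified
    single-snapshot MM-GBSA per-residue binding-energy decomposition.
    A synthetic-data module generates helix-bundle structures and codon
    families with known ground truth so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    ape,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
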