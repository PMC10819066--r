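Package: cavstat
Title: Cavity Location and Flexibility Statistics for Protein Thermostability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects interior solvent-inaccessible cavities in protein
    structures with a spherical probe on a uniform 3-D grid, classifies each
    cavity into surface, boundary or core regions by the occluded-surface
    packing (OSP) of its lining residues, normalizes crystallographic B
    factors per chain, and contrasts two groups of structures (typically
    thermophilic versus mesophilic homolog pairs) with one-tailed two-sample
    t statistics on per-protein cavity-region frequencies and flexibility
    indices. Includes a seeded synthetic-structure and two-group cohort
    generator so the whole pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
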