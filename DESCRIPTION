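Package: atomcharge
Title: Empirical Partial Atomic Charges for Small Molecules and
    Biomacromolecules
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Calculates partial atomic charges with the main empirical
    (non-quantum) charge schemes: the iterative graph-based methods PEOE
    (Gasteiger-Marsili), MGC, VEEM, Del Re and GDAC, and the
    electronegativity-equalization family EEM, SFKEEM, QEq, EQeq and
    EQeq+C, which solve a constrained linear system over interatomic
    distances.  Ships a registry of published parameter sets with
    per-molecule applicability checking and automatic method selection,
    reads SDF (V2000), MOL2, PDB and mmCIF structures (also zip/tar.gz
    archives of them), perceives bonds from covalent radii when a format
    lacks them, and writes charges as PQR, MOL2 or plain text.  Very
    large structures are handled by cutoff and cover approximations of
    the equalization system with automatic routing by atom count.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    ChemmineR,
    bio3d,
    jsonlite,
    graphics,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
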