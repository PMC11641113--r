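Package: slayermap
Title: Lattice Mapping and Geometric Census of Cylindrical S-Layers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse the hexagonal surface-layer (S-layer) lattice of
    cylindrical prokaryotic cells from subtomogram-averaging particle poses.
    Generates seeded synthetic hexagonal lattices wrapped on cylinders (with
    helical offset, positional noise, dropout, vacancies and elliptical
    flattening) and concentric envelope layer point clouds; reads and writes
    particle pose tables in the RELION STAR dialect; reconstructs the lattice
    as a neighbour graph with three tiling-direction classes and detects
    coordination defects; estimates per-particle principal curvatures by local
    quadric fitting and partitions particles into flat and curved subsets;
    fits each cell's cylinder axis and measures the angle between the axial
    tiling direction and that axis; and computes the geometric census of an
    S-layer tube: lattice repeats, hexamer and monomer copy numbers, the
    per-tile pore count with interface sharing, surface-area-to-volume
    comparison against an equal-volume sphere, and dimpled-surface area
    enhancement.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    minpack.lm,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
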