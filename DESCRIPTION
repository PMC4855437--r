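Package: chemspace3d
Title: Color-Coded 3D Chemical Space Maps of Small-Molecule Libraries
Version: 0.1.0
Authors@R: person("chemspace3d", "maintainers", email = "maintainers@example.org",
    role = c("aut", "cre"))
Description: Standardizes small-molecule libraries (SDF V2000 or SMILES text),
    computes five molecular fingerprints (molecular quantum numbers, SMILES
    character counts, atom-pair shape, pharmacophore category atom-pair, and a
    hashed binary substructure fingerprint), projects each fingerprint space to
    three dimensions by principal component analysis, bins molecules onto a
    300x300x300 grid with hue-saturation-lightness property color coding,
    computes resolution and distance-correlation diagnostics, overlays external
    molecule sets into a fitted space, performs exact nearest-neighbor searches
    in the original fingerprint spaces, and exports portable JSON/HTML 3D
    scenes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
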