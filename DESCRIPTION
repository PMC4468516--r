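Package: sitemoiety
Title: Site-Moiety Maps for Binding-Site Anchors and Anchor-Based Virtual Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds site-moiety maps of protein binding sites from ensembles of
    docked ligand poses. Protein-ligand contacts are typed (hydrogen-bond,
    electrostatic, van der Waals) and scored with a piecewise linear potential;
    per-residue interaction profiles are screened for consensus interactions by
    a permutation Z-score; consensus interactions are clustered into spatial
    anchors with functional-group (moiety) preferences. Anchors are aligned
    across superimposed protein panels into core and specific anchors, proteins
    are classified by specific-anchor presence, and screening compounds are
    ranked by a combined anchor-match and docked-energy score. Includes a
    synthetic fixture generator with planted interaction hotspots for
    validation, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    ChemmineR,
    igraph,
    jsonlite,
    methods,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
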