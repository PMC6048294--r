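Package: sc4a
Title: Canonical Correspondence Analysis and Single-Cell Combinatorial
    CCA for T Cell Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Constrained ordination of gene-by-sample expression tables by
    canonical correspondence analysis (CCA), with explanatory variables
    built from differential-expression contrasts between activated and
    resting T cells. Extends CCA to unannotated single-cell data through
    the single-cell combinatorial CCA (SC4A) procedure, which selects one
    representative gene per cell population by pairwise CCA tournaments
    scored on biplot-arrow angles and F1, and uses the selected genes as
    explanatory variables for a final constrained solution. Downstream
    tools cluster cell scores with Gaussian mixtures, build minimum
    spanning trees over cluster centroids, extract bifurcating lineages
    with per-cell pseudotime, and summarise gene-module trajectories,
    quadrant gates and gene-set intersections. Includes seeded generators
    for bulk contrasts and single-cell fixtures with planted markers and
    trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    Matrix,
    mclust,
    limma,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    yaml,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
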