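Package: biofilmshear
Title: Lattice-Spring Simulation of Biofilm Shear Mechanics
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Mesoscale simulation of the shear response of bacterial
    biofilms treated as a two-phase composite of rigid bacteria embedded in
    a soft extracellular polymeric substance (EPS) matrix.  A digitized
    binary microstructure is mapped onto a triangular lattice of axial
    springs; EPS springs strain-stiffen by sequential unfolding of eight
    folded sub-springs with quenched random energy thresholds and
    ultimately rupture, so that quasi-static incremental shear reproduces
    loading-dependent stiffness, diagonal strain localization, the
    stiffening-to-softening crossover, and detachment of bacteria from the
    load-bearing network.  Includes a synthetic rod-shaped microstructure
    generator (uniform, centrally clustered, corner clustered), effective
    stiffness analysis against Hashin-Shtrikman bounds, localization maps,
    and detachment detection.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr,
    png,
    tiff,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
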