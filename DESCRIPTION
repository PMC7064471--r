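Package: scaffseed
Title: Cell Seeding Simulation on 3D-Printed Lattice Scaffolds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale simulation of the cell seeding process on open-cell
    lattice scaffolds in a culture well.  Builds parametric cubic cross-link
    and truncated-octahedron lattice scaffolds, measures their porosity and
    surface-to-volume metrics, fills the well with a laminar incompressible
    free-surface flow on a staggered grid, tracks cells as Lagrangian
    particles under drag and buoyancy, classifies every cell-scaffold impact
    into stick, rebound, spread or splash regimes by a dimensionless impact
    energy with wall-film bookkeeping, and aggregates seeding efficiency,
    attachment time series and lateral attachment distributions.  Includes a
    synthetic two-channel confocal image generator and the matching
    grid-based live/dead cell counting pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    EBImage,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
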