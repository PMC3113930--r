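Package: nanovssa
Title: Electron Tomography Simulation and Volume-Specific Surface Area
    Metrology for Nanomaterials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and metrology pipeline for measuring the
    volume-specific surface area (VSSA) of nanomaterials by conventional
    bright-field electron tomography. Generates voxel phantoms of spherical,
    branched and aggregated nanoparticles with analytic or fine-grid ground
    truth; simulates single-axis tilt-series acquisition under mass-thickness
    contrast with missing wedge, shot noise and stage jitter; aligns series by
    iterative cross-correlation with tilt-axis refinement; reconstructs by
    weighted back projection, SIRT and ART; segments reconstructions by
    bimodal-valley or Otsu thresholding with 2x2x2 smoothing and 3D connected
    components; extracts watertight isosurface meshes and measures surface
    area, enclosed volume and VSSA against the 60 m2/cm3 nanostructure
    threshold; and validates measured areas and volumes against
    equivalent-circle-diameter sphere formulas with Spearman rank correlation
    and one-sample t statistics. Volumes and tilt stacks are read and written
    as MRC2014 with JSON sidecars; meshes as STL or PLY; metrics as CSV.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
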