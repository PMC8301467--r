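Package: mandimorph
Title: Longitudinal Micro-CT Morphometry of Continuously Erupting Dentition
Version: 0.1.0
Authors@R:
    person("Mandimorph", "Developers", email = "mandimorph@example.org",
           role = c("aut", "cre"))
Description: Analysis pipeline for longitudinal micro-CT studies of elodont
    (continuously erupting) dentition in rodent and lagomorph mandibles.
    Provides rigid mutual-information co-registration of follow-up scans to
    baseline via Nelder-Mead simplex optimization, reorientation to the molar
    occlusal plane, incisor path-length and occlusal-angle morphometry in the
    sagittal plane, cheek-tooth height measurement, and left-right symmetry
    statistics (paired-t and bootstrap confidence intervals, baseline-referenced
    Z scores). A voxel hemi-mandible phantom generator with analytically known
    geometry, surgical defect modes, and a parametric cohort simulator make
    every stage verifiable without animal scan data. Includes minimal NIfTI-1
    and MetaImage volume I/O.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    ggplot2,
    stats,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
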