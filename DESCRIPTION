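Package: cryobuild
Title: Template-Based Model Building for High-Resolution Cryo-EM Density Maps
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automatic interpretation of high-resolution (about 3.5 Angstrom or
    better) single-particle cryo-EM density maps. Provides MRC2014/CCP4 volume
    and PDB coordinate input/output, construction of alpha-helix and beta-strand
    density templates (mean map plus distance-binned correlation map) from a
    training map/model pair, fast template search with weighted-correlation
    scoring and Nelder-Mead rigid-body pose refinement, global voxel-size
    (magnification) calibration by correlation-maximising factor scanning,
    Guinier-plot amplitude scaling of a reference map, and log-likelihood-driven
    C-alpha chain extension with optional sequence/side-chain assignment.
    Includes a synthetic fixture generator (ideal secondary-structure geometry,
    Gaussian-atom density simulation) so the whole pipeline can be exercised
    without external depositions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    bio3d,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
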