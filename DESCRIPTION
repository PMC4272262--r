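Package: g4hydro
Title: Hydrodynamic and Spectroscopic Model Discrimination for Multimeric
    G-Quadruplexes
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for deciding between candidate solution structures of
    long, G-rich promoter sequences that can fold into several contiguous
    G-quadruplexes. Implements sequence-derived physical properties
    (molecular weight, nearest-neighbour extinction coefficients), molar
    circular dichroism normalization and composite-spectrum prediction,
    construction of idealized atomic models (stacked parallel quadruplex
    columns, unstacked beads-on-a-string arrangements, and
    duplex-quadruplex hybrids), rigid-body bead-shell hydrodynamics
    (sedimentation coefficients, frictional ratios, rotational relaxation
    times), Perrin-plot fluorescence polarization analysis,
    frequency-domain fluorescence lifetime fitting, and a scoring step
    that ranks structural models against observed hydrodynamic and
    spectroscopic quantities. Seeded synthetic-data generators emulate
    every measurement the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    bio3d,
    minpack.lm
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    Biostrings
Config/testthat/edition: 3
RoxygenNote: 7.3.3
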