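Package: cordparc
Title: Histology-Informed Parcellation of Spinal Cord White Matter Tracts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for data-driven parcellation of spinal cord white matter
    from pixelwise axon and myelin morphometry maps (axon density, axon
    diameter, axon volume fraction, g-ratio, myelin thickness).  Provides a
    connectivity-constrained agglomerative clustering engine (Ward linkage,
    Euclidean affinity) with slice-wise and region-wise drivers, a 2D affine
    plus B-spline free-form-deformation registration engine with displacement
    field composition for step-by-step slice chaining, template building with
    right-left symmetrization, partial-volume tract atlas aggregation,
    overlap-based matching and coloring against a reference tract atlas, and
    a synthetic spinal cord phantom generator that emulates per-tract
    morphometric signatures so the whole pipeline is testable without any
    microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    igraph,
    mclust,
    png,
    stats,
    grDevices,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
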