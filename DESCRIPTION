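Package: orthoseg3d
Title: Consensus 3D Instance Segmentation from Orthogonal 2D Views
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assembles a consensus 3D instance segmentation of cells from
    independent 2D instance segmentations (or predicted 2D gradients and
    cell-probability maps) of the three orthogonal view stacks of a volume.
    Two-dimensional masks are converted to distance-transform gradient
    fields (Euclidean, Poisson, or geodesic; implicit medial-axis or
    explicit point/skeleton attractors), fused across views by
    content-based averaging, and all foreground voxels are advected by
    suppressed gradient descent with momentum to their medial-axis
    attractors; density-based connected-component clustering of the
    advected points yields object labels, which are mapped back to the
    original voxels. Includes quality-control filters, label diffusion and
    guided-filter refinement against an intensity guide image, a synthetic
    3D morphotype generator (convex packings, branched tubes, thin vessel
    networks) with an orthoview slicing and corruption protocol, and
    average-precision / F1 instance-matching evaluation curves.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    EBImage,
    Matrix,
    Rcpp,
    methods,
    stats,
    tiff,
    yaml,
    jsonlite,
    tibble,
    ggplot2,
    generics,
    optparse
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
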