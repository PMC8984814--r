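Package: pcage
Title: Enumeration and Geometric Optimization of Near-Miss Polyhedral Cages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for characterizing homogeneous connectivity-invariant
    polyhedral cages (p-cages): assemblies of planar, nearly regular polygons
    separated by holes, the geometry underlying engineered protein nano-cages
    such as the TRAP-cage. The package constructs the convex uniform solids
    that act as hole-polyhedra, enumerates all connectivity-invariant
    distributions of hole edges over their vertex corners, prunes candidates
    with angle-sum and hole-edge-length constraints, realizes each candidate
    in 3-D by minimizing a face-deformation quality functional with a
    Metropolis plus downhill-simplex scheme, and classifies the results as
    regular, near-miss, or rejected cages. Includes OFF/OBJ mesh export,
    triangle-triangle self-intersection checks, and tidy catalog output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    tibble,
    dplyr,
    purrr,
    tidyr,
    ggplot2,
    generics,
    rlang,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
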