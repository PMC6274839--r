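Package: coilflex
Title: Bending Flexibility and Persistence Length of Coiled-Coil Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis of the bending flexibility of two-chain alpha-helical
    coiled-coil proteins from conformational ensembles (molecular dynamics
    snapshots or synthetic worm-like-chain draws). Approximates the coiled-coil
    axis by a polygonal line through weighted centroids of residue segments,
    computes tangent-correlation profiles against the time-averaged tangent,
    estimates persistence length by least-squares and secant slope estimators,
    converts it to bending stiffness, locates locally flexible regions, counts
    main-chain hydrogen bonds over residue regions, and profiles inter-helix
    distances. Includes a discrete Kratky-Porod chain sampler and a
    pseudo-atomic coiled-coil builder for parameter-recovery validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
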