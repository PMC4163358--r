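Package: grassnpp
Title: Light-Use-Efficiency Modelling of Grassland Net Primary Productivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A CASA-style light-use-efficiency model for monthly grassland net
    primary productivity (NPP) on raster grids. Computes absorbed
    photosynthetically active radiation from solar radiation and FPAR,
    temperature stress scalars around an optimal temperature, and a moisture
    stress scalar from vapor-pressure deficit derived from land-surface
    temperature and total precipitable water. Includes the preprocessing the
    model needs (8-day to monthly compositing, temporal spline gap-filling,
    elevation-aware interpolation of station temperatures), in-situ validation
    of modelled NPP against dry-yield surveys via biomass-to-carbon conversion
    with root:shoot allocation, spatiotemporal partition statistics, and a
    seeded synthetic-scene generator so the whole pipeline is testable without
    satellite downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    mgcv,
    jsonlite,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
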