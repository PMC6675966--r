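Package: sfddepth
Title: Optical Sampling Depth in the Spatial Frequency Domain
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Monte Carlo photon-packet transport in laterally infinite layered
    turbid media with complex-weight tallies performed directly in the spatial
    frequency domain (SFD). Detected packets are binned by the maximum depth
    their trajectory visited, yielding depth-dependent probability
    distributions of photon visitation-and-detection per spatial frequency,
    percentile optical sampling depths (d10..d90), a two-layer phantom
    simulation mode, and a dimensionless lookup table that returns sampling
    depths for arbitrary tissue absorption and reduced scattering properties.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    graphics,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
NeedsCompilation: yes
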