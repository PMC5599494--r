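Package: dtvesicle
Title: Dynamically Triangulated Vesicle Membranes with Molecular Turnover
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Coarse-grained simulation of closed cellular membranes as
    dynamically triangulated surfaces. Vertex positions follow overdamped
    Langevin dynamics under volume, surface and discrete bending elasticity
    with short-range vertex repulsion and an optional polarized active
    surface tension. Membrane fluidity is modelled by Monte Carlo edge flips;
    molecular turnover by stress-dependent splitting and merging of triangle
    pairs coupled to an implicit molecule reservoir through a grand-canonical
    chemical potential. Includes an exact-face-count vesicle generator,
    OFF/PLY mesh I/O, observable and event logging, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
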