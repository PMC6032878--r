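Package: agrosim
Title: Desk-Scale Global Land-Use and Food-System Simulator
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A miniature, fully testable simulator of the coupled global
    land-use and food system. Continuous crop yield-response surfaces are
    fitted to factorial yield potentials (three fertiliser rates crossed with
    rain-fed and irrigated conditions), food demand is projected from income
    with country offsets and optional dietary convergence, land use is chosen
    by per-country least-cost optimisation on k-means clustered grid cells
    under water, protected-area and deforestation constraints, and a
    non-equilibrium world market adjusts commodity prices exponentially
    against stock-buffered over- and undersupply. A synthetic-world generator
    emulates the statistical structure of gridded vegetation-model yield
    output and national socio-economic tables so that every stage runs
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
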