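Package: nanomem
Title: Coarse-Grained Nanoparticle-Membrane Construction and Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds coarse-grained (Martini-style) topologies of
    peptide-coated and citrate-capped metal nanoparticles, generates
    synthetic bilayer and umbrella-sampling fixtures with known ground
    truth, computes membrane trajectory metrics (radial distribution
    functions, lipid order parameters, gridded thickness maps, Voronoi
    area per lipid, transversal density, centre-of-mass separation),
    measures helical peptide orientation angles on bilayers, and
    reconstructs one-dimensional free-energy profiles from biased
    umbrella-window samples with the weighted histogram analysis method.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    deldir,
    graphics,
    stats
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
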