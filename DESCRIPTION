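Package: odnaevo
Title: Stochastic Simulation of Organelle-DNA Heteroplasmy, Bottlenecks
    and Evolvability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A two-scale stochastic simulator of organelle-DNA (mtDNA and
    ptDNA) heteroplasmy evolution. Between generations, each cell's mutant
    fraction h is transformed by a normal mutation kernel and a Wright-style
    segregation ("bottleneck") kernel; at the population level, cells are
    assigned an environment-dependent sigmoidal fitness with an admixture
    (heteroplasmy) penalty and the next generation is drawn by roulette-wheel
    selection. The package includes an evolvable layer in which per-cell
    mutation rate and segregation strength are themselves heritable and
    mutable, a three-type extension tracking dysfunctional oDNA, and an
    experiment harness for adaptation-time parameter sweeps, heteroplasmy
    distribution time series and evolved-parameter surfaces. Results are
    returned as tibbles with tidy() / glance() / autoplot() methods, and a
    small command-line interface drives reproducible simulation runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
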