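Package: coimeio
Title: Crossover Interference and Meiotic Recombination Cytology
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of cytological meiotic-recombination data scored on
    synaptonemal complexes (SCs): crossover (CO) frequencies from MLH1
    foci, axis morphometry and centromere-referenced CO positions,
    crossover interference via maximum-likelihood gamma fits to
    inter-focus distances and coefficient-of-coincidence (CoC) curves,
    and prophase-I double-strand-break dynamics from RPA focus counts.
    Includes a stationary gamma-renewal simulator with obligate-CO
    conditioning and centromere suppression so that every analysis stage
    can be exercised on synthetic data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: stats, utils, tools, grDevices, graphics, yaml
Suggests: testthat (>= 3.0.0), MASS, readxl, jsonlite, withr
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Config/testthat/edition: 3
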