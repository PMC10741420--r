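Package: hopfionDNA
Title: Landau-Hopfion Free-Energy Model of Nucleosomal DNA
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Topology and elastic free energy of closed circular
    (nucleosomal) DNA. Computes linking number, writhe and twist under
    White's formula, converts persistence lengths to bending and torsional
    rigidities, evaluates the Euler-angle Landau free-energy density of a
    two-component order parameter, and reduces it on torus-knot (Hopfion)
    configurations to a closed-form energy minimised over the toroidal
    winding number. Includes the chiral-gauge effective potential for the
    torque-driven B-Z transition, preset nucleosome scenarios, tidy
    tabular outputs, ggplot2 autoplot methods and a command-line front
    end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    ggplot2,
    jsonlite,
    generics,
    rlang,
    stats
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
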