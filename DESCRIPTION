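Package: flavoet
Title: Photoinduced Electron-Transfer Rate Analysis in Flavoproteins
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing ultrafast photoinduced electron transfer from
    aromatic amino-acid donors to the excited isoalloxazine ring of flavin
    cofactors. Implements the Marcus-Kakitani-Mataga rate expression (a
    sigmoidal adiabatic/nonadiabatic distance gate times a classical Marcus
    Franck-Condon factor), the dielectric-continuum solvent reorganization
    energy, and the free-energy gap decomposition with donor-acceptor and
    protein point-charge electrostatics. Provides least-squares fitting of the
    three empirical laws relating logarithmic rate, driving force and
    donor-acceptor distance (the energy gap law, the extended Dutton law and
    the linear distance-energy relation), peak extraction and inverted/normal
    region partitioning, a seeded synthetic-trajectory generator emulating
    molecular-dynamics snapshot series, per-donor peak-equivalence reports,
    and machine-readable fixtures of published fit coefficients for four
    flavoproteins with arithmetic-consistency checking.
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
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
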