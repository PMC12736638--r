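Package: diffmwi
Title: Differential Microwave Imaging of Weak Dielectric Contrasts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Tools for studying the feasibility of differential microwave
    imaging of weak, temperature-induced dielectric contrasts in water
    phantoms. Implements a single-Debye model of the complex permittivity of
    water with temperature-sensitivity statistics, a four-antenna circular
    array geometry with an imaging grid, a first-order Born simulator of
    multi-port scattering parameters (with Touchstone import/export), a
    multi-frequency bi-focusing (MFBF) differential image reconstruction, and
    detection metrics (localization error, peak-versus-contrast regression,
    detection threshold, thermal budget) for sensitivity analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
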