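Package: libsquant
Title: Quantification of Honey Adulteration from LIBS Spectra with PLSR and
    Feature Selection
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Chemometric pipeline for quantifying adulterant content in honey
    from laser-induced breakdown spectroscopy (LIBS) emission spectra. Provides
    a synthetic-spectrum generator for binary honey/adulterant mixtures, peak
    intensity extraction over a 43-line emission library, autoscaled SIMPLS
    partial least squares regression with 10-fold cross-validation, univariate
    screening, and three feature-selection schemes (genetic algorithm,
    variable importance in projection, selectivity ratio), together with
    CSV/JSON readers and writers for every on-disk artifact.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
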