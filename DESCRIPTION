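Package: phosphoshift
Title: Quantifying Sugar Phosphate Hydrolysis from Nucleoside
    Phosphorolysis Equilibrium Shifts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying the hydrolytic decay of
    pentose-1-phosphates from apparent equilibrium shifts of a nucleoside
    phosphorolysis reaction. Provides closed-form mass-action algebra for
    the pre- and post-hydrolysis equilibria (equilibrium conversion,
    hydrolyzed-amount inference, maximum attainable shift), estimation of
    the degree of conversion from UV absorption spectra by non-negative
    spectral unmixing against reference spectra, first-order decay fitting
    with bootstrap uncertainties and pH-rate profiling, a scan of the
    experimental working window over equilibrium constant and phosphate
    excess, and seeded synthetic-data generators so the whole pipeline is
    testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    pracma,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
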