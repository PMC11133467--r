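Package: ferroflex
Title: Fe-Site Flexibility from Nuclear Resonance Spectroscopies
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates and processes the three nuclear-resonance observables
    for 57Fe-labelled metalloproteins such as rubredoxin: energy-domain
    nuclear resonance vibrational spectroscopy (NRVS), velocity-domain
    conventional Moessbauer spectra, and time-domain nuclear forward
    scattering (NFS). Extracts Lamb-Moessbauer factors and mean-square
    displacements of the Fe site as a function of temperature, deconvolves
    the one-phonon partial vibrational density of states by the Fourier-log
    method, fits Debye temperatures, and compares the Fe-site flexibility of
    two proteins (a "corresponding states" test) with a z-score report.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
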