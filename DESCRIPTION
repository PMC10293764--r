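Package: fragnets
Title: Fragments Networks for De Novo Annotation of Orbitrap MS2 Spectra
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: De novo annotation of data-dependent (DDA) Orbitrap MS2 spectra
    by chemical consistency. Profile-mode signal points are clustered into
    peaks, each peak receives its own confidence interval from the observed
    m/z distribution, candidate molecular formulas are enumerated within each
    peak's tolerance, and the set of per-peak annotations maximizing the
    number of chemically consistent (neutral-loss) relations -- the fragments
    network of highest grade -- is selected as the spectrum annotation.
    Includes a synthetic profile-spectrum generator with ground truth, mzML
    and peak-list readers, and a results-table writer.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    mzR,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    optparse,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
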