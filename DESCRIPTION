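Package: ephquant
Title: Quantitative Analyses of Receptor Oligomerization, Conformation, and
    Linker Phosphorylation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tidy analysis pipelines for the biophysical characterization of a
    receptor tyrosine kinase intracellular region and its plasma-membrane
    oligomerization: monomer-dimer FRET equilibrium fitting (two-dimensional
    dissociation constant and intrinsic FRET), fluorescence intensity
    fluctuation (FIF) molecular-brightness analysis of photon-counting
    membrane images, primary SEC-SAXS analysis (Guinier fitting, Debye
    scattering from coordinates, pair-distance distributions and regularized
    indirect Fourier transform), centroid-based hydrogen-deuterium exchange
    uptake arithmetic with back-exchange correction and difference profiles,
    and kinase-screen / phosphosite-cluster statistics. A synthetic-data
    module generates inputs with known ground truth for every pipeline stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    pracma,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0),
    tiff,
    withr
Config/testthat/edition: 3
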