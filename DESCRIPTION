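Package: grmdpheno
Title: Multi-Parametric Phenotyping of Dystrophin-Deficient (GRMD) Dogs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative phenotyping toolkit for preclinical studies in the
    GRMD (golden retriever muscular dystrophy) dog model of Duchenne muscular
    dystrophy. Implements point-count stereology and lesion quantification on
    stained muscle sections (pathological index, picrosirius fibrosis
    fraction, alizarin red calcified-fiber counts, ATPase fiber morphometry,
    slow-myosin fiber fractions, immune-cell densities), isometric force-trace
    indices (tetanic force, relative force, 40-tetanus fatigue index,
    post-tetanic relaxation metrics), an accelerometric gait-quality index
    (GQI) built on a 7-variable reference principal-component plane with
    supplementary projection, an 11-item clinical motor score, longitudinal
    serum creatine-kinase summaries, and the group-comparison statistics used
    for treated-versus-control cohorts. A synthetic-data module generates
    stained sections, force traces and longitudinal cohorts with known ground
    truth so that every stage of the pipeline can be validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    rlang,
    jsonlite,
    EBImage,
    png,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
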