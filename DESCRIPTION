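Package: belemsize
Title: Body-Size Dynamics of Belemnite Assemblages Across Stratigraphic Sections
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analyses body-size dynamics of fossil cephalopod (belemnite)
    assemblages through a stratigraphic section. Computes geometric-mean
    size proxies from rostrum measurements, per-bed summaries and
    log-ratio proportional changes with exact and asymptotic two-sample
    tests, a decomposition of assemblage median shifts into appearance,
    disappearance and within-lineage components, ontogenetic stage
    structure with Wilson intervals and a hierarchical hypothesis
    battery, variation partitioning of size across taxonomy, ontogeny
    and bed separation with permutation tests, and selection among
    generalized least squares models with AR(1) errors relating size to
    per-bed environmental proxies. A synthetic stratigraphic-section
    generator with closed-form ground truth supports end-to-end
    validation of the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    nlme,
    vegan,
    withr,
    yaml,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
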