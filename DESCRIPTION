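Package: bilescreen
Title: In Vitro Screening Pipeline for Microbial Bile Acid Transformation and
    Conjugation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computational pipeline for in vitro screens of gut-bacterial bile
    acid metabolism. Builds an exact-mass library of bile acid steroid cores and
    their amino-acid amide conjugates, matches LC-MS/MS feature tables against
    it at ppm tolerance with MS/MS fragment-triad confirmation and enantiomer
    double-peak detection, quantifies steroid-core transformations from
    five-point standard curves with detection-limit and reporting thresholds,
    predicts hydroxysteroid-dehydrogenase (HSD) and bai-operon genotypes from
    homology hit tables via F-measure-optimal bit-score cutoffs and operon
    co-localization, and summarises genotype-phenotype concordance. Includes a
    seeded synthetic-study generator with a truth ledger for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    withr,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
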