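Package: abploidy
Title: Allele-Balance Copy Number Inference and Mixed-Ploidy
    Differentiation from VCF Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Infers genomic and sub-genomic copy number from the allele
    balance of heterozygous genotypes in VCF data: per-sample allele-depth
    extraction, depth-quantile censoring, fixed-window histogram peak
    calling, and assignment of window peaks to expected dosage ratios
    (1/2, 2/3, 3/4, 4/5 and their mirrors) with a distance-from-expectation
    confidence score. Also computes allele-count-weighted genetic
    differentiation (Nei's Gst and Hedrick's G'st) for populations that
    mix copy numbers, and ships a synthetic VCF simulator with known
    ploidy tracks so every stage can be validated without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    vcfR,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
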