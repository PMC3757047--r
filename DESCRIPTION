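Package: tymap
Title: Mapping Ty Retrotransposons and Their Meiotic DSB Landscape in Yeast
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for compiling a high-resolution catalog of Ty
    LTR-retrotransposon insertions in Saccharomyces cerevisiae from
    paired-end sequencing data, and for quantifying meiotic double-strand
    break (DSB) potential in and around those insertions. Includes
    Ty-matching read classification with unique mate anchoring and
    bidirectional cluster calling of insertion sites, target-site-duplication
    (TSD) and orientation resolution at element-genome junctions, a Poisson
    model of per-site supporting-read counts to estimate catalog
    completeness, Spo11-oligo track normalization (hits per million mapped
    reads) with flanking-window density analysis against control sites,
    intergenic-context classification, burden arithmetic converting oligo
    fractions to per-cell DSB estimates, and a seeded simulator that emits
    reference/sample genome pairs with planted elements, mate-pair
    libraries, annotations, and oligo tracks with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    graphics,
    utils,
    withr,
    jsonlite,
    S4Vectors,
    IRanges,
    GenomicRanges,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
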