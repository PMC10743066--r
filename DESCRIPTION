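Package: soyOrigin
Title: Gene-Based Soybean Origin Discrimination with Allele-Specific InDel Markers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discriminating the geographic origin of soybean grains
    from allele-specific PCR amplification profiles of an eleven-marker InDel
    panel. Amplification profiles are encoded as integer judgment values
    (binary fingerprints), origin discrimination tables are built from labeled
    reference collections, and new samples or 24-grain lots are classified by
    table lookup with explicit handling of judgment values shared between
    origins. Includes qualitative classifier metrics (sensitivity,
    selectivity, efficiency, predictive rates), grain-lot sampling statistics
    (detection power and minimum grain counts for mixed lots), a marker
    discovery stage that segments chromosomes into dense and sparse variation
    blocks by windowed SNP density and extracts InDel candidates from dense
    blocks, and a synthetic data generator (variety fingerprints, noisy grain
    populations, mixed lots, and block-structured VCFs with recorded ground
    truth) for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    IRanges,
    GenomeInfoDb,
    GenomicRanges,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
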