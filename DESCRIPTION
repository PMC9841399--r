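Package: varchive
Title: Compressed Variant Annotation Archives for Rapid VCF Annotation and Filtering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Builds compressed archives of population-scale SNP and indel
    annotations and uses them to rapidly annotate and filter query VCF files.
    Small variants are packed into 32-bit integer codes within 2^20-base
    genome bins; sorted codes are delta-encoded and compressed with Stream
    VByte, annotation columns are zigzag/Stream-VByte encoded, string fields
    are dictionary-coded, and everything is stored in a standard ZIP archive
    for random access. Annotation performs cached per-bin binary search and
    supports expression-based include filters over the annotated values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
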