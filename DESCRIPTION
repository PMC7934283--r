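Package: icbpscan
Title: Internal Complementary Base-Pairing Sequences in Circular RNAs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Detects internal complementary base-pairing sequences (ICBPS),
    pairs of disjoint segments within one circular RNA that are exact
    reverse complements of each other, using a seed-and-extend pointer scan
    with an independent brute-force oracle. Summarises each circRNA by pair
    count, maximum and median arm length, complementary ratio and pairing
    pattern; intersects detected arms with miRNA-recognition-element and
    open-reading-frame annotations on circular coordinates; aggregates
    cohort-level distributions and length correlations; and simulates
    circRNA cohorts with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Biostrings,
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
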