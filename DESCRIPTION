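Package: wobbleA34
Title: Wobble Decoding and Inosine Editing Analysis for A34-Anticodon tRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of sense codon reassignment by orthogonal
    tRNAs carrying adenosine at anticodon position 34 (the wobble position) in
    E. coli. Converts replicate fluorescence measurements bracketed by 0% and
    100% reference constructs into reassignment efficiencies with
    limit-of-detection censoring, computes U3:C3 discrimination ratios with a
    censored floor variant, models the minimum inosine-modified fraction
    detectable as anomalous C-ending decoding, quantifies A-to-I editing at
    position 34 from Sanger chromatogram peak areas (ABIF, XML, and CSV trace
    readers), scores observed decoding against classical and expanded wobble
    rule sets, and generates synthetic chromatograms and screen replicates so
    the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
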