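Package: braintiers
Title: Qualitative Tier-Based Expression Profiling of Disease Gene Sets in the Developing Brain
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Housekeeping-calibrated tier stratification of RPKM expression
    matrices over brain regions and developmental ages, selection of highly
    expressed genes, set algebra over disease gene lists (Venn counts,
    pan-region and region-unique highly expressed genes, overlap fractions),
    Fisher exact term enrichment with Benjamini-Hochberg correction,
    focus-gene interactome module construction with meta-graph overlay and
    hub ranking, ordinal immunohistochemistry cell-type specificity calls,
    and a synthetic-data generator with planted ground truth so every stage
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    igraph
Config/testthat/edition: 3
RoxygenNote: 7.3.3
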