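Package: barcycle
Title: Cell Barcode Identification by Circularized de Bruijn Graph Cycle Search
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies and error-corrects single-cell barcodes from Drop-seq
    style sequencing reads without a whitelist or a prior cell count. Barcode
    windows are circularized (with one-base truncated and extended variants) so
    that reads carrying a mismatch, insertion or deletion still contribute
    error-free k-mers; a weighted de Bruijn graph over (k-1)-mers is searched
    for fixed-length cycles by a greedy capacity-decrementing depth-first
    search; true barcodes are separated from spurious cycles at the knee of
    the cumulative path-capacity curve; and every read is assigned to a
    consensus barcode by k-mer compatibility or Levenshtein distance. Includes
    a read-error simulator and scoring harness for benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    data.table,
    signal,
    Biostrings,
    stats,
    utils
Suggests:
    withr,
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
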