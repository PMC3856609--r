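Package: mifdr
Title: Minimized False Discovery Rate Calling for Two-Group Omics Screens
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Permutation-based false discovery rate (FDR) control for
    two-group feature screens (e.g. microarray or RNA-seq differential
    expression). Implements the miFDR strategy: for a fixed number N of
    called features, search all asymmetric splits of the rejection region
    into N+ positive and N- negative calls and keep the split with the
    lowest permutation-estimated FDR; conversely, find the largest N whose
    minimized FDR stays below a target cut-off. Includes the SAM-style
    moderated d-statistic with fudge factor s0, permutation null
    generation, Storey-type null-proportion estimation, the SAM
    delta-threshold selector and Benjamini-Hochberg / Storey q-value
    baselines, plus a synthetic-data simulation study for method
    comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    generics,
    ggplot2,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
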