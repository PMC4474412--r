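Package: motifshape
Title: De Novo DNA Motif Discovery Guided by Epigenomic Signal Shape
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Word-count based de novo motif discovery for ChIP-seq peak
    regions that augments k-mer over-representation statistics with shape
    features (intensity, kurtosis, asymmetry) of genome-wide signal tracks
    such as DNase I hypersensitivity and histone modification marks
    aggregated around k-mer occurrences.  Over-represented seeds are
    generalized by single-base substitution into position frequency
    matrices, clustered by best-alignment Pearson correlation with the
    cluster number chosen by the gap statistic, trimmed, and exported in
    MEME minimal format.  Includes a log-odds site scanner, a site-level
    AUROC evaluation harness against ChIP-seq summits with cross-validation
    and weight grid search, and a fully synthetic fixture generator for
    planted-motif benchmarks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    Rcpp,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
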