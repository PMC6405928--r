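Package: premirscan
Title: Species-Specific Pre-miRNA Discovery by Homology Scanning,
    Hairpin Filtering and Kernel SVM Classification
Version: 0.1.0
Authors@R:
    person("premirscan", "developers", email = "premirscan@example.org",
           role = c("aut", "cre"))
Description: A toolkit for species-specific plant pre-miRNA discovery from
    genomic sequence. Known mature miRNAs seed a sensitive word-index
    homology scan of the genome; hit loci are flanked and fragmented into
    precursor-scale sliding windows; windows are folded and screened with
    stem-length, GC-content and minimum-free-energy hairpin filters;
    surviving candidates are described by a catalog of compositional,
    triplet-element, thermodynamic and topological features and scored by a
    class-weighted kernel support vector machine. Includes five-fold
    cross-validated evaluation (twelve confusion-matrix metrics, trapezoidal
    ROC/AUC), computational validation operators (miRNA* star-sequence
    detection, exact small-RNA-library matching, homology lookup), and a
    synthetic-genome generator with planted ground truth so the whole
    pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    quadprog,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
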