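Package: kmersketch
Title: HyperLogLog k-mer Sketching for Fast Genomic Distance Estimation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates similarities between genomes or sequencing datasets by
    sketching their k-mer content with HyperLogLog registers. Cardinalities of
    sets, unions and intersections are recovered with three estimators (the
    corrected harmonic mean, a maximum-likelihood estimator solved by the
    secant method, and a joint maximum-likelihood estimator over a
    three-component Poisson mixture that estimates intersection cardinality
    directly), from which Jaccard, containment and overlap coefficients and
    the Mash distance are derived. Includes bottom-k MinHash and Bloom-filter
    baselines, a count-min-sketch abundance pre-filter for sequencing reads,
    an exact hash-set mode, a two-command sketch/dist interface, and a
    synthetic-set benchmark harness for accuracy studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    tibble,
    optparse,
    parallel,
    stats,
    utils
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
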