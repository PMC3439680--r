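Package: kernrank
Title: Kernelized Score Functions for Gene Ranking on Functional Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-supervised ranking of genes with respect to gene modules on
    weighted functional interaction networks. Implements kernelized score
    functions (average, nearest-neighbour and k-nearest-neighbour scores)
    built on q-step random walk kernels, together with Gaussian random field
    propagation, its cost-sensitive GeneMANIA variant, harmonic label
    propagation with clamped labels, Laplacian normalization and network
    integration (unweighted sum and ridge-regression weighted sum), and a
    repeated stratified cross-validation protocol with precision-at-recall
    and AUC metrics. A seeded generator of planted-partition networks with
    known modules supports end-to-end benchmarking without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils
Suggests: testthat (>= 3.0.0), withr, jsonlite, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
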