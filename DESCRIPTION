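Package: kcsf
Title: Compressed Static Function Representations of k-mer Count Tables
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Space-efficient, randomly accessible representations of
    genomic k-mer count tables. Implements a chunked compressed static
    function (CSF) built by GF(2) hypergraph peeling over canonical
    length-limited prefix codes, its Bloom-enhanced variant (BCSF) with
    analytic Bloom filter dimensioning for low-entropy count spectra, and
    two minimizer-bucketed cascading schemes: AMB (exact or
    delta-approximate, ambiguity-marked buckets) and FIL (majority
    representatives plus per-k-mer corrections). Includes k-mer and
    document-frequency counting from FASTA/FASTQ, seeded synthetic data
    generators, entropy and size accounting, and a checksummed container
    format for all structures.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
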