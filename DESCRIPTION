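Package: sibril
Title: Exact Multilocus Genotype and IBD Probabilities in Sibling-Mated
    Recombinant Inbred Lines
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes exact probabilities of all multilocus identity-by-descent
    (IBD) inheritances and genotypes in 2-way recombinant inbred lines produced
    by sibling mating (SIB RILs), for an arbitrary number of linked loci and
    optionally sex-dependent recombination rates. The formally infinite
    inbreeding process is closed into a finite linear system by
    self-consistency over the non-equivalent IBD probabilities; solutions are
    exact rationals for small systems and sparse numeric solves otherwise.
    Includes a forward sibling-pedigree simulator under the Haldane
    (no-interference) model, used as a Monte Carlo cross-check and as a
    synthetic-data generator, and a maximum-probability imputation procedure
    for missing genotype calls that exploits the exact multilocus genotype
    probabilities.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
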