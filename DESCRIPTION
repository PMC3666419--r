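Package: snvexpect
Title: Expected Candidate SNV Counts in Exome Sequencing for Mendelian Disease
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Closed-form calculator for the expected number of candidate
    single-nucleotide variants (SNVs) that survive genotype-based filtering
    in exome sequencing studies of Mendelian disease under the assumption of
    no genetic heterogeneity. Sample allele frequencies follow the neutral
    Wright-Fisher infinite-sites site frequency spectrum E[M_i] = theta/i,
    recast in reference/alternative coordinates. Supports autosomal dominant
    and recessive filters, cohorts of unrelated individuals or full-sibs in
    a nuclear family, optional control samples, and penetrance- and
    phenocopy-tolerant thresholds (at least X affected carriers, at most Y
    control carriers). Includes a Monte-Carlo simulator that provides an
    independent stochastic check of every analytic expectation, a
    reproduction harness for published reference grids, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    optparse,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
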