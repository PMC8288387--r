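Package: mosaicHE
Title: Homoeologous-Exchange Mosaicism in Nascent Allotetraploids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for homoeologous-exchange (HE) generated
    genomic mosaicism in segmental allotetraploid selfing populations.
    Infers per-bin homoeolog dosage (five states, 4:0 through 0:4) from
    parental-diagnostic allele depths via pooled-binomial likelihoods and
    five-state Viterbi smoothing, calls HE breakpoints and per-meiosis
    exchange rates, summarises the genome-wide dosage landscape with
    permutation and exact binomial tests, scans reciprocal crosses for
    cytonuclear biased-retention segments, tests homoeolog expression for
    copy-number dependence, runs homoeolog-dosage GWAS with additive and
    dominance encodings and FarmCPU-style pseudo-QTN iteration, and
    decomposes two-locus epistasis under the F-infinity model.  Includes a
    forward simulator of tetraploid selfing pedigrees with homoeologous
    exchange, viability selection and sequencing-depth sampling.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
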