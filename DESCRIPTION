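Package: protopep
Title: Combinatorial Protocode Peptide Libraries and RNA-Peptide Array
    Screening Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying primordial RNA-peptide interactions with
    fully combinatorial high-density peptide arrays. Encodes the partition
    of the standard genetic code into dominant and recessive AU- and
    GC-protocodes and the combinatorial fusion (Watson-Crick transition)
    rules that map protocode codon assignments onto the standard code;
    enumerates fully combinatorial peptide libraries and randomized,
    replicated array layouts; reads photometric intensity tables and joins
    them with array manifests; computes per-peptide sum properties (charge,
    molecular weight, hydrophobicity, helix propensity); ranks contiguous
    peptide fragments by the interaction score R = mean/sd of their
    fluorescence signal sets, with signature columns, displacement and
    composition analyses; analyzes single-position substitution scans; and
    simulates synthetic screens with planted motif effects and lognormal
    spot noise so the whole pipeline is testable without array data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    data.table,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
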