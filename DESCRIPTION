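Package: psiedit
Title: Specificity and Safety Analyses for Pseudouridine-Directed RNA Editing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for evaluating the specificity and molecular
    safety of guide-snoRNA pseudouridine (Psi) RNA editors that suppress
    premature termination codons. Quantifies site-level Psi stoichiometry as
    deletion rates from deletion-signature sequencing counts, calls off-target
    and endogenous Psi sites with a four-criterion filter, scans the
    transcriptome for guide-complementary off-target candidates, quantifies
    target editing from UMI-consensus amplicon reads, computes
    ribosome-profiling readthrough metrics (RRTS, stop-codon metagene,
    translation efficiency), performs RNA-seq and tRNA-seq abundance-stability
    analyses (RPKM/CPM/RPM, replicate-reproducibility filtering, anticodon and
    isodecoder fold changes), and estimates amino-acid incorporation at the
    premature stop from peptide mass-spectrometry abundance tables. Includes
    synthetic-data generators with planted ground truth so every stage is
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    S4Vectors,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
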