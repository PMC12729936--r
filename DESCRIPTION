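Package: hdpminer
Title: Mining Host-Defense Peptide Candidates from Venom-Gland Secretomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An in-silico discovery pipeline for host-defense peptide (HDP)
    candidates in venom-gland transcriptomes. Implements the secretome filter
    cascade (toxin homology, signal-peptide evidence, expression threshold),
    Chou-Fasman helix annotation with sliding 18-mer window design,
    sequence-derived physicochemistry (average molecular weight,
    Henderson-Hasselbalch net charge and isoelectric point, Eisenberg
    hydrophobic moment), antioxidative residue-composition profiling, and
    composite ranking of external anti-inflammatory/antioxidant/hemolysis
    predictor scores. Ships a seeded synthetic secretome generator with
    planted ground truth so the full pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Imports:
    Biostrings,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
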