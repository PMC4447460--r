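Package: venomtk
Title: Curation of Venom-Gland Transcriptome Peptide Precursors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for curating venom-gland transcriptome assemblies into
    annotated toxin and antimicrobial-peptide precursors: six-frame
    translation and open-reading-frame selection, heuristic signal-peptide
    and propeptide segmentation with C-terminal amidation inference from
    glycine processing motifs (GKR/GRR), rule-based cysteine-framework
    family classification (alpha-KTx, beta-KTx/scorpine-like, calcins,
    defensins, La1-like, Ascaris-type inhibitors, NDBP antimicrobials),
    theoretical monoisotopic and average peptide masses with amidation and
    disulfide mass deltas, matching of theoretical masses against an
    experimental proteome mass list, global pairwise alignment percent
    identity, assembly statistics (N50, FPKM), and a seeded synthetic-data
    generator with ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
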