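# Rule-based venom-family classification of mature peptides.
# Rules are evaluated top to bottom; the first match wins. Each rule may
# constrain the cysteine count (`cys`, a set of admissible counts), the
# mature-peptide length in residues (`len`, inclusive bounds) and require a
# regular-expression `motif`. Length windows follow the canonical family
# descriptions (alpha-KTx 23-42 aa; beta-KTx > 50 aa; calcin 33 aa / 6 Cys;
# DDH calcin 36 aa / 4 Cys; agatoxin-like calcin 42-47 aa / 8 Cys with a CC
# doublet; La1 73 aa / 8 Cys; Ascaris-type inhibitor 10 Cys; NaTx usually
# 58-76 aa; NDBP antimicrobials cysteine-free, classed by length), widened
# around the single-exemplar figures so that curated family members stay
# inside without overlap. Discriminating motifs (defensin GFGCP, calcin CC)
# are checked before the broad alpha-KTx window.
rules:
  - id: ascaris
    family: ascaris-type-inhibitor
    cys: [10]
    len: [50, 95]
  - id: agatoxin
    family: agatoxin-like-calcin
    cys: [8]
    len: [38, 55]
    motif: "CC"
  - id: la1
    family: La1-like
    cys: [8]
    len: [65, 85]
  - id: defensin
    family: defensin
    cys: [6]
    len: [36, 40]
    motif: "^GFGCP"
  - id: calcin
    family: calcin
    cys: [6]
    len: [30, 36]
    motif: "CC"
  - id: ddh
    family: DDH-calcin
    cys: [4]
    len: [33, 40]
  - id: alpha_ktx
    family: alpha-KTx
    cys: [6, 8]
    len: [23, 42]
  - id: natx
    family: NaTx-like
    cys: [7, 8]
    len: [55, 85]
  - id: beta_ktx
    family: scorpine-like/beta-KTx
    cys: [6]
    len: [50, 120]
  - id: allergen
    family: allergen-like
    len: [180, 100000]
  - id: ndbp_short
    family: NDBP-short
    cys: [0]
    len: [1, 19]
  - id: ndbp_medium
    family: NDBP-medium
    cys: [0]
    len: [20, 35]
  - id: ndbp_long
    family: NDBP-long
    cys: [0]
    len: [36, 179]
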