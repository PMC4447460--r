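# Independent oracles and small utilities shared across the suite.

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

rand_peptide <- function(len, pool = AA20) {
  paste(sample(pool, len, replace = TRUE), collapse = "")
}

rand_dna <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# Exhaustive N50: scan every candidate length L and apply the definition
# directly (largest L with sum(lengths >= L) >= total/2).
brute_n50 <- function(lens) {
  if (length(lens) == 0) return(0)
  total <- sum(lens)
  cand <- sort(unique(lens), decreasing = TRUE)
  for (L in cand) {
    if (sum(lens[lens >= L]) >= total / 2) return(L)
  }
  min(lens)
}

# Independently tabulated standard genetic code (codon -> amino acid).
ORACLE_CODONS <- local({
  txt <- "
  TTT F  TTC F  TTA L  TTG L  CTT L  CTC L  CTA L  CTG L
  ATT I  ATC I  ATA I  ATG M  GTT V  GTC V  GTA V  GTG V
  TCT S  TCC S  TCA S  TCG S  CCT P  CCC P  CCA P  CCG P
  ACT T  ACC T  ACA T  ACG T  GCT A  GCC A  GCA A  GCG A
  TAT Y  TAC Y  TAA *  TAG *  CAT H  CAC H  CAA Q  CAG Q
  AAT N  AAC N  AAA K  AAG K  GAT D  GAC D  GAA E  GAG E
  TGT C  TGC C  TGA *  TGG W  CGT R  CGC R  CGA R  CGG R
  AGT S  AGC S  AGA R  AGG R  GGT G  GGC G  GGA G  GGG G"
  toks <- strsplit(trimws(gsub("\\s+", " ", txt)), " ")[[1]]
  stats::setNames(toks[seq(2, length(toks), 2)], toks[seq(1, length(toks), 2)])
})

# Affine-gap global alignment oracles. A gap of length k costs
# open + extend * k (charged extend per gap character, open once at the
# start of each gap run), end gaps included -- the same convention as the
# implementation under test, recomputed by entirely separate code.
blosum62 <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# Plain recursion over all alignment paths (no memoisation): literally
# enumerates every global alignment. Only feasible for very short pairs.
enum_align_score <- function(a, b, open = 10, extend = 0.5, mat = blosum62) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  rec <- function(i, j, last) {
    if (i > n && j > m) return(0)
    best <- -Inf
    if (i <= n && j <= m) {
      best <- max(best, mat[ca[i], cb[j]] + rec(i + 1, j + 1, "M"))
    }
    if (i <= n) {
      cost <- extend + if (last != "A") open else 0
      best <- max(best, -cost + rec(i + 1, j, "A"))
    }
    if (j <= m) {
      cost <- extend + if (last != "B") open else 0
      best <- max(best, -cost + rec(i, j + 1, "B"))
    }
    best
  }
  rec(1, 1, "M")
}

# Memoised variant of the same recursion, for pairs up to length ~8.
memo_align_score <- function(a, b, open = 10, extend = 0.5, mat = blosum62) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  states <- c(M = 1L, A = 2L, B = 3L)
  memo <- array(NA_real_, dim = c(n + 1, m + 1, 3))
  rec <- function(i, j, last) {
    if (i > n && j > m) return(0)
    got <- memo[i, j, states[last]]
    if (!is.na(got)) return(got)
    best <- -Inf
    if (i <= n && j <= m) {
      best <- max(best, mat[ca[i], cb[j]] + rec(i + 1, j + 1, "M"))
    }
    if (i <= n) {
      best <- max(best, -(extend + if (last != "A") open else 0) +
                    rec(i + 1, j, "A"))
    }
    if (j <= m) {
      best <- max(best, -(extend + if (last != "B") open else 0) +
                    rec(i, j + 1, "B"))
    }
    memo[i, j, states[last]] <<- best
    best
  }
  rec(1, 1, "M")
}

# Brute-force longest ORF over six frames: scan every ATG on each strand and
# extend codon-by-codon to the first stop (or sequence end).
brute_longest_orf <- function(nt) {
  revcomp <- function(s) chartr("ACGTN", "TGCAN",
    paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  best <- ""
  for (s in c(nt, revcomp(nt))) {
    L <- nchar(s)
    for (i in seq_len(max(L - 2, 0))) {
      if (substr(s, i, i + 2) != "ATG") next
      prot <- character()
      j <- i
      while (j + 2 <= L) {
        aa <- ORACLE_CODONS[[substr(s, j, j + 2)]]
        if (is.null(aa)) aa <- "X"
        if (aa == "*") break
        prot <- c(prot, aa)
        j <- j + 3
      }
      p <- paste(prot, collapse = "")
      if (nchar(p) > nchar(best)) best <- p
    }
  }
  best
}

# Expected family for a curated fixture row, from its BLAST-style
# description; NA when the description names no modeled family.
expected_family <- function(desc) {
  if (grepl("defensin", desc)) return("defensin")
  if (grepl("opiscorpine", desc)) return("scorpine-like/beta-KTx")
  if (grepl("beta-ktx", desc, ignore.case = TRUE)) return("scorpine-like/beta-KTx")
  if (grepl("[Aa]lpha-KTx", desc)) return("alpha-KTx")
  if (grepl("calcium-channel", desc)) return("calcin|DDH-calcin|agatoxin-like-calcin")
  if (grepl("la1-like", desc)) return("La1-like")
  if (grepl("Ascaris", desc)) return("ascaris-type-inhibitor")
  if (grepl("Sodium-Toxin", desc)) return("NaTx-like")
  if (grepl("venom allergen", desc)) return("allergen-like")
  if (grepl("antimicrobial peptide", desc)) return("NDBP-short|NDBP-medium|NDBP-long")
  NA_character_
}

table3_fixture <- function() {
  utils::read.delim(venomtk_extdata("table3_proteome.tsv"),
                    stringsAsFactors = FALSE)
}
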