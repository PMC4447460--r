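# Seeded generator of venom-gland-like transcript sets with ground truth:
# family-templated precursors, reverse-transcribed transcripts with UTRs and
# decoys, and a noisy proteome mass list.

# Mature-peptide scaffolds taken from curated exemplars; cysteine positions
# are kept (jittered +/-1) and all other residues are resampled.
.SCAFFOLDS <- list(
  "alpha-KTx" = list(mature = "GDIKCSSTKECFRPCEEIGGCSNAKCINGKCRCYGCI",
                     terminal_amide = TRUE),
  "La1-like" = list(
    mature = "FGESCQAGKHIVPVGQQQIDSSTCTLYKCSNYNRKYALETTSCATLKLKSGCRMVPGAATAPFPNCCPMMMCK",
    terminal_amide = TRUE),
  "DDH-calcin" = list(mature = "DLPPSDEYGTCVRPRKCKPHLKCSKAQTCVDPKKGW",
                      terminal_amide = FALSE, n_propeptide = TRUE),
  "ascaris-type-inhibitor" = list(
    mature = "QSGGRGRCRGRGEVFTYCGTGCRLTCQNYRNPPQICTLQCFIGCVCRSGWVRDTRSGRCVRPSQCRR",
    terminal_amide = FALSE))

# Residue pool for random positions: no Cys (scaffolds fix the framework),
# no Gly (so processing-motif glycines occur only where planted) and no
# Asp/Glu (so acidic enrichment occurs only in constructed propeptides).
.POOL <- c("A", "F", "H", "I", "K", "L", "M", "N", "P", "Q", "R", "S", "T",
           "V", "W", "Y")

#' Generator configuration
#'
#' Defaults encode the curated precursor grammar: signal peptides of 23-24
#' residues, NDBP mature peptides shorter than 20 residues ending in a
#' G[KR][KR] motif, acidic propeptides of 31-46 residues, and
#' cysteine-scaffold families templated on curated exemplars.
#'
#' @param n_per_family Named integer vector: precursors per family. Allowed
#'   names: `NDBP-short`, `alpha-KTx`, `La1-like`, `DDH-calcin`,
#'   `ascaris-type-inhibitor`.
#' @param signal_len_range,ndbp_mature_max,pro_len_range Precursor grammar.
#' @param acidic_fraction Target D/E fraction of generated propeptides.
#' @param utr_len_range Nucleotide UTR length range.
#' @param n_decoys Housekeeping-like decoy transcripts (random ORF-free
#'   composition) added by [reverse_transcribe()].
#' @param mass_noise_sd Gaussian noise (Da) on proteome masses.
#' @param dropout Fraction of mature peptides absent from the proteome list.
#' @param seed RNG seed threaded through all generator stages.
#' @return A `generator_config` list.
#' @export
generator_config <- function(n_per_family = c("NDBP-short" = 50,
                                              "alpha-KTx" = 50,
                                              "DDH-calcin" = 30,
                                              "La1-like" = 40,
                                              "ascaris-type-inhibitor" = 30),
                             signal_len_range = c(23L, 24L),
                             ndbp_mature_max = 19L,
                             pro_len_range = c(31L, 46L),
                             acidic_fraction = 0.4,
                             utr_len_range = c(25L, 120L),
                             n_decoys = 20L,
                             mass_noise_sd = 0.5,
                             dropout = 0.2,
                             seed = 1L) {
  known <- c("NDBP-short", names(.SCAFFOLDS))
  bad <- setdiff(names(n_per_family), known)
  if (length(bad)) stop("unknown family label(s): ", paste(bad, collapse = ", "),
                        call. = FALSE)
  stopifnot(all(n_per_family >= 0), dropout >= 0, dropout <= 1,
            acidic_fraction >= 0.25, signal_len_range[1] <= signal_len_range[2],
            pro_len_range[1] <= pro_len_range[2],
            utr_len_range[1] <= utr_len_range[2], mass_noise_sd >= 0)
  out <- list(n_per_family = n_per_family,
              signal_len_range = as.integer(signal_len_range),
              ndbp_mature_max = as.integer(ndbp_mature_max),
              pro_len_range = as.integer(pro_len_range),
              acidic_fraction = acidic_fraction,
              utr_len_range = as.integer(utr_len_range),
              n_decoys = as.integer(n_decoys),
              mass_noise_sd = mass_noise_sd,
              dropout = dropout, seed = as.integer(seed))
  class(out) <- "generator_config"
  out
}

.rand_signal <- function(len) {
  # M-K, hydrophobic core (uniform L so the hydropathy profile peaks at the
  # true cut), then Q-N-S-D-A: small residues at (-3,-1) only at the cut.
  stopifnot(len >= 15)
  c("M", "K", sample(c("L", "I", "F"), 3, replace = TRUE),
    rep("L", len - 10L), "Q", "N", "S", "D", "A")
}

.rand_scaffold <- function(template) {
  aa <- strsplit(template, "")[[1]]
  L <- length(aa)
  cys <- which(aa == "C")
  jit <- cys + sample(c(-1L, 0L, 1L), length(cys), replace = TRUE)
  if (jit[1] < 1 || jit[length(jit)] > L || any(diff(jit) < 1)) jit <- cys
  out <- sample(.POOL, L, replace = TRUE)
  out[jit] <- "C"
  paste(out, collapse = "")
}

.rand_acidic <- function(len, acidic_fraction, terminal = c("none", "ER"),
                         allow_r = TRUE) {
  terminal <- match.arg(terminal)
  pool <- if (allow_r) .POOL else setdiff(.POOL, "R")
  aa <- sample(pool, len, replace = TRUE)
  n_acid <- ceiling(acidic_fraction * len)
  fixed <- integer()
  if (terminal == "ER") {
    aa[len - 1L] <- "E"; aa[len] <- "R"
    fixed <- c(len - 1L, len)
    n_acid <- n_acid - 1L
  }
  free <- setdiff(seq_len(len), fixed)
  pos <- sample(free, min(n_acid, length(free)))
  aa[pos] <- sample(c("D", "E"), length(pos), replace = TRUE)
  paste(aa, collapse = "")
}

#' Generate family-templated precursors with ground truth
#'
#' Each precursor is drawn from its family template: a hydrophobic signal
#' peptide with small residues at the (-3,-1) positions, a mature peptide
#' built on the family's cysteine scaffold (or a cysteine-free NDBP), and,
#' depending on the family, a GKR/GRR-initiated acidic C-terminal
#' propeptide, a terminal amidation glycine, or an acidic N-terminal
#' propeptide. Deterministic given `config$seed`.
#'
#' @param config A [generator_config()].
#' @return List with `records` (data.frame `id`, `desc`, `seq`: precursor
#'   amino-acid sequences) and `truth` (per-record family, segments,
#'   amidation flag, and theoretical mature masses `mature_mono_da` /
#'   `mature_avg_da`, monoisotopic/average with amidation and disulfide
#'   bridges applied).
#' @export
generate_precursors <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(config$seed)
  rows <- list()
  for (fam in names(config$n_per_family)) {
    n <- config$n_per_family[[fam]]
    if (n == 0) next
    for (i in seq_len(n)) {
      sig <- paste(.rand_signal(sample(
        config$signal_len_range[1]:config$signal_len_range[2], 1)),
        collapse = "")
      pro_n <- ""; amid_gly <- ""; basic <- ""; pro_c <- ""; amid <- FALSE
      if (fam == "NDBP-short") {
        mat <- paste(sample(.POOL, sample(10:config$ndbp_mature_max, 1),
                            replace = TRUE), collapse = "")
        motif <- sample(c("GKR", "GRR"), 1)
        amid_gly <- "G"; basic <- substr(motif, 2, 3); amid <- TRUE
        pro_c <- .rand_acidic(sample(config$pro_len_range[1]:
                                       config$pro_len_range[2], 1),
                              config$acidic_fraction)
      } else {
        tpl <- .SCAFFOLDS[[fam]]
        mat <- .rand_scaffold(tpl$mature)
        if (isTRUE(tpl$terminal_amide)) { amid_gly <- "G"; amid <- TRUE }
        if (isTRUE(tpl$n_propeptide)) {
          pro_n <- .rand_acidic(sample(12:25, 1), config$acidic_fraction,
                                terminal = "ER", allow_r = FALSE)
        }
      }
      prec <- paste0(sig, pro_n, mat, amid_gly, basic, pro_c)
      mp <- mass_profile(mat, amidated = amid)
      rows[[length(rows) + 1L]] <- data.frame(
        id = sprintf("synth_%s_%04d", gsub("[^A-Za-z]", "", fam), i),
        family = fam, precursor = prec, signal = sig, pro_n = pro_n,
        mature = mat, amid_gly = amid_gly, basic = basic, pro_c = pro_c,
        amidated = amid,
        mature_mono_da = mp$variants[["mono_with_ss"]],
        mature_avg_da = mp$variants[["avg_with_ss"]],
        stringsAsFactors = FALSE)
    }
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(), family = character(), precursor = character(),
               signal = character(), pro_n = character(), mature = character(),
               amid_gly = character(), basic = character(), pro_c = character(),
               amidated = logical(), mature_mono_da = numeric(),
               mature_avg_da = numeric(), stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  records <- data.frame(id = truth$id, desc = truth$family,
                        seq = truth$precursor, stringsAsFactors = FALSE)
  list(records = records, truth = truth)
}

.syn_codons <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc_tab <- Biostrings::GENETIC_CODE
      cache <<- split(names(gc_tab), unname(gc_tab))
    }
    cache
  }
})

.rand_utr <- function(len, no_c_tail = FALSE) {
  # G-free (no forward ATG), built so that CAT (a reverse-strand ATG) never
  # occurs: after a C-A run the next base cannot be T. When requested the
  # final base is not C, so no CAT forms across the junction with a
  # downstream ATG.
  if (len == 0) return("")
  b <- character(len)
  for (i in seq_len(len)) {
    pool <- c("A", "C", "T")
    if (i >= 3 && b[i - 2] == "C" && b[i - 1] == "A") pool <- c("A", "C")
    if (no_c_tail && i == len) pool <- setdiff(pool, "C")
    b[i] <- pool[sample.int(length(pool), 1)]
  }
  paste(b, collapse = "")
}

#' Reverse-transcribe precursors into transcripts with UTRs
#'
#' Codons are sampled uniformly among synonyms; an in-frame stop codon and
#' random UTRs (alphabet chosen so that no spurious start codon arises on
#' either strand outside the planted CDS) are added, and the transcript is
#' randomly placed on the forward or reverse strand. Each transcript is
#' verified to yield the planted precursor as its top-ranked ORF, so
#' noiseless round-trips through [find_orfs()] recover the ground truth
#' exactly. Decoy transcripts without any long ORF are appended.
#' Deterministic given `config$seed` (offset +1 from the precursor stage).
#'
#' @param truth `truth` data.frame from [generate_precursors()].
#' @param config The same [generator_config()].
#' @return List with `transcripts` (data.frame `id`, `desc`, `seq`;
#'   nucleotide) and `truth` augmented with `strand`, `cds_start`,
#'   `cds_end` (0-based half-open forward-strand coordinates of the coding
#'   codons, stop excluded).
#' @export
reverse_transcribe <- function(truth, config = generator_config()) {
  set.seed(config$seed + 1L)
  syn <- .syn_codons()
  stops <- syn[["*"]]
  n <- nrow(truth)
  txs <- character(n); strands <- character(n)
  starts <- integer(n); ends <- integer(n)
  for (i in seq_len(n)) {
    aa <- strsplit(truth$precursor[i], "")[[1]]
    ok <- FALSE
    for (try in 1:20) {
      cds <- paste(vapply(aa, function(a) {
        cand <- syn[[a]]
        cand[sample.int(length(cand), 1)]
      }, character(1)), collapse = "")
      cds <- paste0(cds, stops[sample.int(length(stops), 1)])
      u5 <- .rand_utr(sample(config$utr_len_range[1]:config$utr_len_range[2], 1),
                      no_c_tail = TRUE)
      u3 <- .rand_utr(sample(config$utr_len_range[1]:config$utr_len_range[2], 1))
      tx <- paste0(u5, cds, u3)
      strand <- sample(c("+", "-"), 1)
      s0 <- nchar(u5)                       # 0-based CDS start, coding codons
      e0 <- s0 + 3L * length(aa)
      if (strand == "-") {
        tx <- .revcomp(tx)
        tmp <- nchar(tx) - e0
        e0 <- nchar(tx) - s0
        s0 <- tmp
      }
      top <- select_precursor_orf(find_orfs(tx, id = truth$id[i], min_aa = 40L))
      if (!is.null(top) && top$protein == truth$precursor[i] &&
          top$strand == strand && top$start_nt == s0 && top$end_nt == e0) {
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("failed to embed CDS for ", truth$id[i], call. = FALSE)
    txs[i] <- tx; strands[i] <- strand; starts[i] <- s0; ends[i] <- e0
  }
  decoys <- character(config$n_decoys)
  for (j in seq_len(config$n_decoys)) {
    decoys[j] <- .rand_utr(sample(200:600, 1))  # ORF-free by construction
  }
  transcripts <- rbind(
    data.frame(id = truth$id, desc = paste0("synthetic ", truth$family),
               seq = txs, stringsAsFactors = FALSE),
    if (config$n_decoys > 0)
      data.frame(id = sprintf("decoy_%04d", seq_len(config$n_decoys)),
                 desc = "synthetic decoy", seq = decoys,
                 stringsAsFactors = FALSE))
  truth$strand <- strands
  truth$cds_start <- starts
  truth$cds_end <- ends
  list(transcripts = transcripts, truth = truth)
}

#' Simulate a proteome mass list from ground truth
#'
#' Each mature mass (monoisotopic, amidation and disulfide bridges applied)
#' is retained with probability `1 - dropout`, perturbed by Gaussian noise
#' of sd `mass_noise_sd`, and assigned a uniform retention time in 10-50
#' minutes. Deterministic given `config$seed` (offset +2).
#'
#' @param truth `truth` data.frame from [generate_precursors()].
#' @param config The same [generator_config()].
#' @return Data.frame with `rt_min`, `mass_da`, `source_id`.
#' @export
synth_proteome <- function(truth, config = generator_config()) {
  set.seed(config$seed + 2L)
  n <- nrow(truth)
  keep <- stats::runif(n) >= config$dropout
  m <- sum(keep)
  data.frame(
    rt_min = stats::runif(m, 10, 50),
    mass_da = truth$mature_mono_da[keep] +
      stats::rnorm(m, 0, config$mass_noise_sd),
    source_id = truth$id[keep],
    stringsAsFactors = FALSE)
}
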