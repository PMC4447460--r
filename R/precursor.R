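# Precursor segmentation: signal peptide, propeptides, mature peptide and
# C-terminal amidation.

# Kyte-Doolittle hydropathy; X (unknown residue) scored neutral.
.KD <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
         G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
         P = -1.6, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3, X = 0)

# Small residues admitted at the (-3,-1) positions of a signal-peptidase site.
.SMALL <- c("A", "G", "S", "C", "T", "V")

.check_aa <- function(seq, what = "sequence", allow_x = TRUE) {
  pat <- if (allow_x) "[^ACDEFGHIKLMNPQRSTVWYX]" else "[^ACDEFGHIKLMNPQRSTVWY]"
  if (grepl(pat, seq)) {
    stop("illegal amino-acid character in ", what, call. = FALSE)
  }
}

#' Predict the signal-peptide cleavage site
#'
#' A transparent stand-in for trained signal-peptide predictors: every
#' candidate cut position in `[min_cut, max_cut]` is scored as the mean
#' Kyte-Doolittle hydropathy of the hydrophobic core (0-based positions 5
#' to cut-6) plus a bonus of +1 when the residues at cut-3 and cut-1 are
#' small (A, G, S, C, T, V; the classical (-3,-1) rule). The best-scoring
#' cut is returned unless it falls below `threshold`.
#'
#' @param precursor Amino-acid string; must start with M and be at least 25
#'   residues long, otherwise `NULL` is returned.
#' @param min_cut,max_cut Candidate cut range (0-based cut position; the
#'   signal peptide is `[0, cut)`).
#' @param threshold Minimum acceptable score.
#' @return `list(cut, score)` or `NULL` when no credible signal is found.
#' @export
#' @examples
#' fx <- load_precursor_fixture()
#' p <- fx$precursor[fx$name == "comp17_c0_seq1-4"]
#' predict_signal_cleavage(p)$cut  # 23
predict_signal_cleavage <- function(precursor, min_cut = 15L, max_cut = 45L,
                                    threshold = 1.0) {
  .check_aa(precursor, "precursor")
  n <- nchar(precursor)
  if (n < 25 || substr(precursor, 1, 1) != "M") return(NULL)
  aa <- strsplit(precursor, "")[[1]]
  cuts <- seq.int(min_cut, min(max_cut, n - 5L))
  if (length(cuts) == 0) return(NULL)
  score <- vapply(cuts, function(cut) {
    h <- aa[6:(cut - 5L)]                       # 1-based 6..cut-5 = 0-based 5..cut-6
    s <- mean(.KD[h])
    if (aa[cut - 2L] %in% .SMALL && aa[cut] %in% .SMALL) s <- s + 1
    s
  }, numeric(1))
  best <- which.max(score)
  if (score[best] < threshold) return(NULL)
  list(cut = cuts[best], score = unname(score[best]))
}

#' Find proteolytic processing motifs
#'
#' Reports every glycine that can mark the end of a mature peptide: the
#' G[KR][KR] tripeptide motif (GKR/GRR and variants), the G[KR] dipeptide,
#' and a precursor-terminal glycine. Overlapping hits at the same glycine
#' are reported once with the tripeptide kind preferred.
#'
#' @param seq Amino-acid string.
#' @return Data.frame with `pos` (0-based position of the glycine), `kind`
#'   and `motif`, ordered by position.
#' @export
find_processing_motifs <- function(seq) {
  .check_aa(seq)
  aa <- strsplit(seq, "")[[1]]
  n <- length(aa)
  basic <- c("K", "R")
  hits <- list()
  for (i in seq_len(n)) {
    if (aa[i] != "G") next
    if (i + 2 <= n && aa[i + 1] %in% basic && aa[i + 2] %in% basic) {
      hits[[length(hits) + 1L]] <- data.frame(
        pos = i - 1L, kind = "G-KR/G-RR",
        motif = paste(aa[i:(i + 2)], collapse = ""), stringsAsFactors = FALSE)
    } else if (i + 1 <= n && aa[i + 1] %in% basic) {
      hits[[length(hits) + 1L]] <- data.frame(
        pos = i - 1L, kind = "G-K/G-R",
        motif = paste(aa[i:(i + 1)], collapse = ""), stringsAsFactors = FALSE)
    } else if (i == n) {
      hits[[length(hits) + 1L]] <- data.frame(
        pos = i - 1L, kind = "terminal-G", motif = "G",
        stringsAsFactors = FALSE)
    }
  }
  if (length(hits) == 0) {
    return(data.frame(pos = integer(), kind = character(),
                      motif = character(), stringsAsFactors = FALSE))
  }
  do.call(rbind, hits)
}

.acidic_fraction <- function(seq) {
  if (!nzchar(seq)) return(0)
  aa <- strsplit(seq, "")[[1]]
  mean(aa %in% c("D", "E"))
}

#' Segment a precursor into signal, propeptides and mature peptide
#'
#' Applies, in order: (1) signal-peptide prediction
#' ([predict_signal_cleavage()]; a signal of length 0 is used when none is
#' found); (2) the NDBP-style processing motif rule: a G[KR][KR] or G[KR]
#' motif whose glycine lies 8-25 residues downstream of the signal, with an
#' acidic-enriched remainder (at least `acidic_min` D/E, default 0.20:
#' curated NDBP propeptides run 20-40% D/E while cysteine-rich mature
#' regions stay below ~15%) after the motif's basic
#' residues, ends an amidated mature peptide and starts the C-terminal
#' propeptide; (3) the terminal-glycine rule: a precursor ending in G
#' (optionally followed by up to two basic residues) donates a C-terminal
#' amide, provided a cysteine lies within the five residues preceding the
#' donor glycine (the donor directly follows the disulfide scaffold; this
#' guards against ordinary matures that merely end in glycine); (4) the
#' N-terminal propeptide rule: an acidic-enriched stretch of 10-30 residues
#' directly after the signal, ending in R (including KR/ER), followed by at
#' least 20 residues; (5) otherwise everything after the signal is the
#' mature peptide, not amidated.
#'
#' The returned segments always concatenate back to the input precursor:
#' `signal + pro_n + mature + amid_gly + basic + pro_c`.
#'
#' @param precursor Full-length precursor (amino-acid string).
#' @param min_mature Minimum mature length before a processing motif.
#' @param motif_window Furthest glycine offset (residues after the signal)
#'   considered for the motif rule.
#' @param acidic_min Minimum D/E fraction for propeptide detection.
#' @param signal_override Optional externally supplied cut position
#'   (0-based), e.g. from a dedicated signal-peptide predictor; bypasses the
#'   heuristic.
#' @return An object of class `venom_segmentation`: a list with
#'   `precursor`, `signal`, `pro_n`, `mature`, `amid_gly`, `basic`, `pro_c`,
#'   `amidated`, `motif`, `method_flags`, `signal_score`.
#' @export
#' @examples
#' fx <- load_precursor_fixture()
#' s <- segment_precursor(fx$precursor[fx$name == "comp17_c0_seq1-4"])
#' s$mature; s$amidated
segment_precursor <- function(precursor, min_mature = 8L, motif_window = 25L,
                              acidic_min = 0.20, signal_override = NULL) {
  .check_aa(precursor, "precursor")
  n <- nchar(precursor)
  seg <- list(precursor = precursor, signal = "", pro_n = "", mature = "",
              amid_gly = "", basic = "", pro_c = "", amidated = FALSE,
              motif = NA_character_, method_flags = character(),
              signal_score = NA_real_)
  finish <- function(seg) {
    recon <- paste0(seg$signal, seg$pro_n, seg$mature, seg$amid_gly,
                    seg$basic, seg$pro_c)
    stopifnot(identical(recon, seg$precursor))
    class(seg) <- "venom_segmentation"
    seg
  }
  if (n < 25) {
    seg$mature <- precursor
    seg$method_flags <- "too-short"
    return(finish(seg))
  }

  if (!is.null(signal_override)) {
    cut <- as.integer(signal_override)
    seg$method_flags <- c(seg$method_flags, "signal:override")
  } else {
    sig <- predict_signal_cleavage(precursor)
    cut <- if (is.null(sig)) 0L else sig$cut
    seg$signal_score <- if (is.null(sig)) NA_real_ else sig$score
    seg$method_flags <- c(seg$method_flags,
                          if (is.null(sig)) "signal:none" else "signal:heuristic")
  }
  seg$signal <- substr(precursor, 1, cut)
  rest <- substr(precursor, cut + 1L, n)
  nr <- nchar(rest)

  # (2) G[KR][KR] / G[KR] processing motif with an acidic C-terminal propeptide
  motifs <- find_processing_motifs(rest)
  motifs <- motifs[motifs$kind != "terminal-G", , drop = FALSE]
  motifs <- motifs[motifs$pos >= min_mature & motifs$pos <= motif_window, ,
                   drop = FALSE]
  for (k in seq_len(nrow(motifs))) {
    gpos <- motifs$pos[k]                      # 0-based within rest
    basics <- substr(motifs$motif[k], 2, nchar(motifs$motif[k]))
    remainder <- substr(rest, gpos + 2L + nchar(basics), nr)
    if (.acidic_fraction(remainder) >= acidic_min && nzchar(remainder)) {
      seg$mature <- substr(rest, 1, gpos)
      seg$amid_gly <- "G"
      seg$basic <- basics
      seg$pro_c <- remainder
      seg$amidated <- TRUE
      seg$motif <- motifs$motif[k]
      if (nrow(motifs) > k) {
        seg$method_flags <- c(seg$method_flags,
          paste0("other-motifs:", paste(motifs$pos[-seq_len(k)], collapse = ",")))
      }
      seg$method_flags <- c(seg$method_flags, "boundary:motif")
      return(finish(seg))
    }
  }

  # (3) terminal donor glycine (optionally followed by <= 2 basic residues),
  # with a cysteine close upstream of the donor
  m <- regmatches(rest, regexpr("G[KR]{0,2}$", rest))
  if (length(m) == 1 && nzchar(m)) {
    gpos <- nr - nchar(m) + 1L                 # 1-based donor position
    upstream <- substr(rest, max(1L, gpos - 5L), gpos - 1L)
    if (gpos - 1L >= min_mature && grepl("C", upstream)) {
      seg$mature <- substr(rest, 1, gpos - 1L)
      seg$amid_gly <- "G"
      seg$basic <- substr(m, 2, nchar(m))
      seg$amidated <- TRUE
      seg$motif <- m
      seg$method_flags <- c(seg$method_flags, "boundary:terminal-G")
      return(finish(seg))
    }
  }

  # (4) acidic N-terminal propeptide ending in R, then a mature of >= 20 aa
  for (k in 10:30) {
    if (k > nr - 20L) break
    pre <- substr(rest, 1, k)
    if (substr(pre, k, k) == "R" && .acidic_fraction(pre) >= acidic_min) {
      seg$pro_n <- pre
      seg$mature <- substr(rest, k + 1L, nr)
      seg$method_flags <- c(seg$method_flags, "boundary:pro-n")
      return(finish(seg))
    }
  }

  seg$mature <- rest
  seg$method_flags <- c(seg$method_flags, "boundary:terminal")
  finish(seg)
}

#' @export
print.venom_segmentation <- function(x, ...) {
  cat("Precursor segmentation (", nchar(x$precursor), " aa)\n", sep = "")
  cat("  signal : ", if (nzchar(x$signal)) x$signal else "-", "\n", sep = "")
  if (nzchar(x$pro_n)) cat("  pro_n  : ", x$pro_n, "\n", sep = "")
  cat("  mature : ", x$mature, "\n", sep = "")
  if (nzchar(x$pro_c)) cat("  pro_c  : ", x$pro_c, "\n", sep = "")
  cat("  amidated: ", x$amidated,
      if (!is.na(x$motif)) paste0(" (motif ", x$motif, ")"), "\n", sep = "")
  invisible(x)
}

#' Report whether a segmentation implies C-terminal amidation
#'
#' True iff the segmentation identified a donor glycine directly after the
#' mature peptide (processing-motif or terminal-glycine rule).
#'
#' @param segmentation A `venom_segmentation` object.
#' @return Logical scalar.
#' @export
infer_amidation <- function(segmentation) {
  stopifnot(inherits(segmentation, "venom_segmentation"))
  isTRUE(segmentation$amidated) && segmentation$amid_gly == "G"
}

#' Group records with identical amino-acid sequences
#'
#' Mirrors the transcript-to-unique-peptide census of curated venom
#' transcriptomes: several transcripts frequently encode the same precursor.
#'
#' @param ids Character vector of record identifiers.
#' @param seqs Character vector of sequences (same length as `ids`).
#' @return Data.frame, one row per distinct sequence in order of first
#'   occurrence, with `seq`, `n` and a semicolon-joined `members` column.
#' @export
dedupe_unique <- function(ids, seqs) {
  stopifnot(length(ids) == length(seqs))
  if (length(ids) == 0) {
    return(data.frame(seq = character(), n = integer(),
                      members = character(), stringsAsFactors = FALSE))
  }
  first <- !duplicated(seqs)
  keys <- seqs[first]
  members <- vapply(keys, function(k) paste(ids[seqs == k], collapse = ";"),
                    character(1))
  data.frame(seq = keys,
             n = as.integer(table(factor(seqs, levels = keys))),
             members = members, stringsAsFactors = FALSE, row.names = NULL)
}
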