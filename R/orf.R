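# Six-frame translation and selection of the precursor-coding ORF.

#' Translate a nucleotide sequence in a given frame
#'
#' Standard genetic code ([Biostrings::GENETIC_CODE]); codons containing N
#' translate to `X`, stop codons to `*`, and a trailing partial codon is
#' dropped.
#'
#' @param nt Nucleotide string over ACGTN (case-insensitive).
#' @param frame 0, 1 or 2: offset of the first codon.
#' @return Amino-acid string.
#' @export
#' @examples
#' translate_nt("ATGGCC")   # "MA"
translate_nt <- function(nt, frame = 0L) {
  stopifnot(length(nt) == 1, frame %in% 0:2)
  nt <- toupper(nt)
  if (grepl("[^ACGTN]", nt)) {
    stop("illegal nucleotide character in sequence", call. = FALSE)
  }
  n <- nchar(nt) - frame
  n_codons <- n %/% 3
  if (n_codons <= 0) return("")
  starts <- frame + 1L + 3L * (seq_len(n_codons) - 1L)
  codons <- substring(nt, starts, starts + 2L)
  aa <- unname(Biostrings::GENETIC_CODE[codons])
  aa[is.na(aa)] <- "X"  # codons containing N
  paste(aa, collapse = "")
}

.revcomp <- function(nt) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(nt, "")[[1]]), collapse = ""))
}

#' Find open reading frames on both strands
#'
#' In start-anchored mode (default) every methionine-initiated,
#' stop-terminated stretch is reported; stretches running into the end of
#' the sequence without a stop are flagged `partial`. In stop-to-stop mode
#' whole inter-stop segments are reported regardless of a start codon.
#' Coordinates are 0-based half-open on the forward strand and cover the
#' coding codons only (stop codon excluded), so `end_nt - start_nt` equals
#' three times the protein length.
#'
#' Candidates are ordered by decreasing protein length, then strand `+`
#' before `-`, then lower `start_nt`.
#'
#' @param seq Nucleotide string, or a one-row data.frame with `id` and `seq`.
#' @param id Identifier used for `parent_id` when `seq` is a plain string.
#' @param min_aa Minimum protein length to report.
#' @param mode `"start"` (require ATG) or `"stop-to-stop"`.
#' @return Data.frame with columns `parent_id`, `strand`, `frame`,
#'   `start_nt`, `end_nt`, `aa_len`, `partial`, `protein`.
#' @export
find_orfs <- function(seq, id = "seq", min_aa = 40L,
                      mode = c("start", "stop-to-stop")) {
  mode <- match.arg(mode)
  if (is.data.frame(seq)) {
    stopifnot(nrow(seq) == 1)
    id <- seq$id
    seq <- seq$seq
  }
  seq <- toupper(seq)
  L <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else .revcomp(seq)
    for (frame in 0:2) {
      prot <- translate_nt(s, frame)
      if (!nzchar(prot)) next
      aa <- strsplit(prot, "")[[1]]
      np <- length(aa)
      stops <- which(aa == "*")
      seg_start <- c(1L, stops + 1L)
      seg_end <- c(stops - 1L, np)
      for (k in seq_along(seg_start)) {
        a <- seg_start[k]; b <- seg_end[k]
        if (a > b) next
        partial <- (b == np) && (length(stops) == 0 || b > max(stops))
        anchors <- if (mode == "start") a - 1L + which(aa[a:b] == "M") else a
        for (m in anchors) {
          len <- b - m + 1L
          if (len < min_aa) next
          start_f <- frame + 3L * (m - 1L)        # 0-based on coding strand
          end_f <- start_f + 3L * len
          if (strand == "+") {
            start_nt <- start_f; end_nt <- end_f
          } else {
            start_nt <- L - end_f; end_nt <- L - start_f
          }
          out[[length(out) + 1L]] <- data.frame(
            parent_id = id, strand = strand, frame = frame,
            start_nt = start_nt, end_nt = end_nt, aa_len = len,
            partial = partial,
            protein = paste(aa[m:b], collapse = ""),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(parent_id = character(), strand = character(),
                      frame = integer(), start_nt = integer(),
                      end_nt = integer(), aa_len = integer(),
                      partial = logical(), protein = character(),
                      stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  ord <- order(-res$aa_len, res$strand != "+", res$start_nt)
  res <- res[ord, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Select the precursor-coding ORF among candidates
#'
#' Returns the top-ranked candidate under the [find_orfs()] ordering
#' (longest protein; ties broken by forward strand, then lower start), or
#' `NULL` when there are none.
#'
#' @param candidates Data.frame from [find_orfs()].
#' @return A one-row data.frame or `NULL`.
#' @export
select_precursor_orf <- function(candidates) {
  if (is.null(candidates) || nrow(candidates) == 0) return(NULL)
  ord <- order(-candidates$aa_len, candidates$strand != "+",
               candidates$start_nt)
  candidates[ord[1], , drop = FALSE]
}
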