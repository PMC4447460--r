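# Global pairwise alignment and percent identity for cross-species
# comparisons of venom peptides.

#' Optimal global pairwise alignment
#'
#' Needleman-Wunsch global alignment with affine gap penalties, computed by
#' [Biostrings::pairwiseAlignment()] (a gap of length k costs
#' `gap_open + gap_extend * k`; end gaps are penalized). An empty input is
#' aligned as all-gap columns against the other sequence.
#'
#' @param a,b Amino-acid strings (20-letter alphabet).
#' @param gap_open,gap_extend Affine gap penalties (positive costs).
#' @param matrix Substitution matrix name (shipped with Biostrings),
#'   default BLOSUM62.
#' @return An object of class `pairwise_alignment`: list with `aligned_a`,
#'   `aligned_b` (equal-length gapped strings), `score` and `n_identical`.
#' @export
#' @examples
#' global_align("PEPTIDE", "PEPTIDE")$n_identical  # 7
global_align <- function(a, b, gap_open = 10, gap_extend = 0.5,
                         matrix = "BLOSUM62") {
  .check_aa(a, "sequence a", allow_x = FALSE)
  .check_aa(b, "sequence b", allow_x = FALSE)
  if (!nzchar(a) && !nzchar(b)) stop("both sequences empty", call. = FALSE)
  if (!nzchar(a) || !nzchar(b)) {
    other <- if (nzchar(a)) a else b
    gaps <- strrep("-", nchar(other))
    out <- list(aligned_a = if (nzchar(a)) a else gaps,
                aligned_b = if (nzchar(b)) b else gaps,
                score = -(gap_open + gap_extend * nchar(other)),
                n_identical = 0L)
    class(out) <- "pairwise_alignment"
    return(out)
  }
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "global",
    substitutionMatrix = matrix,
    gapOpening = gap_open, gapExtension = gap_extend)
  ga <- as.character(Biostrings::alignedPattern(aln))
  gb <- as.character(Biostrings::alignedSubject(aln))
  ca <- strsplit(ga, "")[[1]]
  cb <- strsplit(gb, "")[[1]]
  out <- list(aligned_a = ga, aligned_b = gb,
              score = Biostrings::score(aln),
              n_identical = sum(ca == cb & ca != "-"))
  class(out) <- "pairwise_alignment"
  out
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("Global alignment (score ", format(x$score), ", ",
      x$n_identical, " identical)\n", sep = "")
  w <- 60L
  n <- nchar(x$aligned_a)
  for (s in seq(1, n, by = w)) {
    e <- min(s + w - 1L, n)
    ca <- substr(x$aligned_a, s, e)
    cb <- substr(x$aligned_b, s, e)
    mid <- paste(ifelse(strsplit(ca, "")[[1]] == strsplit(cb, "")[[1]] &
                          strsplit(ca, "")[[1]] != "-", "|", " "),
                 collapse = "")
    cat(ca, "\n", mid, "\n", cb, "\n\n", sep = "")
  }
  invisible(x)
}

#' Percent identity between two sequences
#'
#' Identity over the optimal global alignment, under either of the two
#' definitions in common use: `"columns"` divides the identical-column
#' count by the alignment length excluding terminal-gap overhang (columns
#' before both sequences have started or after either has ended), and
#' `"shorter"` divides by the length of the shorter sequence.
#'
#' @param a,b Amino-acid strings; an error is raised when both are empty.
#' @param definition `"columns"` or `"shorter"`.
#' @param ... Passed to [global_align()].
#' @return Percentage in `[0, 100]` (two decimals are meaningful; more are
#'   reported).
#' @export
#' @examples
#' percent_identity("PEPTIDE", "PEPTIDE")  # 100
percent_identity <- function(a, b, definition = c("columns", "shorter"), ...) {
  definition <- match.arg(definition)
  if (!nzchar(a) && !nzchar(b)) {
    stop("percent identity undefined for two empty sequences", call. = FALSE)
  }
  aln <- global_align(a, b, ...)
  if (definition == "shorter") {
    denom <- min(nchar(a), nchar(b))
    if (denom == 0) return(0)
    return(100 * aln$n_identical / denom)
  }
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  ia <- which(ca != "-"); ib <- which(cb != "-")
  if (length(ia) == 0 || length(ib) == 0) return(0)
  from <- max(min(ia), min(ib))
  to <- min(max(ia), max(ib))
  if (to < from) return(0)
  100 * aln$n_identical / (to - from + 1L)
}
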