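# Sequence and fixture input/output, plus basic assembly statistics.

#' Path to a packaged data file
#'
#' Convenience accessor for the TSV/FASTA fixtures shipped with the package
#' (the curated precursor table, the proteome mass list and the reference
#' calcin sequences).
#'
#' @param file File name inside the package's `extdata` directory. With no
#'   argument, lists the available files.
#' @return A file path (or a character vector of file names).
#' @export
#' @examples
#' venomtk_extdata()
#' venomtk_extdata("table3_proteome.tsv")
venomtk_extdata <- function(file = NULL) {
  dir <- system.file("extdata", package = "venomtk", mustWork = TRUE)
  if (is.null(file)) return(list.files(dir))
  path <- file.path(dir, file)
  if (!file.exists(path)) stop("no packaged file '", file, "'", call. = FALSE)
  path
}

.alphabet_regex <- function(alphabet) {
  switch(alphabet,
    dna = "[^ACGTN]",
    aa  = "[^ACDEFGHIKLMNPQRSTVWYX*]",
    any = "[^A-Z*]"
  )
}

#' Read a FASTA file into a sequence table
#'
#' Parsing is delegated to [Biostrings::readBStringSet()]; a light pre-scan
#' reports malformed headers or illegal residues with their line number,
#' which the Biostrings parser does not do. Sequences are uppercased and
#' whitespace is stripped; record order is preserved.
#'
#' @param path FASTA file (wrapped or unwrapped, multi-record).
#' @param alphabet `"dna"` (ACGTN), `"aa"` (20 amino acids plus X) or
#'   `"any"`. Validation is applied after uppercasing.
#' @return A data.frame with columns `id`, `desc`, `seq`.
#' @export
read_fasta <- function(path, alphabet = c("any", "dna", "aa")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines) & !startsWith(lines, ";")
  if (!any(keep)) {
    return(data.frame(id = character(), desc = character(), seq = character(),
                      stringsAsFactors = FALSE))
  }
  bad <- .alphabet_regex(alphabet)
  in_body <- FALSE
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    ln <- lines[i]
    if (startsWith(ln, ">")) {
      in_body <- TRUE
      if (grepl("^>\\s*$", ln)) {
        stop("FASTA parse error: empty header at line ", i, call. = FALSE)
      }
    } else {
      if (!in_body) {
        stop("FASTA parse error: sequence before first header at line ", i,
             call. = FALSE)
      }
      res <- toupper(gsub("\\s", "", ln))
      if (grepl(bad, res)) {
        stop("FASTA parse error: illegal character for alphabet '", alphabet,
             "' at line ", i, call. = FALSE)
      }
    }
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  if (any(!nzchar(ids))) stop("FASTA parse error: record with empty id", call. = FALSE)
  data.frame(id = ids, desc = desc,
             seq = toupper(as.character(set)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write a sequence table to FASTA
#'
#' @param records Data.frame with `id`, `seq` and optionally `desc` columns.
#' @param path Output file.
#' @param width Line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.data.frame(records), all(c("id", "seq") %in% names(records)))
  headers <- records$id
  if (!is.null(records$desc)) {
    headers <- ifelse(nzchar(records$desc),
                      paste(records$id, records$desc), records$id)
  }
  set <- Biostrings::BStringSet(stats::setNames(records$seq, headers))
  Biostrings::writeXStringSet(set, path, width = width)
  invisible(path)
}

#' Load an experimental proteome mass list
#'
#' Reads a tab-separated list of deconvolved masses, such as the packaged
#' transcription of the published venom LC-MS list (`table3_proteome.tsv`).
#' Columns named `rt_min` and `mass_da` are used when present; otherwise the
#' first two columns are taken as retention time (minutes) and mass (Da).
#'
#' @param path TSV file with a header row.
#' @return A data.frame with numeric columns `rt_min` and `mass_da` (file
#'   order preserved), plus any further columns present in the file.
#' @export
#' @examples
#' pm <- load_proteome_masses(venomtk_extdata("table3_proteome.tsv"))
#' nrow(pm)
load_proteome_masses <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(tab) == 0) {
    return(data.frame(rt_min = numeric(), mass_da = numeric()))
  }
  if (!all(c("rt_min", "mass_da") %in% names(tab))) {
    if (ncol(tab) < 2) stop("expected at least two columns", call. = FALSE)
    names(tab)[1:2] <- c("rt_min", "mass_da")
  }
  for (col in c("rt_min", "mass_da")) {
    val <- suppressWarnings(as.numeric(tab[[col]]))
    if (anyNA(val)) {
      stop("parse error: non-numeric value in column '", col, "' (row ",
           which(is.na(val))[1], ")", call. = FALSE)
    }
    tab[[col]] <- val
  }
  if (any(tab$mass_da <= 0)) stop("masses must be positive", call. = FALSE)
  if (any(tab$rt_min < 0)) stop("retention times must be non-negative", call. = FALSE)
  tab
}

#' Load the curated precursor fixture
#'
#' Reads the packaged table of curated venom-peptide precursors
#' (`table2_precursors.tsv`): per row the signal peptide, optional
#' N-terminal propeptide, mature peptide, amidation donor glycine, the
#' dibasic residues of the processing motif, the C-terminal propeptide and
#' the amidation flag. The full precursor is reconstructed by concatenation
#' and each row is validated against the segmentation invariants.
#'
#' @param path TSV file; defaults to the packaged fixture.
#' @return A data.frame with the segment columns plus a reconstructed
#'   `precursor` column.
#' @export
#' @examples
#' fx <- load_precursor_fixture()
#' fx[fx$name == "comp17_c0_seq1-4", c("signal", "mature", "amidated")]
load_precursor_fixture <- function(path = venomtk_extdata("table2_precursors.tsv")) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  if (nrow(tab) == 0) return(tab)
  need <- c("name", "signal", "pro_n", "mature", "amid_gly", "basic",
            "pro_c", "amidated")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("fixture lacks columns: ", paste(miss, collapse = ", "))
  seg_cols <- c("signal", "pro_n", "mature", "amid_gly", "basic", "pro_c")
  tab[seg_cols][is.na(tab[seg_cols])] <- ""
  tab$amidated <- toupper(tab$amidated) == "TRUE"
  recon <- do.call(paste0, tab[seg_cols])
  for (i in seq_len(nrow(tab))) {
    if (!nzchar(tab$mature[i])) {
      stop("validation error in row '", tab$name[i], "': empty mature peptide",
           call. = FALSE)
    }
    if (tab$amidated[i] && tab$amid_gly[i] != "G") {
      stop("validation error in row '", tab$name[i],
           "': amidated without donor glycine", call. = FALSE)
    }
    if ("precursor" %in% names(tab) && nzchar(tab$precursor[i]) &&
        tab$precursor[i] != recon[i]) {
      stop("validation error in row '", tab$name[i],
           "': segments do not reconstruct the precursor", call. = FALSE)
    }
  }
  tab$precursor <- recon
  tab
}

#' Assembly statistics (counts, mean length, N50)
#'
#' The N50 is the largest length L such that contigs of length L or longer
#' jointly contain at least half of the assembled bases.
#'
#' @param x A sequence table from [read_fasta()], or a numeric vector of
#'   contig lengths.
#' @return A list with `n_seqs`, `total_nt`, `mean_len`, `n50`.
#' @export
#' @examples
#' assembly_stats(c(2, 2, 2))$n50
assembly_stats <- function(x) {
  lens <- if (is.data.frame(x)) nchar(x$seq) else as.numeric(x)
  if (length(lens) == 0) {
    return(list(n_seqs = 0L, total_nt = 0, mean_len = NaN, n50 = 0))
  }
  stopifnot(all(lens >= 0))
  total <- sum(lens)
  sorted <- sort(lens, decreasing = TRUE)
  n50 <- sorted[which(cumsum(sorted) >= total / 2)[1]]
  list(n_seqs = length(lens), total_nt = total,
       mean_len = mean(lens), n50 = n50)
}
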