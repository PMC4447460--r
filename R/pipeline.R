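# End-to-end orchestration: read -> ORF -> segment -> classify -> mass ->
# match, with TSV/JSON reports; plus the FPKM expression utility.

#' Fragments per kilobase of transcript per million mapped fragments
#'
#' `fpkm = fragments * 1e9 / (mapped_total * length_bp)`.
#'
#' @param fragments Fragments mapped to the transcript (vectorized).
#' @param mapped_total Total mapped fragments in the library.
#' @param length_bp Transcript length in bp.
#' @return FPKM value(s).
#' @export
#' @examples
#' fpkm(1000, 1e6, 1000)  # 1000
fpkm <- function(fragments, mapped_total, length_bp) {
  if (any(length_bp <= 0)) stop("length_bp must be positive", call. = FALSE)
  if (any(mapped_total <= 0)) stop("mapped_total must be positive", call. = FALSE)
  if (any(fragments < 0)) stop("fragments must be non-negative", call. = FALSE)
  as.numeric(fragments) * 1e9 / (as.numeric(mapped_total) * as.numeric(length_bp))
}

#' Run the precursor curation pipeline
#'
#' For every transcript: select the precursor ORF ([find_orfs()],
#' [select_precursor_orf()]), segment it ([segment_precursor()]), classify
#' the mature peptide ([classify_peptide()]) and compute its mass profile
#' ([mass_profile()]). When a proteome mass list is supplied, theoretical
#' masses are matched against it ([match_masses()]). Records without an
#' acceptable ORF are logged as dropped, never lost: every input record
#' appears exactly once in the annotation table or the dropped table.
#'
#' @param input Path to a transcript FASTA file, or a data.frame of records
#'   (`id`, `seq`); nucleotide input is translated, amino-acid input
#'   (detected, or forced with `is_protein = TRUE`) is segmented directly.
#' @param proteome Optional path to a proteome mass TSV or a data.frame
#'   from [load_proteome_masses()].
#' @param out_dir Optional directory; when given, annotation,
#'   classification, mass and match TSVs plus a JSON summary are written.
#' @param tol_da,tol_ppm Matching tolerance (see [match_masses()]).
#' @param rules Family rules (see [load_family_rules()]).
#' @param min_aa Minimum ORF length in residues.
#' @param mass_convention Variant used as the theoretical mass for
#'   matching: one of `"mono_with_ss"`, `"mono_no_ss"`, `"avg_with_ss"`,
#'   `"avg_no_ss"`.
#' @param is_protein Treat input sequences as precursor proteins.
#' @return List with `annotation`, `classification`, `mass`, `dropped`
#'   data.frames, a `match` report (or NULL) and a `summary` list.
#' @export
run_pipeline <- function(input, proteome = NULL, out_dir = NULL,
                         tol_da = 1.0, tol_ppm = NULL,
                         rules = default_family_rules(), min_aa = 40L,
                         mass_convention = c("mono_with_ss", "mono_no_ss",
                                             "avg_with_ss", "avg_no_ss"),
                         is_protein = FALSE) {
  mass_convention <- match.arg(mass_convention)
  records <- if (is.data.frame(input)) input else read_fasta(input)
  if (is.character(proteome)) proteome <- load_proteome_masses(proteome)

  looks_protein <- function(s) grepl("[EFILPQXDHKMRSVWY]", s)
  ann <- list(); dropped <- list()
  for (i in seq_len(nrow(records))) {
    id <- records$id[i]; s <- toupper(records$seq[i])
    if (is_protein || looks_protein(s)) {
      prec <- s
    } else {
      top <- select_precursor_orf(find_orfs(s, id = id, min_aa = min_aa))
      if (is.null(top)) {
        dropped[[length(dropped) + 1L]] <- data.frame(
          id = id, reason = paste0("no ORF of >= ", min_aa, " aa"),
          stringsAsFactors = FALSE)
        next
      }
      prec <- top$protein
    }
    seg <- segment_precursor(prec)
    mp <- mass_profile(seg)
    ann[[length(ann) + 1L]] <- data.frame(
      id = id, precursor = prec, signal = seg$signal, pro_n = seg$pro_n,
      mature = seg$mature, amid_gly = seg$amid_gly, basic = seg$basic,
      pro_c = seg$pro_c, amidated = seg$amidated,
      motif = if (is.na(seg$motif)) "" else seg$motif,
      method_flags = paste(seg$method_flags, collapse = ";"),
      n_cys = mp$n_cys, n_bridges = mp$n_bridges,
      mono_no_ss = mp$variants[["mono_no_ss"]],
      mono_with_ss = mp$variants[["mono_with_ss"]],
      avg_no_ss = mp$variants[["avg_no_ss"]],
      avg_with_ss = mp$variants[["avg_with_ss"]],
      stringsAsFactors = FALSE)
  }
  bind <- function(x, proto) if (length(x)) do.call(rbind, x) else proto
  annotation <- bind(ann, data.frame(id = character(), precursor = character(),
    signal = character(), pro_n = character(), mature = character(),
    amid_gly = character(), basic = character(), pro_c = character(),
    amidated = logical(), motif = character(), method_flags = character(),
    n_cys = integer(), n_bridges = integer(), mono_no_ss = numeric(),
    mono_with_ss = numeric(), avg_no_ss = numeric(), avg_with_ss = numeric(),
    stringsAsFactors = FALSE))
  dropped <- bind(dropped, data.frame(id = character(), reason = character(),
                                      stringsAsFactors = FALSE))

  classification <- cbind(
    id = annotation$id,
    classify_peptide(annotation$mature, rules = rules))
  mass_tab <- annotation[, c("id", "mature", "n_cys", "n_bridges", "amidated",
                             "mono_no_ss", "mono_with_ss", "avg_no_ss",
                             "avg_with_ss")]

  match <- NULL
  if (!is.null(proteome)) {
    theory <- data.frame(name = annotation$id,
                         mass = annotation[[mass_convention]],
                         stringsAsFactors = FALSE)
    theory <- theory[!is.na(theory$mass), , drop = FALSE]
    match <- match_masses(theory, proteome, tol_da = tol_da, tol_ppm = tol_ppm)
  }

  fam_counts <- as.list(table(classification$family))
  summary <- list(
    n_input = nrow(records),
    n_annotated = nrow(annotation),
    n_dropped = nrow(dropped),
    n_unique_precursors = if (nrow(annotation))
      nrow(dedupe_unique(annotation$id, annotation$precursor)) else 0L,
    families = fam_counts,
    n_exp_matched = if (is.null(match)) NA_integer_ else match$n_exp_matched,
    n_theory_matched = if (is.null(match)) NA_integer_ else match$n_theory_matched)

  out <- list(annotation = annotation, classification = classification,
              mass = mass_tab, dropped = dropped, match = match,
              summary = summary)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    wt <- function(x, f) utils::write.table(
      x, file.path(out_dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
    wt(annotation, "annotation.tsv")
    wt(classification, "classification.tsv")
    wt(mass_tab, "mass.tsv")
    wt(dropped, "dropped.tsv")
    if (!is.null(match)) wt(match$matches, "matches.tsv")
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(out)
}
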