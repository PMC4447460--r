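# Theoretical peptide masses under monoisotopic and average conventions,
# with C-terminal amidation and disulfide-bridge mass deltas.

# Standard IUPAC amino-acid residue masses (Da). Monoisotopic values from the
# principal-isotope elemental masses; average values from isotope-abundance-
# weighted atomic weights (the tables used by common protein calculators).
.RESIDUE_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
.RESIDUE_AVG <- c(
  G = 57.0519, A = 71.0788, S = 87.0782, P = 97.1167, V = 99.1326,
  T = 101.1051, C = 103.1388, L = 113.1594, I = 113.1594, N = 114.1038,
  D = 115.0886, Q = 128.1307, K = 128.1741, E = 129.1155, M = 131.1926,
  H = 137.1411, F = 147.1766, R = 156.1875, Y = 163.1760, W = 186.2132)
.WATER <- c(mono = 18.010565, avg = 18.01528)
.HYDROGEN <- c(mono = 1.007825, avg = 1.00794)
# C-terminal amidation: -OH replaced by -NH2.
.AMIDATION <- c(mono = 0.98402, avg = 0.9847)

#' Theoretical mass of an unmodified peptide
#'
#' Sum of standard residue masses plus one water, under the monoisotopic or
#' average convention.
#'
#' @param seq Amino-acid string over the 20-letter alphabet (no X).
#' @param kind `"mono"` or `"avg"`.
#' @return Mass in Da.
#' @export
#' @examples
#' peptide_mass("G", "mono")  # 75.032
peptide_mass <- function(seq, kind = c("mono", "avg")) {
  kind <- match.arg(kind)
  .check_aa(seq, "peptide", allow_x = FALSE)
  if (!nzchar(seq)) stop("empty peptide", call. = FALSE)
  tab <- if (kind == "mono") .RESIDUE_MONO else .RESIDUE_AVG
  sum(tab[strsplit(seq, "")[[1]]]) + .WATER[[kind]]
}

#' Apply post-translational mass deltas
#'
#' C-terminal amidation subtracts 0.98402 Da (monoisotopic) or 0.9847 Da
#' (average); each disulfide bridge subtracts two hydrogen masses.
#'
#' @param base Unmodified mass in Da.
#' @param kind `"mono"` or `"avg"`.
#' @param amidated Apply the amidation delta?
#' @param n_bridges Number of disulfide bridges formed.
#' @return Modified mass in Da.
#' @export
apply_modifications <- function(base, kind = c("mono", "avg"),
                                amidated = FALSE, n_bridges = 0L) {
  kind <- match.arg(kind)
  stopifnot(n_bridges >= 0)
  out <- base
  if (amidated) out <- out - .AMIDATION[[kind]]
  out - n_bridges * 2 * .HYDROGEN[[kind]]
}

#' Mass profile of a mature peptide
#'
#' Computes all four mass conventions used when comparing transcript-derived
#' theoretical masses with LC-MS proteome masses: monoisotopic and average,
#' each with and without subtraction of the disulfide hydrogens. The
#' amidation delta (when the segmentation flags a donor glycine) is applied
#' to all four. Published theoretical masses frequently mix these
#' conventions, so reports carry all variants rather than committing to one.
#'
#' The number of bridges is `floor(#Cys / 2)`; an odd cysteine count is
#' flagged (one free thiol).
#'
#' @param x A `venom_segmentation` object, or a mature peptide string.
#' @param amidated Used when `x` is a plain string.
#' @param ... Unused.
#' @return An object of class `mass_profile`: list with `mature`,
#'   `amidated`, `n_cys`, `n_bridges`, `odd_cys`, `available` and a named
#'   numeric `variants` vector (`mono_no_ss`, `mono_with_ss`, `avg_no_ss`,
#'   `avg_with_ss`), plus `mono_da`/`avg_da` (the with-bridges values).
#'   Peptides containing X yield an unavailable profile (all masses NA).
#' @export
#' @examples
#' p <- mass_profile("ILSAIWSGIKSLF", amidated = TRUE)
#' round(p$variants[["avg_no_ss"]], 2)  # 1433.76
mass_profile <- function(x, ...) UseMethod("mass_profile")

#' @rdname mass_profile
#' @export
mass_profile.venom_segmentation <- function(x, ...) {
  mass_profile.character(x$mature, amidated = infer_amidation(x))
}

#' @rdname mass_profile
#' @export
mass_profile.character <- function(x, amidated = FALSE, ...) {
  stopifnot(length(x) == 1)
  n_cys <- lengths(regmatches(x, gregexpr("C", x, fixed = TRUE)))
  n_bridges <- n_cys %/% 2L
  odd <- n_cys %% 2L == 1L
  out <- list(mature = x, amidated = amidated, n_cys = as.integer(n_cys),
              n_bridges = as.integer(n_bridges), odd_cys = odd,
              available = TRUE)
  if (grepl("X", x, fixed = TRUE) || !nzchar(x)) {
    out$available <- FALSE
    out$variants <- c(mono_no_ss = NA_real_, mono_with_ss = NA_real_,
                      avg_no_ss = NA_real_, avg_with_ss = NA_real_)
    out$mono_da <- NA_real_
    out$avg_da <- NA_real_
    class(out) <- "mass_profile"
    return(out)
  }
  if (odd) warning("odd cysteine count (", n_cys, "); ", n_bridges,
                   " bridge(s) assumed, one free thiol", call. = FALSE)
  mono <- apply_modifications(peptide_mass(x, "mono"), "mono", amidated, 0L)
  avg <- apply_modifications(peptide_mass(x, "avg"), "avg", amidated, 0L)
  out$variants <- c(
    mono_no_ss = mono,
    mono_with_ss = apply_modifications(mono, "mono", FALSE, n_bridges),
    avg_no_ss = avg,
    avg_with_ss = apply_modifications(avg, "avg", FALSE, n_bridges))
  out$mono_da <- out$variants[["mono_with_ss"]]
  out$avg_da <- out$variants[["avg_with_ss"]]
  class(out) <- "mass_profile"
  out
}

#' @export
print.mass_profile <- function(x, ...) {
  cat("Mass profile: ", x$mature, "\n", sep = "")
  cat("  Cys ", x$n_cys, " (", x$n_bridges, " bridge(s)",
      if (x$odd_cys) ", odd count", "); amidated ", x$amidated, "\n", sep = "")
  if (x$available) {
    v <- round(x$variants, 4)
    cat(sprintf("  mono %0.4f (no SS) / %0.4f (with SS)\n",
                v[["mono_no_ss"]], v[["mono_with_ss"]]))
    cat(sprintf("  avg  %0.4f (no SS) / %0.4f (with SS)\n",
                v[["avg_no_ss"]], v[["avg_with_ss"]]))
  } else cat("  (mass unavailable: ambiguous residue)\n")
  invisible(x)
}

#' Closest mass-convention variant to an observed mass
#'
#' @param profile A `mass_profile`.
#' @param observed Observed/printed mass in Da.
#' @return List with `variant`, `mass_da`, `delta_da`.
#' @export
closest_variant <- function(profile, observed) {
  stopifnot(inherits(profile, "mass_profile"))
  if (!profile$available) {
    return(list(variant = NA_character_, mass_da = NA_real_,
                delta_da = NA_real_))
  }
  d <- abs(profile$variants - observed)
  i <- which.min(d)
  list(variant = names(profile$variants)[i],
       mass_da = unname(profile$variants[i]),
       delta_da = unname(profile$variants[i] - observed))
}
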