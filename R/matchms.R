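# Correlation of theoretical peptide masses with an experimental proteome
# mass list.

#' Match theoretical masses against an experimental mass list
#'
#' Reports every theory/experiment pair whose mass difference is within the
#' tolerance (absolute Da, or relative ppm of the experimental mass), and
#' labels each experimental mass with its nearest theoretical candidate
#' (smallest absolute delta; ties broken by lower theory index). Retention
#' time is carried through but never used for matching.
#'
#' @param theory Data.frame with columns `name` and `mass` (Da), or a named
#'   numeric vector.
#' @param experiment Data.frame with columns `rt_min` and `mass_da`, e.g.
#'   from [load_proteome_masses()].
#' @param tol_da Absolute tolerance in Da (default 1.0).
#' @param tol_ppm Relative tolerance in ppm; overrides `tol_da` when given.
#' @return An object of class `mass_match_report`: list with `matches`
#'   (data.frame `theory_name`, `theory_da`, `exp_rt_min`, `exp_da`,
#'   `delta_da`, `delta_ppm`), `nearest` (per experimental mass),
#'   `n_exp_matched`, `n_theory_matched`, `tolerance`.
#' @export
#' @examples
#' t3 <- utils::read.delim(venomtk_extdata("table3_proteome.tsv"))
#' rep <- match_masses(data.frame(name = t3$name, mass = t3$theor_mw_da),
#'                     load_proteome_masses(venomtk_extdata("table3_proteome.tsv")),
#'                     tol_da = 4.0)
#' rep$n_exp_matched  # 16
match_masses <- function(theory, experiment, tol_da = 1.0, tol_ppm = NULL) {
  if (is.numeric(theory)) {
    theory <- data.frame(name = names(theory), mass = unname(theory),
                         stringsAsFactors = FALSE)
  }
  use_ppm <- !is.null(tol_ppm)
  tol <- if (use_ppm) tol_ppm else tol_da
  stopifnot(tol > 0)
  empty <- data.frame(theory_name = character(), theory_da = numeric(),
                      exp_rt_min = numeric(), exp_da = numeric(),
                      delta_da = numeric(), delta_ppm = numeric(),
                      stringsAsFactors = FALSE)
  out <- list(matches = empty, nearest = empty,
              n_exp_matched = 0L, n_theory_matched = 0L,
              tolerance = list(value = tol, unit = if (use_ppm) "ppm" else "Da"))
  class(out) <- "mass_match_report"
  nt <- nrow(theory); ne <- nrow(experiment)
  if (nt == 0 || ne == 0) return(out)

  delta <- outer(theory$mass, experiment$mass_da, `-`)        # theory - exp
  lim <- if (use_ppm) {
    matrix(rep(tol * 1e-6 * experiment$mass_da, each = nt), nrow = nt)
  } else tol
  hit <- abs(delta) <= lim
  idx <- which(hit, arr.ind = TRUE)
  if (nrow(idx)) {
    ord <- order(idx[, "col"], idx[, "row"])
    idx <- idx[ord, , drop = FALSE]
    out$matches <- data.frame(
      theory_name = theory$name[idx[, "row"]],
      theory_da = theory$mass[idx[, "row"]],
      exp_rt_min = experiment$rt_min[idx[, "col"]],
      exp_da = experiment$mass_da[idx[, "col"]],
      delta_da = delta[idx],
      delta_ppm = delta[idx] * 1e6 / experiment$mass_da[idx[, "col"]],
      stringsAsFactors = FALSE)
  }
  near_i <- vapply(seq_len(ne), function(j) {
    d <- abs(delta[, j])
    which(d == min(d))[1]
  }, integer(1))
  out$nearest <- data.frame(
    exp_rt_min = experiment$rt_min,
    exp_da = experiment$mass_da,
    theory_name = theory$name[near_i],
    theory_da = theory$mass[near_i],
    delta_da = theory$mass[near_i] - experiment$mass_da,
    stringsAsFactors = FALSE)
  out$n_exp_matched <- sum(colSums(hit) > 0)
  out$n_theory_matched <- sum(rowSums(hit) > 0)
  out
}

#' @export
print.mass_match_report <- function(x, ...) {
  cat("Mass match report (tolerance ", x$tolerance$value, " ",
      x$tolerance$unit, ")\n", sep = "")
  cat("  ", nrow(x$matches), " pair(s); ", x$n_exp_matched,
      " experimental and ", x$n_theory_matched,
      " theoretical mass(es) matched\n", sep = "")
  invisible(x)
}
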