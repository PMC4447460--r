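# Rule-based classification of mature peptides into venom families.

#' Load family classification rules
#'
#' Rules live in a YAML file (see the packaged
#' `extdata/family_rules.yaml`) so users can add or adjust families without
#' touching code. Each rule has an `id`, a `family` label, and optional
#' `cys` (admissible cysteine counts), `len` (inclusive length bounds) and
#' `motif` (regular expression) constraints; rules are applied in file
#' order and the first match wins.
#'
#' @param path YAML rules file.
#' @return A list of rule lists, in priority order.
#' @export
load_family_rules <- function(path = venomtk_extdata("family_rules.yaml")) {
  spec <- yaml::read_yaml(path)
  rules <- spec$rules
  if (is.null(rules)) stop("rules file has no 'rules' entry", call. = FALSE)
  ids <- vapply(rules, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate rule ids", call. = FALSE)
  for (r in rules) {
    if (!is.null(r$len) && r$len[1] > r$len[2]) {
      stop("rule '", r$id, "': length bounds reversed", call. = FALSE)
    }
  }
  rules
}

#' Default family rules
#'
#' The packaged rule set covering the scorpion-venom families:
#' Ascaris-type protease inhibitors (10 Cys), agatoxin-like calcins
#' (8 Cys + CC doublet), La1-like peptides (8 Cys, ~73 aa), defensins
#' (6 Cys, GFGCP), calcins (6 Cys, ~33 aa, CC), DDH calcins (4 Cys),
#' alpha-KTx (6/8 Cys, 23-42 aa), NaTx-like, scorpine-like/beta-KTx,
#' allergen-like and the three cysteine-free NDBP length classes.
#'
#' @return A list of rules (see [load_family_rules()]).
#' @export
default_family_rules <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- load_family_rules()
    cache
  }
})

.classify_one <- function(mature, rules) {
  if (is.na(mature) || !nzchar(mature)) {
    return(list(family = "unclassified", rule_id = NA_character_,
                reason = "empty"))
  }
  if (grepl("X", mature, fixed = TRUE)) {
    return(list(family = "unclassified", rule_id = NA_character_,
                reason = "ambiguous residue X"))
  }
  len <- nchar(mature)
  cys <- lengths(regmatches(mature, gregexpr("C", mature, fixed = TRUE)))
  for (r in rules) {
    if (!is.null(r$cys) && !(cys %in% r$cys)) next
    if (!is.null(r$len) && (len < r$len[1] || len > r$len[2])) next
    if (!is.null(r$motif) && !grepl(r$motif, mature)) next
    return(list(family = r$family, rule_id = r$id, reason = NA_character_))
  }
  if (cys >= 1) {
    return(list(family = "venom-protein/other", rule_id = "fallback_cys",
                reason = NA_character_))
  }
  list(family = "unclassified", rule_id = NA_character_, reason = "no rule")
}

#' Classify mature peptides into venom families
#'
#' Deterministic, total classification: every input receives exactly one
#' family label. Cysteine-containing peptides matching no family rule fall
#' back to `venom-protein/other`; empty peptides or peptides containing the
#' ambiguity character X are `unclassified`.
#'
#' @param mature Character vector of mature peptide sequences.
#' @param rules Rule list from [load_family_rules()]; defaults to the
#'   packaged rules.
#' @return Data.frame with one row per input: `mature`, `family`, `length`,
#'   `cys`, `rule_id`, `reason`.
#' @export
#' @examples
#' classify_peptide("ILSAIWSGIKSLF")$family                       # NDBP-short
#' classify_peptide("KDCLKKLKLCKENKDCCSKSCKRRGTNIEKRCR")$family   # calcin
classify_peptide <- function(mature, rules = default_family_rules()) {
  calls <- lapply(as.character(mature), .classify_one, rules = rules)
  data.frame(
    mature = as.character(mature),
    family = vapply(calls, `[[`, character(1), "family"),
    length = ifelse(is.na(mature), 0L, nchar(as.character(mature))),
    cys = vapply(as.character(mature), function(s) {
      if (is.na(s)) 0L else lengths(regmatches(s, gregexpr("C", s, fixed = TRUE)))
    }, integer(1), USE.NAMES = FALSE),
    rule_id = vapply(calls, `[[`, character(1), "rule_id"),
    reason = vapply(calls, `[[`, character(1), "reason"),
    stringsAsFactors = FALSE, row.names = NULL)
}
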