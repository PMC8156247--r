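# Post-translational modification deltas for cyclic cores.
#
# The amatoxin state (tryptathionine Trp-Cys bridge, four hydroxylations,
# one sulfoxide) is modeled as element-count deltas applied to the
# unmodified macrocycle formula: net +5 O, -2 H. Intact-mass matching needs
# only the net composition, not the placement of the modifications.

#' Modification delta
#'
#' A named, signed element-count change with an optional applicability
#' requirement expressed as a set of residues that must all be present in
#' the core sequence.
#'
#' @param name Modification name.
#' @param delta Named numeric vector of signed integer element-count
#'   changes, e.g. `c(H = -2)`.
#' @param requires Character vector of one-letter residue codes that must
#'   all occur in the core (default none).
#' @return An object of class `modification_delta`.
#' @examples
#' modification_delta("tryptathionine", c(H = -2), requires = c("W", "C"))
#' @export
modification_delta <- function(name, delta, requires = character(0)) {
  stopifnot(is.character(name), length(name) == 1L)
  if (length(delta) && (is.null(names(delta)) || any(!nzchar(names(delta)))))
    stop("delta must be a named element-count vector")
  if (any(delta != round(delta))) stop("delta counts must be integers")
  structure(list(name = name, delta = delta, requires = toupper(requires)),
            class = "modification_delta")
}

#' Toxin modification template
#'
#' An ordered list of [modification_delta()]s applied together to a cyclic
#' core.
#'
#' @param name Template name.
#' @param deltas List of `modification_delta` objects.
#' @param enabled Whether [candidate_mass_list()] considers this template by
#'   default.
#' @return An object of class `toxin_template`.
#' @export
toxin_template <- function(name, deltas, enabled = TRUE) {
  stopifnot(is.character(name), length(name) == 1L)
  ok <- vapply(deltas, inherits, logical(1), "modification_delta")
  if (!all(ok)) stop("deltas must be modification_delta objects")
  structure(list(name = name, deltas = deltas, enabled = isTRUE(enabled)),
            class = "toxin_template")
}

#' @export
print.toxin_template <- function(x, ...) {
  cat("<toxin_template> ", x$name,
      if (!x$enabled) " (disabled)", ": ",
      paste(vapply(x$deltas, `[[`, "", "name"), collapse = " + "), "\n", sep = "")
  invisible(x)
}

#' Built-in amatoxin template
#'
#' Converts an unmodified macrocycle into the amatoxin modification state:
#' tryptathionine bridge (-2 H, requires Trp and Cys), four hydroxylations
#' (+4 O) and one sulfoxide (+1 O, requires Cys). Net delta +5 O, -2 H
#' (+77.958925 Da). Applied to cyclo(IWGIGCNP) / cyclo(IWGIGCDP) this
#' yields the alpha-/beta-amanitin formulas C39H54N10O14S / C39H53N9O15S.
#'
#' @return A `toxin_template`.
#' @export
amatoxin_template <- function() {
  toxin_template("amatoxin", list(
    modification_delta("tryptathionine", c(H = -2), requires = c("W", "C")),
    modification_delta("hydroxylation_x4", c(O = 4)),
    modification_delta("sulfoxide", c(O = 1), requires = "C")
  ))
}

#' Phallotoxin template stub
#'
#' Provided as a configuration stub only and disabled by default: the
#' template carries the tryptathionine bridge and hydroxylations typical of
#' phallotoxins but is not used by [candidate_mass_list()] unless enabled
#' explicitly (phallotoxins are absent in the species this model targets).
#'
#' @return A disabled `toxin_template`.
#' @export
phallotoxin_template <- function() {
  toxin_template("phallotoxin", list(
    modification_delta("tryptathionine", c(H = -2), requires = c("W", "C")),
    modification_delta("hydroxylation_x3", c(O = 3))
  ), enabled = FALSE)
}

#' Read modification templates from a JSON config file
#'
#' The file holds an array of objects with fields `name`, optional
#' `enabled`, and `deltas`: an array of `{name, delta: {element: count},
#' requires: [residues]}`.
#'
#' @param path Path to the JSON file.
#' @return A list of `toxin_template` objects.
#' @export
read_templates <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  lapply(raw, function(tpl) {
    deltas <- lapply(tpl$deltas, function(d) {
      modification_delta(d$name, unlist(d$delta),
                         requires = as.character(unlist(d$requires)))
    })
    toxin_template(tpl$name, deltas,
                   enabled = if (is.null(tpl$enabled)) TRUE else tpl$enabled)
  })
}

.net_delta <- function(template) {
  out <- numeric(0)
  for (d in template$deltas) {
    for (el in names(d$delta)) {
      out[el] <- (if (el %in% names(out)) out[el] else 0) + d$delta[[el]]
    }
  }
  out
}

#' Apply a toxin template to a cyclic core
#'
#' Checks every delta's residue requirement against the core sequence, then
#' adds the signed element deltas to the unmodified cyclic formula. Errors
#' if a requirement fails or an element count would become negative.
#'
#' @param core A cyclic `peptide` (or a sequence string, taken as cyclic).
#' @param template A `toxin_template` (default [amatoxin_template()]).
#' @return The modified `mol_formula`.
#' @examples
#' apply_template(peptide("IWGIGCNP", "cyclic"))  # C39H54N10O14S
#' @export
apply_template <- function(core, template = amatoxin_template()) {
  core <- .as_peptide(core)
  if (core$topology != "cyclic") stop("core must be cyclic")
  stopifnot(inherits(template, "toxin_template"))
  residues <- strsplit(core$sequence, "")[[1]]
  for (d in template$deltas) {
    missing <- setdiff(d$requires, residues)
    if (length(missing))
      stop(sprintf("modification '%s' of template '%s' requires residue(s) %s absent from core %s",
                   d$name, template$name, paste(missing, collapse = ","), core$sequence))
  }
  f <- peptide_formula(core)
  net <- .net_delta(template)
  if (length(net) == 0L) return(f)
  pos <- net[net > 0]
  neg <- -net[net < 0]
  if (length(pos)) f <- f + mol_formula(pos)
  if (length(neg)) f <- f - mol_formula(neg)   # errors on negative counts
  f
}

#' Candidate cyclic peptides with and without toxin modifications
#'
#' For each core emits the unmodified head-to-tail macrocycle; additionally
#' emits one modified candidate per enabled template whose residue
#' requirements the core satisfies (for the amatoxin template: cores
#' containing both Trp and Cys). Each candidate carries its Hill formula,
#' neutral monoisotopic mass and singly protonated m/z.
#'
#' @param cores Character vector of core sequences (or list of cyclic
#'   `peptide`s).
#' @param templates List of `toxin_template`s considered (default: the
#'   amatoxin template; disabled templates are skipped).
#' @return A data.frame with columns `core`, `modification`, `formula`,
#'   `neutral_mass`, `mz`.
#' @examples
#' candidate_mass_list(c("IWGIGCNP", "GFGFIP"))
#' @export
candidate_mass_list <- function(cores, templates = list(amatoxin_template())) {
  if (length(cores) == 0L)
    return(data.frame(core = character(0), modification = character(0),
                      formula = character(0), neutral_mass = numeric(0),
                      mz = numeric(0), stringsAsFactors = FALSE))
  rows <- list()
  for (core in cores) {
    pep <- .as_peptide(core)
    f <- peptide_formula(pep)
    m <- peptide_mass(pep)
    rows[[length(rows) + 1L]] <- data.frame(
      core = pep$sequence, modification = "none",
      formula = formula_string(f), neutral_mass = m,
      mz = mz_protonated(m), stringsAsFactors = FALSE)
    residues <- strsplit(pep$sequence, "")[[1]]
    for (tpl in templates) {
      if (!tpl$enabled) next
      req_ok <- all(vapply(tpl$deltas, function(d) all(d$requires %in% residues),
                           logical(1)))
      if (!req_ok) next
      fm <- apply_template(pep, tpl)
      mm <- formula_mass(fm)
      rows[[length(rows) + 1L]] <- data.frame(
        core = pep$sequence, modification = tpl$name,
        formula = formula_string(fm), neutral_mass = mm,
        mz = mz_protonated(mm), stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
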