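# Exact monoisotopic mass and molecular-formula arithmetic for linear and
# head-to-tail cyclic peptides.
#
# All arithmetic uses a fixed internal table of monoisotopic element masses
# (6 decimal places) so that reported 4-decimal m/z values are reproducible
# independent of external constant tables.

.ELEMENT_MASSES <- c(
  C = 12.000000,
  H = 1.007825,
  N = 14.003074,
  O = 15.994915,
  S = 31.972071
)
.PROTON_MASS <- 1.007276
.ELECTRON_MASS <- 0.000549

# residue formulas: amino acid minus one water
.RESIDUE_FORMULAS <- list(
  A = c(C = 3, H = 5, N = 1, O = 1),
  C = c(C = 3, H = 5, N = 1, O = 1, S = 1),
  D = c(C = 4, H = 5, N = 1, O = 3),
  E = c(C = 5, H = 7, N = 1, O = 3),
  F = c(C = 9, H = 9, N = 1, O = 1),
  G = c(C = 2, H = 3, N = 1, O = 1),
  H = c(C = 6, H = 7, N = 3, O = 1),
  I = c(C = 6, H = 11, N = 1, O = 1),
  K = c(C = 6, H = 12, N = 2, O = 1),
  L = c(C = 6, H = 11, N = 1, O = 1),
  M = c(C = 5, H = 9, N = 1, O = 1, S = 1),
  N = c(C = 4, H = 6, N = 2, O = 2),
  P = c(C = 5, H = 7, N = 1, O = 1),
  Q = c(C = 5, H = 8, N = 2, O = 2),
  R = c(C = 6, H = 12, N = 4, O = 1),
  S = c(C = 3, H = 5, N = 1, O = 2),
  T = c(C = 4, H = 7, N = 1, O = 2),
  V = c(C = 5, H = 9, N = 1, O = 1),
  W = c(C = 11, H = 10, N = 2, O = 1),
  Y = c(C = 9, H = 9, N = 1, O = 2)
)

.AA_ALPHABET <- names(.RESIDUE_FORMULAS)

.WATER <- c(H = 2, O = 1)

#' Monoisotopic element mass table
#'
#' Fixed monoisotopic masses (Da, 6 decimals) for C, H, N, O, S plus the
#' proton and electron masses used for ionized species. The proton mass is
#' the hydrogen-atom mass minus one electron mass; protonated m/z values use
#' the proton (not the hydrogen-atom) mass.
#'
#' @return A list with components `elements` (named numeric vector),
#'   `proton` and `electron` (Da).
#' @examples
#' element_masses()$proton  # 1.007276
#' @export
element_masses <- function() {
  list(elements = .ELEMENT_MASSES,
       proton = .PROTON_MASS,
       electron = .ELECTRON_MASS)
}

#' Molecular formula
#'
#' A molecular formula is a named vector of non-negative integer element
#' counts. Formulas support `+` and `-`; subtraction errors if any element
#' count would become negative.
#'
#' @param counts Named numeric vector of non-negative integer counts, e.g.
#'   `c(C = 2, H = 5, N = 1, O = 2)`. Zero counts are dropped.
#' @return An object of class `mol_formula`.
#' @examples
#' mol_formula(c(C = 39, H = 54, N = 10, O = 14, S = 1))
#' parse_formula("C39H54N10O14S")
#' @export
mol_formula <- function(counts = numeric(0)) {
  if (length(counts) == 0L) {
    x <- integer(0)
    names(x) <- character(0)
    return(structure(x, class = "mol_formula"))
  }
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("all formula counts must be named by element symbol")
  if (any(counts != round(counts)))
    stop("element counts must be integers")
  if (any(counts < 0))
    stop("element counts must be non-negative")
  counts <- counts[counts > 0]
  x <- as.integer(counts)
  names(x) <- names(counts)
  # merge duplicated symbols
  if (anyDuplicated(names(x))) {
    x <- vapply(split(x, names(x)), sum, integer(1))
  }
  structure(x[order(names(x))], class = "mol_formula")
}

#' @rdname mol_formula
#' @param string Formula string such as `"C39H54N10O14S"`.
#' @export
parse_formula <- function(string) {
  stopifnot(is.character(string), length(string) == 1L)
  s <- gsub("\\s", "", string)
  if (!nzchar(s)) return(mol_formula())
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", s)[[1]]
  toks <- regmatches(s, list(m))[[1]]
  if (sum(attr(m, "match.length")) != nchar(s))
    stop("cannot parse formula string: ", string)
  sym <- sub("[0-9]*$", "", toks)
  num <- sub("^[A-Za-z]+", "", toks)
  cnt <- ifelse(nzchar(num), as.integer(num), 1L)
  names(cnt) <- sym
  mol_formula(cnt)
}

.as_counts <- function(f) {
  if (inherits(f, "mol_formula")) return(unclass(f))
  unclass(mol_formula(f))
}

#' @export
`+.mol_formula` <- function(e1, e2) {
  a <- .as_counts(e1); b <- .as_counts(e2)
  el <- union(names(a), names(b))
  out <- ifelse(el %in% names(a), a[el], 0L) + ifelse(el %in% names(b), b[el], 0L)
  names(out) <- el
  mol_formula(out)
}

#' @export
`-.mol_formula` <- function(e1, e2) {
  if (missing(e2)) stop("unary minus is not defined for formulas")
  a <- .as_counts(e1); b <- .as_counts(e2)
  el <- union(names(a), names(b))
  out <- ifelse(el %in% names(a), a[el], 0L) - ifelse(el %in% names(b), b[el], 0L)
  names(out) <- el
  if (any(out < 0))
    stop("formula subtraction would give negative count for: ",
         paste(el[out < 0], collapse = ", "))
  mol_formula(out)
}

#' @export
format.mol_formula <- function(x, ...) formula_string(x)

#' @export
print.mol_formula <- function(x, ...) {
  cat("<mol_formula> ", formula_string(x), "\n", sep = "")
  invisible(x)
}

#' Hill-order formula string
#'
#' Formats a formula as carbon first, hydrogen second, then remaining
#' elements alphabetically (Hill convention).
#'
#' @param formula A `mol_formula`.
#' @return A single string, `""` for the empty formula.
#' @export
formula_string <- function(formula) {
  cnt <- .as_counts(formula)
  if (length(cnt) == 0L) return("")
  el <- names(cnt)
  ord <- c(intersect(c("C", "H"), el), sort(setdiff(el, c("C", "H"))))
  paste0(ord, ifelse(cnt[ord] == 1L, "", cnt[ord]), collapse = "")
}

#' Monoisotopic mass of a molecular formula
#'
#' @param formula A `mol_formula` (or named count vector).
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' formula_mass(parse_formula("H2O"))  # 18.010565
#' @export
formula_mass <- function(formula) {
  cnt <- .as_counts(formula)
  if (length(cnt) == 0L) return(0)
  unknown <- setdiff(names(cnt), names(.ELEMENT_MASSES))
  if (length(unknown))
    stop("unknown element symbol: ", paste(unknown, collapse = ", "))
  sum(cnt * .ELEMENT_MASSES[names(cnt)])
}

#' Amino-acid residue table
#'
#' Residue (amino acid minus water) molecular formulas and monoisotopic
#' masses for the 20 standard amino acids. Residue masses are computed from
#' the residue formulas using the internal element-mass table.
#'
#' @return A data.frame with columns `code`, `formula` (Hill string) and
#'   `mass` (Da), one row per residue.
#' @export
residue_table <- function() {
  data.frame(
    code = .AA_ALPHABET,
    formula = vapply(.RESIDUE_FORMULAS, function(f) formula_string(mol_formula(f)), ""),
    mass = vapply(.RESIDUE_FORMULAS, formula_mass, 0),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

.RESIDUE_MASSES <- vapply(.RESIDUE_FORMULAS, function(f) sum(f * .ELEMENT_MASSES[names(f)]), 0)

.check_sequence <- function(sequence) {
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!(chars %in% .AA_ALPHABET))
  if (length(bad))
    stop(sprintf("non-standard residue '%s' at position %d", chars[bad[1]], bad[1]))
  chars
}

#' Peptide with linear or head-to-tail cyclic topology
#'
#' @param sequence One-letter amino-acid string over the 20-letter standard
#'   alphabet.
#' @param topology `"linear"` or `"cyclic"`; a cyclic peptide needs at least
#'   two residues.
#' @return An object of class `peptide`.
#' @examples
#' peptide("GFGFIP", "cyclic")
#' @export
peptide <- function(sequence, topology = c("linear", "cyclic")) {
  topology <- match.arg(topology)
  stopifnot(is.character(sequence), length(sequence) == 1L)
  if (nchar(sequence) < 1L) stop("sequence must have length >= 1")
  if (topology == "cyclic" && nchar(sequence) < 2L)
    stop("cyclic topology requires length >= 2")
  .check_sequence(sequence)
  structure(list(sequence = sequence, topology = topology), class = "peptide")
}

#' @export
print.peptide <- function(x, ...) {
  if (x$topology == "cyclic") {
    cat("<peptide> cyclo(", x$sequence, ")\n", sep = "")
  } else {
    cat("<peptide> ", x$sequence, "\n", sep = "")
  }
  invisible(x)
}

.as_peptide <- function(x, topology = "cyclic") {
  if (inherits(x, "peptide")) x else peptide(x, topology)
}

#' Molecular formula of a peptide
#'
#' The cyclic formula is the element-wise sum of the residue formulas; the
#' linear formula additionally gains one water (the terminal H and OH).
#'
#' @param pep A `peptide`.
#' @return A `mol_formula`.
#' @examples
#' peptide_formula(peptide("GFGFIP", "cyclic"))  # C33H42N6O6
#' @export
peptide_formula <- function(pep) {
  stopifnot(inherits(pep, "peptide"))
  chars <- .check_sequence(pep$sequence)
  total <- Reduce(`+`, lapply(.RESIDUE_FORMULAS[chars], mol_formula))
  if (pep$topology == "linear") total <- total + mol_formula(.WATER)
  total
}

#' Neutral monoisotopic mass of a peptide
#'
#' Computed by two independent routes: direct summation of residue masses
#' (`route = "residue"`, default) or via the molecular formula
#' (`route = "formula"`). The two agree to well within 1e-5 Da and serve as
#' a cross-check of the element bookkeeping.
#'
#' @param pep A `peptide`.
#' @param route `"residue"` or `"formula"`.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptide_mass(peptide("GFGFIP", "cyclic"))  # 618.3166
#' @export
peptide_mass <- function(pep, route = c("residue", "formula")) {
  route <- match.arg(route)
  stopifnot(inherits(pep, "peptide"))
  if (route == "formula") return(formula_mass(peptide_formula(pep)))
  chars <- .check_sequence(pep$sequence)
  m <- sum(.RESIDUE_MASSES[chars])
  if (pep$topology == "linear") m <- m + formula_mass(mol_formula(.WATER))
  m
}

#' Protonated m/z
#'
#' `[M + z H]^z+` m/z computed with the proton mass (1.007276 Da), i.e.
#' `(M + z * m_p) / z`.
#'
#' @param neutral_mass Neutral monoisotopic mass in Da.
#' @param charge Positive integer charge state (default 1).
#' @return m/z in Th.
#' @examples
#' mz_protonated(618.3166)  # ~619.3239
#' @export
mz_protonated <- function(neutral_mass, charge = 1L) {
  if (any(charge < 1) || any(charge != round(charge)))
    stop("charge must be a positive integer")
  (neutral_mass + charge * .PROTON_MASS) / charge
}

#' Signed ppm mass deviation
#'
#' `(measured - theoretical) / theoretical * 1e6`.
#'
#' @param measured Measured m/z.
#' @param theoretical Theoretical m/z (> 0).
#' @return Signed deviation in ppm.
#' @examples
#' ppm_delta(619.3244, 619.3239)  # 0.8073
#' @export
ppm_delta <- function(measured, theoretical) {
  if (any(theoretical <= 0)) stop("theoretical m/z must be > 0")
  (measured - theoretical) / theoretical * 1e6
}
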