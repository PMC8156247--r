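# Theoretical MS/MS fragment ions of head-to-tail cyclic peptides.
#
# A macrocycle fragments after ring opening: cleaving one of the n ring
# amides yields a linear isomer (a rotation of the sequence), which then
# fragments like a linear peptide. "y-type" ions of the paper's annotation
# are modeled as contiguous arcs of the cycle carrying y-ion chemistry
# (arc residue sum + H2O + proton); b-type arcs (sum + proton) are also
# enumerated. Immonium ions cover single residues; neutral losses (-NH3 on
# K/R/N/Q, -H2O on S/T/D/E) are applied per-subsequence.

.NH3_MASS <- 17.026549   # N + 3 H
.H2O_MASS <- 18.010565   # 2 H + O
.CO_MASS <- 27.994915    # C + O

.NH3_RESIDUES <- c("K", "R", "N", "Q")
.H2O_RESIDUES <- c("S", "T", "D", "E")

#' Immonium ion m/z
#'
#' The low-mass diagnostic cation `H2N+=CH-R` of a single residue:
#' residue mass - CO + H - electron.
#'
#' @param residue One-letter residue code.
#' @return m/z of the singly charged immonium ion.
#' @examples
#' immonium_mz("F")  # 120.0808
#' @export
immonium_mz <- function(residue) {
  stopifnot(is.character(residue), length(residue) == 1L)
  residue <- toupper(residue)
  if (!(residue %in% .AA_ALPHABET)) stop("invalid residue: ", residue)
  .RESIDUE_MASSES[[residue]] - .CO_MASS + .ELEMENT_MASSES[["H"]] - .ELECTRON_MASS
}

#' Ring openings of a cyclic peptide
#'
#' Enumerates the n linear isomers of an n-residue cycle: opening the ring
#' after position i yields the rotation starting at position i+1.
#'
#' @param core A cyclic `peptide` (or sequence string, taken as cyclic).
#' @return Character vector of n rotations (possibly with repeats for
#'   symmetric cycles).
#' @examples
#' ring_openings(peptide("GFGFIP", "cyclic"))
#' @export
ring_openings <- function(core) {
  core <- .as_peptide(core)
  if (core$topology != "cyclic") stop("ring_openings requires a cyclic peptide")
  s <- core$sequence
  n <- nchar(s)
  vapply(seq_len(n), function(i) {
    j <- i %% n + 1L   # rotation starts at i+1 (wrapping)
    paste0(substr(s, j, n), substr(s, 1, j - 1L))
  }, "")
}

#' b/y fragment ion series of a linear peptide
#'
#' For a linear peptide of length n, emits b_i (N-terminal prefix sum +
#' proton) and y_i (C-terminal suffix sum + H2O + proton) for i = 1..n-1.
#' The conservation identity b_i + y_(n-i) = M + H2O + 2 protons holds,
#' with M the sum of residue masses.
#'
#' @param linear A linear `peptide` (or sequence string).
#' @return A data.frame with columns `kind` (`"b"`/`"y"`), `index`,
#'   `subsequence`, `mz`, `label`.
#' @examples
#' by_series(peptide("GP", "linear"))
#' @export
by_series <- function(linear) {
  linear <- .as_peptide(linear, topology = "linear")
  if (linear$topology != "linear") stop("by_series requires a linear peptide")
  chars <- strsplit(linear$sequence, "")[[1]]
  n <- length(chars)
  if (n < 2L) stop("b/y series requires length >= 2")
  masses <- .RESIDUE_MASSES[chars]
  idx <- seq_len(n - 1L)
  b_mz <- cumsum(masses)[idx] + .PROTON_MASS
  y_mz <- rev(cumsum(rev(masses)))[idx + 1L] + .H2O_MASS + .PROTON_MASS
  b_sub <- vapply(idx, function(i) paste(chars[1:i], collapse = ""), "")
  y_sub <- vapply(idx, function(i) paste(chars[(i + 1L):n], collapse = ""), "")
  rbind(
    data.frame(kind = "b", index = idx, subsequence = b_sub, mz = b_mz,
               label = paste0("b:", b_sub), stringsAsFactors = FALSE),
    data.frame(kind = "y", index = n - idx, subsequence = y_sub, mz = y_mz,
               label = paste0("y:", y_sub), stringsAsFactors = FALSE)
  )
}

.loss_variants <- function(ions) {
  out <- list()
  has_any <- function(sub, set) any(strsplit(sub, "")[[1]] %in% set)
  nh3 <- ions[vapply(ions$subsequence, has_any, TRUE, set = .NH3_RESIDUES), ,
              drop = FALSE]
  if (nrow(nh3)) {
    nh3$kind <- paste0(nh3$kind, "-NH3")
    nh3$mz <- nh3$mz - .NH3_MASS
    nh3$label <- paste0(nh3$kind, ":", nh3$subsequence)
    out[[length(out) + 1L]] <- nh3
  }
  h2o <- ions[vapply(ions$subsequence, has_any, TRUE, set = .H2O_RESIDUES), ,
              drop = FALSE]
  if (nrow(h2o)) {
    h2o$kind <- paste0(h2o$kind, "-H2O")
    h2o$mz <- h2o$mz - .H2O_MASS
    h2o$label <- paste0(h2o$kind, ":", h2o$subsequence)
    out[[length(out) + 1L]] <- h2o
  }
  out
}

#' Theoretical fragment-ion library of a cyclic peptide
#'
#' Union over all ring openings of the b/y series, plus immonium ions of
#' all distinct residues, neutral-loss variants (-NH3 for subsequences
#' containing K/R/N/Q, -H2O for S/T/D/E), and the precursor ion with its
#' eligible loss variants. Entries are deduplicated by
#' `(kind, mz rounded to 4 decimals)`, so arcs of equal composition
#' collapse to one entry; all fragments are singly charged.
#'
#' @param core A cyclic `peptide` (or sequence string).
#' @param losses Character subset of `c("nh3", "h2o")` enabling the
#'   neutral-loss variants (default both).
#' @return An object of class `fragment_library`: list with `core`,
#'   `precursor_mz`, and `ions` (data.frame `kind`, `label`, `subsequence`,
#'   `length`, `mz`).
#' @examples
#' lib <- build_library(peptide("GKVNPP", "cyclic"))
#' head(lib$ions)
#' @export
build_library <- function(core, losses = c("nh3", "h2o")) {
  core <- .as_peptide(core)
  if (core$topology != "cyclic") stop("build_library requires a cyclic core")
  losses <- if (length(losses))
    match.arg(tolower(losses), c("nh3", "h2o"), several.ok = TRUE) else
    character(0)
  chars <- strsplit(core$sequence, "")[[1]]
  n <- length(chars)
  prec_mz <- mz_protonated(peptide_mass(core))

  base <- do.call(rbind, lapply(ring_openings(core), by_series))
  base <- base[, c("kind", "subsequence", "mz", "label")]

  imm <- data.frame(kind = "immonium", subsequence = unique(chars),
                    mz = vapply(unique(chars), immonium_mz, 0),
                    stringsAsFactors = FALSE)
  imm$label <- paste0("imm:", imm$subsequence)
  imm <- imm[, c("kind", "subsequence", "mz", "label")]

  prec <- data.frame(kind = "precursor", subsequence = core$sequence,
                     mz = prec_mz,
                     label = paste0("prec:", core$sequence),
                     stringsAsFactors = FALSE)

  variants <- .loss_variants(rbind(base, prec))
  keep_kinds <- c("b", "y", "immonium", "precursor")
  if ("nh3" %in% losses)
    keep_kinds <- c(keep_kinds, "b-NH3", "y-NH3", "precursor-NH3")
  if ("h2o" %in% losses)
    keep_kinds <- c(keep_kinds, "b-H2O", "y-H2O", "precursor-H2O")

  ions <- rbind(base, imm, prec, do.call(rbind, c(list(base[0, ]), variants)))
  ions <- ions[ions$kind %in% keep_kinds, , drop = FALSE]
  key <- paste(ions$kind, sprintf("%.4f", ions$mz))
  dup <- duplicated(key)
  ions <- ions[!dup, , drop = FALSE]
  ions$length <- nchar(ions$subsequence)
  ions <- ions[order(ions$mz, ions$kind), c("kind", "label", "subsequence",
                                            "length", "mz")]
  rownames(ions) <- NULL
  structure(list(core = core, precursor_mz = prec_mz, ions = ions),
            class = "fragment_library")
}

#' @export
print.fragment_library <- function(x, ...) {
  cat("<fragment_library> cyclo(", x$core$sequence, "): ",
      nrow(x$ions), " ions, precursor [M+H]+ ",
      sprintf("%.4f", x$precursor_mz), "\n", sep = "")
  invisible(x)
}

#' Write a fragment library to TSV
#'
#' @param library A `fragment_library`.
#' @param path Output TSV path.
#' @return Invisibly, the ion data.frame.
#' @export
write_library <- function(library, path) {
  stopifnot(inherits(library, "fragment_library"))
  utils::write.table(library$ions, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(library$ions)
}
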