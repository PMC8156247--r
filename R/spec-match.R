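# Matching candidate cyclic peptides against MS data: precursor m/z
# screening within ppm tolerance and MS/MS fragment annotation with a
# deterministic nearest-peak rule.

#' MS/MS spectrum
#'
#' @param id Spectrum identifier.
#' @param precursor_mz Precursor m/z (> 0).
#' @param peaks Two-column matrix or data.frame (`mz`, `intensity`); sorted
#'   ascending by m/z on construction, intensities must be non-negative.
#' @param charge Precursor charge (default 1).
#' @param metadata Optional named list.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(id, precursor_mz, peaks, charge = 1L, metadata = list()) {
  stopifnot(length(precursor_mz) == 1L, precursor_mz > 0)
  peaks <- as.data.frame(peaks)
  if (ncol(peaks) < 2L) peaks <- data.frame(mz = numeric(0), intensity = numeric(0))
  names(peaks)[1:2] <- c("mz", "intensity")
  peaks <- peaks[, c("mz", "intensity")]
  if (any(peaks$intensity < 0)) stop("intensities must be non-negative")
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  rownames(peaks) <- NULL
  structure(list(id = as.character(id), precursor_mz = precursor_mz,
                 charge = as.integer(charge), peaks = peaks,
                 metadata = metadata),
            class = "spectrum")
}

#' @export
print.spectrum <- function(x, ...) {
  cat("<spectrum> ", x$id, ": precursor ", sprintf("%.4f", x$precursor_mz),
      " (", x$charge, "+), ", nrow(x$peaks), " peaks\n", sep = "")
  invisible(x)
}

#' Read spectra from a Mascot generic format (MGF) file
#'
#' Supports the standard dialect: `BEGIN IONS` / `END IONS` blocks with
#' `PEPMASS=` (first token is the precursor m/z), optional `CHARGE=` (e.g.
#' `1+`, defaults to 1+) and `TITLE=`, and whitespace-separated
#' `mz intensity` peak lines. Peaks are sorted on load.
#'
#' @param path Path to the MGF file.
#' @return A list of `spectrum` objects (empty list for an empty file).
#' @export
read_mgf <- function(path) {
  lines <- readLines(path, warn = FALSE)
  spectra <- list()
  in_block <- FALSE
  block_line <- 0L
  title <- NULL; pepmass <- NULL; charge <- 1L
  mzs <- numeric(0); ints <- numeric(0)
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || startsWith(ln, "#")) next
    if (ln == "BEGIN IONS") {
      if (in_block) stop("nested BEGIN IONS at line ", i)
      in_block <- TRUE; block_line <- i
      title <- NULL; pepmass <- NULL; charge <- 1L
      mzs <- numeric(0); ints <- numeric(0)
    } else if (ln == "END IONS") {
      if (!in_block) stop("END IONS without BEGIN IONS at line ", i)
      if (is.null(pepmass)) stop("block starting at line ", block_line,
                                 " has no PEPMASS")
      id <- if (is.null(title)) paste0("spectrum_", length(spectra) + 1L) else title
      spectra[[length(spectra) + 1L]] <-
        spectrum(id, pepmass, data.frame(mz = mzs, intensity = ints),
                 charge = charge)
      in_block <- FALSE
    } else if (in_block && grepl("=", ln, fixed = TRUE)) {
      key <- toupper(sub("=.*$", "", ln))
      val <- sub("^[^=]*=", "", ln)
      if (key == "PEPMASS") {
        pepmass <- suppressWarnings(as.numeric(strsplit(trimws(val), "\\s+")[[1]][1]))
        if (is.na(pepmass)) stop("unparseable PEPMASS at line ", i)
      } else if (key == "CHARGE") {
        ch <- suppressWarnings(as.integer(gsub("[^0-9]", "", val)))
        if (!is.na(ch) && ch >= 1L) charge <- ch
      } else if (key == "TITLE") {
        title <- trimws(val)
      }
    } else if (in_block) {
      toks <- strsplit(ln, "\\s+")[[1]]
      vals <- suppressWarnings(as.numeric(toks))
      if (length(vals) < 2L || anyNA(vals[1:2]))
        stop("malformed peak line at line ", i, ": ", ln)
      mzs <- c(mzs, vals[1]); ints <- c(ints, vals[2])
    } else {
      # header junk outside blocks is ignored
    }
  }
  if (in_block) stop("unterminated BEGIN IONS block starting at line ", block_line)
  spectra
}

#' Read a plain two-column peak list
#'
#' First line `PRECURSOR <mz> [<charge>]`, then whitespace-separated
#' `mz intensity` lines.
#'
#' @param path Path to the peak-list file.
#' @param id Spectrum id (defaults to the file name).
#' @return A `spectrum`.
#' @export
read_peaklist <- function(path, id = basename(path)) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines) || !grepl("^PRECURSOR\\b", trimws(lines[1])))
    stop("peak list must start with a 'PRECURSOR <mz> [<charge>]' header")
  toks <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  pepmass <- as.numeric(toks[2])
  charge <- if (length(toks) >= 3L) as.integer(toks[3]) else 1L
  if (is.na(pepmass)) stop("unparseable PRECURSOR header")
  peaks <- if (length(lines) > 1L) {
    vals <- lapply(lines[-1], function(ln) as.numeric(strsplit(trimws(ln), "\\s+")[[1]]))
    bad <- which(vapply(vals, function(v) length(v) < 2L || anyNA(v[1:2]), TRUE))
    if (length(bad)) stop("malformed peak line ", bad[1] + 1L)
    data.frame(mz = vapply(vals, `[`, 0, 1), intensity = vapply(vals, `[`, 0, 2))
  } else data.frame(mz = numeric(0), intensity = numeric(0))
  spectrum(id, pepmass, peaks, charge = charge)
}

#' Screen spectra against candidate precursor masses
#'
#' Reports every (spectrum, candidate) pair whose precursor m/z lies within
#' `tol_ppm` of the candidate's theoretical `[M+H]+`, with the signed ppm
#' deviation.
#'
#' @param spectra List of `spectrum` objects (or a single one).
#' @param candidates Candidate table from [candidate_mass_list()].
#' @param tol_ppm Precursor tolerance in ppm (default 5).
#' @return A data.frame with columns `spectrum_id`, `core`, `modification`,
#'   `theoretical_mz`, `measured_mz`, `ppm`.
#' @export
screen_precursors <- function(spectra, candidates, tol_ppm = 5) {
  stopifnot(tol_ppm > 0)
  if (inherits(spectra, "spectrum")) spectra <- list(spectra)
  rows <- list()
  for (sp in spectra) {
    ppm <- ppm_delta(sp$precursor_mz, candidates$mz)
    hit <- which(abs(ppm) <= tol_ppm)
    for (h in hit) {
      rows[[length(rows) + 1L]] <- data.frame(
        spectrum_id = sp$id, core = candidates$core[h],
        modification = candidates$modification[h],
        theoretical_mz = candidates$mz[h], measured_mz = sp$precursor_mz,
        ppm = ppm[h], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(spectrum_id = character(0), core = character(0),
                      modification = character(0), theoretical_mz = numeric(0),
                      measured_mz = numeric(0), ppm = numeric(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Annotate MS/MS fragments against a theoretical library
#'
#' Each library entry is matched to its nearest observed peak; a match
#' stands if the deviation is within `tol_ppm` or within the absolute floor
#' `abs_tol_da` (the ppm window shrinks below instrument resolution in the
#' low-mass immonium region). A peak may annotate several isobaric library
#' entries, but each library entry matches at most one peak. Coverage is
#' the fraction of arc lengths `1..n-1` with at least one matched
#' (non-precursor) ion; the score is `n_matched + coverage`.
#'
#' @param sp A `spectrum`.
#' @param library A `fragment_library`.
#' @param tol_ppm Fragment tolerance in ppm (default 10).
#' @param min_intensity_fraction Drop peaks below this fraction of the base
#'   peak before matching (default 0 = keep all).
#' @param abs_tol_da Absolute tolerance floor in Da (default 0.002).
#' @return An object of class `spectrum_match` with elements `spectrum_id`,
#'   `core`, `matches` (data.frame), `n_matched`, `coverage`, `score`.
#' @export
annotate_fragments <- function(sp, library, tol_ppm = 10,
                               min_intensity_fraction = 0,
                               abs_tol_da = 0.002) {
  stopifnot(inherits(sp, "spectrum"), inherits(library, "fragment_library"),
            tol_ppm > 0,
            min_intensity_fraction >= 0, min_intensity_fraction < 1)
  peaks <- sp$peaks
  if (nrow(peaks) && min_intensity_fraction > 0) {
    peaks <- peaks[peaks$intensity >= min_intensity_fraction * max(peaks$intensity), ,
                   drop = FALSE]
  }
  ions <- library$ions
  n <- nchar(library$core$sequence)
  matches <- list()
  if (nrow(peaks)) {
    for (k in seq_len(nrow(ions))) {
      theo <- ions$mz[k]
      j <- which.min(abs(peaks$mz - theo))
      err_da <- peaks$mz[j] - theo
      err_ppm <- err_da / theo * 1e6
      tol_da <- max(tol_ppm * theo / 1e6, abs_tol_da)
      if (abs(err_da) <= tol_da) {
        matches[[length(matches) + 1L]] <- data.frame(
          kind = ions$kind[k], label = ions$label[k],
          subsequence = ions$subsequence[k], length = ions$length[k],
          mz_theoretical = theo, mz_observed = peaks$mz[j],
          intensity = peaks$intensity[j],
          error_da = err_da, error_ppm = err_ppm,
          stringsAsFactors = FALSE)
      }
    }
  }
  matches <- if (length(matches)) do.call(rbind, matches) else
    data.frame(kind = character(0), label = character(0),
               subsequence = character(0), length = integer(0),
               mz_theoretical = numeric(0), mz_observed = numeric(0),
               intensity = numeric(0), error_da = numeric(0),
               error_ppm = numeric(0), stringsAsFactors = FALSE)
  matches <- matches[!duplicated(matches$label), , drop = FALSE]
  rownames(matches) <- NULL
  frag <- matches[!startsWith(matches$kind, "precursor"), , drop = FALSE]
  arc_lengths <- seq_len(n - 1L)
  coverage <- if (length(arc_lengths))
    mean(arc_lengths %in% unique(frag$length)) else 0
  n_matched <- nrow(matches)
  structure(list(spectrum_id = sp$id, core = library$core$sequence,
                 precursor_mz = sp$precursor_mz,
                 theoretical_mz = library$precursor_mz,
                 matches = matches, n_matched = n_matched,
                 coverage = coverage, score = n_matched + coverage),
            class = "spectrum_match")
}

#' @export
print.spectrum_match <- function(x, ...) {
  cat("<spectrum_match> ", x$spectrum_id, " vs cyclo(", x$core, "): ",
      x$n_matched, " matched ion(s), coverage ",
      sprintf("%.2f", x$coverage), ", score ", sprintf("%.2f", x$score),
      "\n", sep = "")
  invisible(x)
}

#' Build a candidate-level match report
#'
#' One row per candidate in the style of a theoretical-vs-measured mass
#' table: candidates without a precursor hit carry `NA` measured m/z and
#' ppm; when several spectra hit one candidate the smallest |ppm| wins.
#' Candidates sharing a theoretical m/z (rounded to 4 decimals) are flagged
#' isobaric.
#'
#' @param screens Screening results from [screen_precursors()].
#' @param candidates Candidate table from [candidate_mass_list()].
#' @param annotations Optional list of `spectrum_match` objects; their
#'   `n_matched` is joined by core sequence.
#' @return A data.frame with columns `core`, `modification`, `formula`,
#'   `theoretical_mz`, `measured_mz`, `ppm`, `n_fragments`, `isobaric`.
#' @export
build_report <- function(screens, candidates, annotations = NULL) {
  rep <- candidates[, c("core", "modification", "formula", "mz")]
  names(rep)[names(rep) == "mz"] <- "theoretical_mz"
  rep$measured_mz <- NA_real_
  rep$ppm <- NA_real_
  rep$n_fragments <- NA_integer_
  if (nrow(screens)) {
    for (i in seq_len(nrow(rep))) {
      hits <- screens[screens$core == rep$core[i] &
                        screens$modification == rep$modification[i], , drop = FALSE]
      if (nrow(hits)) {
        best <- hits[which.min(abs(hits$ppm)), ]
        rep$measured_mz[i] <- best$measured_mz
        rep$ppm[i] <- best$ppm
      }
    }
  }
  if (!is.null(annotations)) {
    for (ann in annotations) {
      sel <- rep$core == ann$core & !is.na(rep$measured_mz)
      if (any(sel))
        rep$n_fragments[sel] <- pmax(rep$n_fragments[sel], ann$n_matched,
                                     na.rm = TRUE)
    }
  }
  key <- sprintf("%.4f", rep$theoretical_mz)
  rep$isobaric <- key %in% key[duplicated(key)]
  rownames(rep) <- NULL
  rep
}

#' Write a match report to TSV, using the "N/A" convention for misses
#'
#' @param report Report from [build_report()].
#' @param path Output TSV path.
#' @return Invisibly, the formatted data.frame.
#' @export
write_report <- function(report, path) {
  out <- report
  out$theoretical_mz <- sprintf("%.4f", out$theoretical_mz)
  out$measured_mz <- ifelse(is.na(out$measured_mz), "N/A",
                            sprintf("%.4f", out$measured_mz))
  out$ppm <- ifelse(is.na(out$ppm), "N/A", sprintf("%.4f", out$ppm))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out)
}
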