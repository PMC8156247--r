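# Motif-based mining of MSDIN precursor peptides.
#
# An MSDIN precursor is a short protein: a 10-aa leader starting with Met, a
# 5-12-aa core (excised and macrocyclized by POPB), and a 15-17-aa follower
# (recognition) sequence running to the end of the protein. Mining scans
# protein (or six-frame-translated nucleotide) sequences with a
# position-specific leader pattern and resolves the core/follower boundary
# by the follower-length constraint: stop codons terminate candidate
# windows, so a precursor must lie entirely between stops.

#' MSDIN precursor model
#'
#' Position-specific residue-set patterns and length constraints that define
#' a precursor. The default leader pattern
#' `M [ST] [DN] I N [AS] [TLSI] [RH] [LF] [PA]` matches all published
#' leaders of the family in this species (including the Ala-terminal
#' leaders of AmAMA2/AmAMA3); the default follower start is
#' `[CYF] [VIA] [GSDA]`.
#'
#' @param leader_pattern List of 10 character vectors, the allowed residues
#'   per leader position.
#' @param follower_start_pattern List of character vectors, the allowed
#'   residues at the first follower positions.
#' @param core_length Length-2 integer range for the core (inclusive).
#' @param follower_length Length-2 integer range for the follower, measured
#'   from the follower start to the first stop/sequence end.
#' @param precursor_length Length-2 integer range for the whole precursor.
#' @return An object of class `precursor_model`.
#' @export
precursor_model <- function(
    leader_pattern = list("M", c("S", "T"), c("D", "N"), "I", "N",
                          c("A", "S"), c("T", "L", "S", "I"), c("R", "H"),
                          c("L", "F"), c("P", "A")),
    follower_start_pattern = list(c("C", "Y", "F"), c("V", "I", "A"),
                                  c("G", "S", "D", "A")),
    core_length = c(5L, 12L),
    follower_length = c(15L, 17L),
    precursor_length = c(30L, 40L)) {
  stopifnot(length(leader_pattern) >= 1L,
            length(follower_start_pattern) >= 1L,
            length(core_length) == 2L, core_length[1] <= core_length[2],
            length(follower_length) == 2L, follower_length[1] <= follower_length[2],
            length(precursor_length) == 2L, precursor_length[1] <= precursor_length[2])
  structure(list(leader_pattern = lapply(leader_pattern, toupper),
                 follower_start_pattern = lapply(follower_start_pattern, toupper),
                 core_length = as.integer(core_length),
                 follower_length = as.integer(follower_length),
                 precursor_length = as.integer(precursor_length)),
            class = "precursor_model")
}

.match_pattern_at <- function(chars, pattern, at) {
  if (at + length(pattern) - 1L > length(chars)) return(FALSE)
  for (i in seq_along(pattern)) {
    if (!(chars[at + i - 1L] %in% pattern[[i]])) return(FALSE)
  }
  TRUE
}

.empty_hits <- function() {
  data.frame(source_id = character(0), start = integer(0), end = integer(0),
             frame = character(0), nt_start = integer(0), nt_end = integer(0),
             leader = character(0), core = character(0),
             follower = character(0), stringsAsFactors = FALSE)
}

# Scan one protein string; returns hit rows with 0-based half-open aa coords.
.scan_protein <- function(id, seq, model) {
  chars <- strsplit(toupper(seq), "")[[1]]
  n <- length(chars)
  stops <- c(which(chars == "*"), n + 1L)
  llen <- length(model$leader_pattern)
  rows <- list()
  seg_start <- 1L
  for (stop_at in stops) {
    seg_end <- stop_at - 1L
    if (seg_end - seg_start + 1L >= model$precursor_length[1]) {
      m_pos <- seg_start - 1L + which(chars[seg_start:seg_end] == "M")
      for (s in m_pos) {
        wlen <- seg_end - s + 1L
        if (wlen < model$precursor_length[1] || wlen > model$precursor_length[2]) next
        if (!.match_pattern_at(chars, model$leader_pattern, s)) next
        # leftmost follower start with matching start pattern and an implied
        # follower length (to the window end) inside the allowed range
        found <- NA_integer_
        for (j in (llen + model$core_length[1]):(llen + model$core_length[2])) {
          flen <- wlen - j
          if (flen < model$follower_length[1] || flen > model$follower_length[2]) next
          if (.match_pattern_at(chars, model$follower_start_pattern, s + j)) {
            found <- j
            break
          }
        }
        if (is.na(found)) next
        rows[[length(rows) + 1L]] <- data.frame(
          source_id = id, start = s - 1L, end = s - 1L + wlen,
          frame = NA_character_, nt_start = NA_integer_, nt_end = NA_integer_,
          leader = paste(chars[s:(s + llen - 1L)], collapse = ""),
          core = paste(chars[(s + llen):(s + found - 1L)], collapse = ""),
          follower = paste(chars[(s + found):(s + wlen - 1L)], collapse = ""),
          stringsAsFactors = FALSE)
      }
    }
    seg_start <- stop_at + 1L
  }
  if (length(rows) == 0L) return(.empty_hits())
  do.call(rbind, rows)
}

.as_named_seqs <- function(x) {
  if (inherits(x, "XStringSet")) {
    out <- as.character(x)
    if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
    return(out)
  }
  if (is.data.frame(x)) {
    stopifnot(all(c("id", "sequence") %in% names(x)))
    return(stats::setNames(as.character(x$sequence), as.character(x$id)))
  }
  out <- stats::setNames(as.character(x), names(x))
  if (is.null(names(out))) names(out) <- paste0("seq", seq_along(out))
  out
}

#' Find MSDIN precursors in protein sequences
#'
#' Scans each sequence for windows that start at a Met matching the leader
#' pattern and end at the next stop (`*`) or the sequence end, and splits
#' each window into leader / core / follower. The core/follower boundary is
#' the leftmost candidate position (after leader + minimum core) whose
#' residues match the follower-start pattern and whose implied follower
#' length falls in the allowed range; this rejects pattern look-alikes
#' inside the core (for example the internal Cys of IWGIGCNP, whose implied
#' follower would be 20 aa).
#'
#' @param proteins Named character vector of protein sequences, a
#'   data.frame with columns `id` and `sequence`, or an `AAStringSet`.
#' @param model A [precursor_model()].
#' @return A data.frame of hits with 0-based half-open coordinates, sorted
#'   by `(source_id, start)`: columns `source_id`, `start`, `end`, `frame`,
#'   `nt_start`, `nt_end`, `leader`, `core`, `follower`.
#' @examples
#' hits <- find_msdin_precursors(msdin_precursor_seqs())
#' nrow(hits)  # 21
#' @export
find_msdin_precursors <- function(proteins, model = precursor_model()) {
  seqs <- .as_named_seqs(proteins)
  stopifnot(inherits(model, "precursor_model"))
  hits <- do.call(rbind, c(list(.empty_hits()),
                           Map(.scan_protein, names(seqs), seqs,
                               MoreArgs = list(model = model))))
  hits <- hits[order(hits$source_id, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Six-frame translation
#'
#' Translates a DNA sequence in frames +1, +2, +3 and, on the reverse
#' complement, -1, -2, -3 under the standard genetic code. Stop codons are
#' rendered as `*`; trailing partial codons are dropped; codons containing
#' `N` translate to the residue if unambiguous, otherwise `X`.
#'
#' @param dna A single DNA string over `A C G T N` (case-insensitive).
#' @return A named character vector of 6 protein strings
#'   (`+1, +2, +3, -1, -2, -3`).
#' @examples
#' translate_six_frames("ATGTCA")[["+1"]]  # "MS"
#' @export
translate_six_frames <- function(dna) {
  stopifnot(is.character(dna), length(dna) == 1L)
  up <- toupper(dna)
  bad <- regexpr("[^ACGTN]", up)
  if (bad > 0)
    stop(sprintf("invalid nucleotide '%s' at position %d",
                 substr(up, bad, bad), bad))
  fwd <- Biostrings::DNAString(up)
  rev <- Biostrings::reverseComplement(fwd)
  tr1 <- function(x, k) {
    L <- length(x)
    ncod <- (L - k + 1L) %/% 3L
    if (ncod < 1L) return("")
    sub <- Biostrings::subseq(x, k, k + 3L * ncod - 1L)
    as.character(suppressWarnings(
      Biostrings::translate(sub, no.init.codon = TRUE, if.fuzzy.codon = "solve")))
  }
  out <- c(tr1(fwd, 1L), tr1(fwd, 2L), tr1(fwd, 3L),
           tr1(rev, 1L), tr1(rev, 2L), tr1(rev, 3L))
  names(out) <- c("+1", "+2", "+3", "-1", "-2", "-3")
  out
}

# aa interval (0-based half-open, within the frame translation) -> forward
# strand nt interval (0-based half-open)
.nt_interval <- function(frame, aa_start, aa_end, L) {
  k <- abs(as.integer(frame))
  off <- k - 1L
  if (as.integer(frame) > 0L) {
    c(off + 3L * aa_start, off + 3L * aa_end)
  } else {
    c(L - (off + 3L * aa_end), L - (off + 3L * aa_start))
  }
}

#' Mine a FASTA file (protein or nucleotide) for MSDIN precursors
#'
#' Nucleotide input is translated in all six frames (intronless windows);
#' hits carry the frame and the 0-based half-open interval on the forward
#' strand in addition to the amino-acid coordinates within the frame
#' translation.
#'
#' @param path Path to a FASTA file.
#' @param type `"auto"` (detect from the alphabet), `"prot"` or `"nucl"`.
#' @param model A [precursor_model()].
#' @return A hits data.frame as in [find_msdin_precursors()].
#' @export
mine_fasta <- function(path, type = c("auto", "prot", "nucl"),
                       model = precursor_model()) {
  type <- match.arg(type)
  raw <- Biostrings::readBStringSet(path)
  seqs <- toupper(as.character(raw))
  if (is.null(names(seqs))) names(seqs) <- paste0("seq", seq_along(seqs))
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (type == "auto") {
    nt_frac <- vapply(seqs, function(s) {
      ch <- strsplit(s, "")[[1]]
      if (!length(ch)) return(1)
      mean(ch %in% c("A", "C", "G", "T", "N"))
    }, 0)
    type <- if (all(nt_frac >= 0.99)) "nucl" else "prot"
  }
  if (type == "prot") return(find_msdin_precursors(seqs, model))
  rows <- list(.empty_hits())
  for (id in names(seqs)) {
    L <- nchar(seqs[[id]])
    frames <- translate_six_frames(seqs[[id]])
    for (fr in names(frames)) {
      if (!nzchar(frames[[fr]])) next
      h <- find_msdin_precursors(stats::setNames(frames[fr], id), model)
      if (nrow(h) == 0L) next
      h$frame <- fr
      nt <- t(mapply(function(a, b) .nt_interval(fr, a, b, L), h$start, h$end))
      h$nt_start <- as.integer(nt[, 1])
      h$nt_end <- as.integer(nt[, 2])
      rows[[length(rows) + 1L]] <- h
    }
  }
  hits <- do.call(rbind, rows)
  hits <- hits[order(hits$source_id, hits$frame, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Deduplicate mined precursors into a census
#'
#' Groups hits by core peptide (`key = "core"`, the family-level count) or
#' by the full leader+core+follower sequence (`key = "full_sequence"`).
#'
#' @param hits A hits data.frame from [find_msdin_precursors()].
#' @param key Grouping key.
#' @return An object of class `msdin_census`: the hits with a
#'   `duplicate_group` column, the unique cores, and per-group copy counts.
#' @examples
#' census <- deduplicate(find_msdin_precursors(msdin_precursor_seqs()))
#' length(census$unique_cores)  # 17
#' @export
deduplicate <- function(hits, key = c("core", "full_sequence")) {
  key <- match.arg(key)
  keyval <- if (key == "core") hits$core else
    paste0(hits$leader, hits$core, hits$follower)
  groups <- if (nrow(hits)) match(keyval, unique(keyval)) else integer(0)
  hits$duplicate_group <- groups
  cores <- unique(hits$core)
  core_counts <- if (nrow(hits))
    as.data.frame(table(core = hits$core), stringsAsFactors = FALSE) else
    data.frame(core = character(0), Freq = integer(0))
  names(core_counts)[2] <- "n_copies"
  structure(list(
    precursors = hits,
    key = key,
    n_precursors = nrow(hits),
    n_groups = length(unique(groups)),
    unique_cores = cores,
    cores = core_counts,
    catalogue = NULL,
    novel_cores = NULL
  ), class = "msdin_census")
}

#' Classify census cores as known or novel
#'
#' @param census An `msdin_census`.
#' @param catalogue Named character vector mapping known core sequences to
#'   annotations; defaults to [default_core_catalogue()].
#' @return The census with `catalogue`, `novel_cores` and a `label` column
#'   on `$cores` filled in.
#' @examples
#' census <- deduplicate(find_msdin_precursors(msdin_precursor_seqs()))
#' census <- classify_cores(census)
#' length(census$novel_cores)  # 14
#' @export
classify_cores <- function(census, catalogue = default_core_catalogue()) {
  stopifnot(inherits(census, "msdin_census"))
  census$catalogue <- catalogue
  census$novel_cores <- setdiff(census$unique_cores, names(catalogue))
  if (nrow(census$cores)) {
    census$cores$label <- ifelse(census$cores$core %in% names(catalogue),
                                 catalogue[census$cores$core], "novel")
  } else {
    census$cores$label <- character(0)
  }
  census
}

#' @export
print.msdin_census <- function(x, ...) {
  cat("<msdin_census> ", x$n_precursors, " precursor(s), ",
      x$n_groups, " group(s) by ", x$key, ", ",
      length(x$unique_cores), " unique core(s)", sep = "")
  if (!is.null(x$novel_cores))
    cat(", ", length(x$novel_cores), " novel", sep = "")
  cat("\n")
  invisible(x)
}

#' Write a census hits table to TSV
#'
#' @param census An `msdin_census` (after [classify_cores()] for labels).
#' @param path Output TSV path.
#' @return Invisibly, the written data.frame.
#' @export
write_census <- function(census, path) {
  stopifnot(inherits(census, "msdin_census"))
  df <- census$precursors
  if (!is.null(census$catalogue)) {
    df$label <- ifelse(df$core %in% names(census$catalogue),
                       census$catalogue[df$core], "novel")
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
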