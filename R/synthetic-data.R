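# Deterministic synthetic fixtures: decoy proteomes with embedded MSDIN
# precursors, intronless nucleotide contigs, MGF spectra with Gaussian ppm
# jitter plus noise peaks, and FPKM tables. Every generator is a pure
# function of its config (the seed fixes all randomness) and returns
# machine-readable ground truth alongside the fixture.

#' Simulation configuration
#'
#' Defaults state the emulated world: the 21 published precursor sequences
#' embedded among uniform-composition decoys, 2 ppm Gaussian m/z jitter,
#' noise peaks uniform over the instrument scan range 500-1700 m/z, and the
#' published 24-row FPKM table.
#'
#' @param seed Integer seed; fixes every generated byte.
#' @param n_decoy_proteins Number of decoy proteins.
#' @param decoy_length_range Length-2 range of decoy protein lengths.
#' @param embedded_precursors Named character vector of precursor proteins
#'   to embed (default [msdin_precursor_seqs()]).
#' @param spectrum_jitter_ppm Gaussian sigma of the m/z error in ppm.
#' @param n_noise_peaks Number of uniform noise peaks per spectrum.
#' @param noise_mz_range Length-2 m/z range of noise peaks.
#' @param contig_length_range Length-2 range of contig lengths (nt).
#' @param background_gc GC content of contig background (0..1).
#' @param fpkm_spec List: `mode = "table1"` (published values) or
#'   `mode = "lognormal"` with `n_genes`, `meanlog`, `sdlog`,
#'   `zero_fraction`.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_decoy_proteins = 100L,
                       decoy_length_range = c(200L, 400L),
                       embedded_precursors = msdin_precursor_seqs(),
                       spectrum_jitter_ppm = 2,
                       n_noise_peaks = 50L,
                       noise_mz_range = c(500, 1700),
                       contig_length_range = c(600L, 1500L),
                       background_gc = 0.5,
                       fpkm_spec = list(mode = "table1")) {
  stopifnot(spectrum_jitter_ppm >= 0, n_noise_peaks >= 0,
            length(noise_mz_range) == 2L,
            noise_mz_range[1] < noise_mz_range[2],
            background_gc > 0, background_gc < 1)
  structure(list(seed = as.integer(seed),
                 n_decoy_proteins = as.integer(n_decoy_proteins),
                 decoy_length_range = as.integer(decoy_length_range),
                 embedded_precursors = embedded_precursors,
                 spectrum_jitter_ppm = spectrum_jitter_ppm,
                 n_noise_peaks = as.integer(n_noise_peaks),
                 noise_mz_range = noise_mz_range,
                 contig_length_range = as.integer(contig_length_range),
                 background_gc = background_gc,
                 fpkm_spec = fpkm_spec),
            class = "sim_config")
}

.random_protein <- function(len) {
  paste(sample(.AA_ALPHABET, len, replace = TRUE), collapse = "")
}

#' Generate a decoy proteome with embedded MSDIN precursors
#'
#' Decoy proteins draw residues uniformly from the 20-letter alphabet. Each
#' configured precursor is spliced into a distinct random host at a random
#' position, flanked by stop characters (`*`) on both sides so that the
#' precursor forms a complete between-stops window, as it would in a
#' six-frame translation of its gene.
#'
#' @param config A [sim_config()].
#' @return A list with `fasta` (named character vector of proteins) and
#'   `truth` (data.frame: `protein_id`, `precursor_id`, `start`
#'   0-based position of the precursor Met, `leader`, `core`, `follower`).
#' @export
make_proteome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_decoy_proteins
  lens <- sample(config$decoy_length_range[1]:config$decoy_length_range[2],
                 n, replace = TRUE)
  prots <- vapply(lens, .random_protein, "")
  names(prots) <- sprintf("decoy%03d", seq_len(n))
  prec <- config$embedded_precursors
  if (length(prec) > n)
    stop("need at least as many decoy proteins as embedded precursors")
  truth <- NULL
  if (length(prec)) {
    hosts <- sample(seq_len(n), length(prec))
    rows <- vector("list", length(prec))
    for (i in seq_along(prec)) {
      p <- prec[[i]]
      insert <- paste0("*", p, "*")
      host <- hosts[i]
      hlen <- nchar(prots[[host]])
      if (nchar(insert) > hlen)
        stop("embedded precursor longer than host protein")
      pos <- sample.int(hlen - nchar(insert) + 1L, 1L)  # 1-based
      prots[[host]] <- paste0(substr(prots[[host]], 1L, pos - 1L), insert,
                              substr(prots[[host]], pos + nchar(insert), hlen))
      rows[[i]] <- data.frame(
        protein_id = names(prots)[host],
        precursor_id = if (is.null(names(prec))) paste0("prec", i) else names(prec)[i],
        start = pos,            # 0-based: pos-1 is the '*', pos is the Met
        sequence = p, stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, rows)
  } else {
    truth <- data.frame(protein_id = character(0), precursor_id = character(0),
                        start = integer(0), sequence = character(0),
                        stringsAsFactors = FALSE)
  }
  list(fasta = prots, truth = truth)
}

.CODONS_BY_AA <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), gc)
})

.reverse_complement <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

.random_dna <- function(len, gc) {
  probs <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(probs), len, replace = TRUE, prob = probs), collapse = "")
}

#' Generate nucleotide contigs carrying intronless precursor genes
#'
#' Each precursor is reverse-translated with random synonymous codons,
#' flanked by in-frame TAA stop codons, and inserted into a random-GC
#' background on a random strand. The precursor then appears intact in
#' exactly one of the six translation frames.
#'
#' @param config A [sim_config()].
#' @return A list with `fasta` (named character vector of contigs) and
#'   `truth` (data.frame: `contig_id`, `precursor_id`, `strand`, `frame`,
#'   `nt_start` 0-based forward-strand start of the inserted cassette,
#'   `sequence`).
#' @export
make_contigs <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1L)
  prec <- config$embedded_precursors
  contigs <- character(0)
  rows <- vector("list", length(prec))
  for (i in seq_along(prec)) {
    p <- prec[[i]]
    aa <- strsplit(p, "")[[1]]
    codons <- vapply(aa, function(a) {
      opts <- .CODONS_BY_AA[[a]]
      opts[sample.int(length(opts), 1L)]
    }, "")
    cassette <- paste0("TAA", paste(codons, collapse = ""), "TAA")
    L <- sample(config$contig_length_range[1]:config$contig_length_range[2], 1L)
    L <- max(L, nchar(cassette) + 60L)
    strand <- sample(c("+", "-"), 1L)
    insert_fwd <- if (strand == "+") cassette else .reverse_complement(cassette)
    bg <- .random_dna(L, config$background_gc)
    pos <- sample.int(L - nchar(insert_fwd) + 1L, 1L)  # 1-based
    contig <- paste0(substr(bg, 1L, pos - 1L), insert_fwd,
                     substr(bg, pos + nchar(insert_fwd), L))
    p0 <- pos - 1L  # 0-based forward start of cassette
    if (strand == "+") {
      m0 <- p0 + 3L
      frame <- sprintf("+%d", (m0 %% 3L) + 1L)
    } else {
      r0 <- nchar(contig) - (p0 + nchar(insert_fwd))  # cassette start in revcomp
      m0 <- r0 + 3L
      frame <- sprintf("-%d", (m0 %% 3L) + 1L)
    }
    id <- sprintf("contig%03d", i)
    contigs[[id]] <- contig
    rows[[i]] <- data.frame(
      contig_id = id,
      precursor_id = if (is.null(names(prec))) paste0("prec", i) else names(prec)[i],
      strand = strand, frame = frame, nt_start = p0, sequence = p,
      stringsAsFactors = FALSE)
  }
  truth <- if (length(rows)) do.call(rbind, rows) else
    data.frame(contig_id = character(0), precursor_id = character(0),
               strand = character(0), frame = character(0),
               nt_start = integer(0), sequence = character(0),
               stringsAsFactors = FALSE)
  list(fasta = contigs, truth = truth)
}

#' Published MS/MS annotation presets
#'
#' Ion subsets (as `kind:composition` selectors) emulating the manually
#' annotated daughter-ion sets of the two novel cyclic peptides:
#' * `cylk1` (cyclo(GFGFIP)): Ile and Phe immonium ions plus the six
#'   annotated y-type arcs (the published "GGI" label is not a contiguous
#'   arc of the cycle and is excluded).
#' * `cylk2` (cyclo(GKVNPP)): the 11 matched ions — Pro immonium, seven
#'   y-type arcs and the three NH3-loss variants of the Lys-containing
#'   arcs. The published "KPP" label is, like "GGI", not a contiguous arc
#'   of the cycle ({K,P,P} cannot be contiguous in G-K-V-N-P-P); the arc
#'   model's corresponding predicted ion is the arc N-P-P, so the preset
#'   carries `y:NPP` as the seventh y-type ion.
#'
#' @param name `"cylk1"` or `"cylk2"`.
#' @return Character vector of ion selectors.
#' @export
ion_preset <- function(name = c("cylk1", "cylk2")) {
  name <- match.arg(name)
  switch(name,
    cylk1 = c("immonium:I", "immonium:F", "y:GP", "y:GF", "y:GFP",
              "y:GFPIG", "y:GFPIF", "y:GFPFG"),
    cylk2 = c("immonium:P", "y:GP", "y:GK", "y:GKP", "y:NPP", "y:GPPN",
              "y:GKPP", "y:GKPPN", "y-NH3:GK", "y-NH3:GKP", "y-NH3:GKPP"))
}

.sorted_chars <- function(s) paste(sort(strsplit(s, "")[[1]]), collapse = "")

# resolve "kind:composition" selectors against a library (compositional
# match: arc labels are unordered residue multisets)
.select_ions <- function(library, selectors) {
  ions <- library$ions
  comp <- vapply(ions$subsequence, .sorted_chars, "")
  idx <- vapply(selectors, function(sel) {
    parts <- strsplit(sel, ":", fixed = TRUE)[[1]]
    if (length(parts) != 2L) stop("bad ion selector: ", sel)
    hit <- which(ions$kind == parts[1] & comp == .sorted_chars(parts[2]))
    if (!length(hit))
      stop("requested ion absent from library: ", sel)
    hit[1]
  }, 0L)
  ions[idx, , drop = FALSE]
}

#' Generate synthetic MS/MS spectra for cyclic cores
#'
#' One spectrum per core: the precursor at the theoretical `[M+H]+` and a
#' subset of library ions as peaks, all with Gaussian ppm jitter, plus
#' uniform noise peaks over the scan range. True-ion intensities are drawn
#' uniform on [0.2, 1], noise on [0, 0.1] (intensities are cosmetic: the
#' matcher does not use them by default).
#'
#' @param cores Character vector of core sequences.
#' @param config A [sim_config()].
#' @param ion_spec `NULL` (use every non-precursor library ion), a
#'   character vector of `kind:composition` selectors applied to every
#'   core, or a named list of such vectors keyed by core sequence (see
#'   [ion_preset()]).
#' @return A list with `spectra` (list of `spectrum` objects) and `truth`
#'   (data.frame: `spectrum_id`, `core`, `n_true_ions`, `true_labels`).
#' @export
make_spectra <- function(cores, config = sim_config(), ion_spec = NULL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2L)
  sigma <- config$spectrum_jitter_ppm
  jitter <- function(mz) mz * (1 + stats::rnorm(length(mz), 0, sigma) * 1e-6)
  spectra <- list()
  rows <- vector("list", length(cores))
  for (i in seq_along(cores)) {
    core <- cores[i]
    lib <- build_library(core)
    sel <- if (is.null(ion_spec)) {
      lib$ions[!startsWith(lib$ions$kind, "precursor"), , drop = FALSE]
    } else if (is.list(ion_spec)) {
      .select_ions(lib, ion_spec[[core]])
    } else {
      .select_ions(lib, ion_spec)
    }
    true_mz <- jitter(sel$mz)
    true_int <- stats::runif(nrow(sel), 0.2, 1.0)
    noise_mz <- stats::runif(config$n_noise_peaks, config$noise_mz_range[1],
                             config$noise_mz_range[2])
    noise_int <- stats::runif(config$n_noise_peaks, 0, 0.1)
    id <- sprintf("sim_%s", core)
    spectra[[id]] <- spectrum(
      id,
      precursor_mz = jitter(lib$precursor_mz),
      peaks = data.frame(mz = c(true_mz, noise_mz),
                         intensity = c(true_int, noise_int)),
      charge = 1L)
    rows[[i]] <- data.frame(spectrum_id = id, core = core,
                            n_true_ions = nrow(sel),
                            true_labels = paste(sel$label, collapse = ","),
                            stringsAsFactors = FALSE)
  }
  list(spectra = spectra,
       truth = do.call(rbind, c(list(data.frame()), rows)))
}

#' Generate an FPKM table
#'
#' `mode = "table1"` (default) returns the published 24-row table verbatim;
#' `mode = "lognormal"` draws `n_genes` FPKM values from a log-normal
#' distribution with a configurable point mass at zero.
#'
#' @param config A [sim_config()].
#' @return A list with `table` (data.frame `gene_id`, `class`, `fpkm`) and
#'   `truth` (the generating parameters).
#' @export
make_fpkm_table <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  spec <- config$fpkm_spec
  if (identical(spec$mode, "table1")) {
    return(list(table = ref_expression_table(),
                truth = list(mode = "table1")))
  }
  if (!identical(spec$mode, "lognormal"))
    stop("unknown fpkm_spec mode: ", spec$mode)
  set.seed(config$seed + 3L)
  n <- if (is.null(spec$n_genes)) 1000L else as.integer(spec$n_genes)
  meanlog <- if (is.null(spec$meanlog)) 0 else spec$meanlog
  sdlog <- if (is.null(spec$sdlog)) 2 else spec$sdlog
  zf <- if (is.null(spec$zero_fraction)) 0 else spec$zero_fraction
  fpkm <- stats::rlnorm(n, meanlog, sdlog)
  zero <- stats::runif(n) < zf
  fpkm[zero] <- 0
  list(table = data.frame(gene_id = sprintf("gene%05d", seq_len(n)),
                          class = "other", fpkm = fpkm,
                          stringsAsFactors = FALSE),
       truth = list(mode = "lognormal", n_genes = n, meanlog = meanlog,
                    sdlog = sdlog, zero_fraction = zf))
}

#' Write sequences as FASTA (deterministic, 60-column wrap)
#'
#' @param seqs Named character vector.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(seqs, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (id in names(seqs)) {
    writeLines(paste0(">", id), con)
    s <- seqs[[id]]
    starts <- seq(1L, nchar(s), by = 60L)
    writeLines(substring(s, starts, pmin(starts + 59L, nchar(s))), con)
  }
  invisible(path)
}

#' Write spectra as MGF
#'
#' @param spectra List of `spectrum` objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", sp$id),
                 paste0("PEPMASS=", sprintf("%.6f", sp$precursor_mz)),
                 paste0("CHARGE=", sp$charge, "+")), con)
    if (nrow(sp$peaks))
      writeLines(sprintf("%.6f %.6f", sp$peaks$mz, sp$peaks$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(path)
}

#' Write an expression table as TSV
#'
#' @param table Data.frame with `gene_id`, `class`, `fpkm`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_expression_table <- function(table, path) {
  out <- table
  out$fpkm <- sprintf("%.2f", out$fpkm)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
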