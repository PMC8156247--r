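# Expression-tier classification of MSDIN and pathway genes from a
# gene-level FPKM table. FPKM values are consumed as input (transcript
# quantification itself is upstream of this package).

#' Load a gene-level FPKM table
#'
#' Expects a TSV with header columns `gene_id`, `class`, `fpkm`, where
#' `class` is a core peptide sequence for MSDIN genes or a gene-class label
#' (`POPB`, `POPA`, `rbp2`, ...) otherwise.
#'
#' @param path Path to the TSV file.
#' @return A data.frame of expression records.
#' @export
load_expression_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("empty expression table (no header)")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  need <- c("gene_id", "class", "fpkm")
  if (!all(need %in% header))
    stop("expression table header must contain: ", paste(need, collapse = ", "))
  body <- lines[-1]
  body <- body[nzchar(trimws(body))]
  if (!length(body))
    return(data.frame(gene_id = character(0), class = character(0),
                      fpkm = numeric(0), stringsAsFactors = FALSE))
  parts <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf != length(header))
  if (length(bad))
    stop("malformed row at line ", bad[1] + 1L, ": expected ",
         length(header), " fields, got ", nf[bad[1]])
  mat <- do.call(rbind, parts)
  colnames(mat) <- header
  fpkm <- suppressWarnings(as.numeric(mat[, "fpkm"]))
  badv <- which(is.na(fpkm))
  if (length(badv))
    stop("non-numeric fpkm at line ", badv[1] + 1L)
  negv <- which(fpkm < 0)
  if (length(negv))
    stop("negative fpkm at line ", negv[1] + 1L)
  ids <- mat[, "gene_id"]
  if (anyDuplicated(ids))
    stop("duplicate gene_id: ", ids[duplicated(ids)][1])
  data.frame(gene_id = ids, class = mat[, "class"], fpkm = fpkm,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Expression tier scheme
#'
#' The default scheme follows the published boundaries: `zero`
#' (FPKM = 0), `low` (0 < FPKM < 1), `mid` (1 <= FPKM <= 100) and `high`
#' (FPKM > 100). Only the `< 1` and `> 100` boundaries are stated
#' explicitly in the source study; the mid tier fills the gap and the
#' boundaries are configurable.
#'
#' @param low_upper Upper boundary of the low tier (exclusive; default 1).
#' @param high_lower Lower boundary of the high tier (exclusive from above;
#'   default 100).
#' @param labels Tier labels, low to high.
#' @return An object of class `tier_scheme`.
#' @export
tier_scheme <- function(low_upper = 1, high_lower = 100,
                        labels = c("zero", "low", "mid", "high")) {
  stopifnot(low_upper > 0, high_lower >= low_upper, length(labels) == 4L)
  structure(list(low_upper = low_upper, high_lower = high_lower,
                 labels = labels),
            class = "tier_scheme")
}

#' Assign a tier label to FPKM values
#'
#' @param fpkm Numeric vector of FPKM values (>= 0).
#' @param scheme A [tier_scheme()].
#' @return Factor of tier labels (levels low to high).
#' @export
tier_of <- function(fpkm, scheme = tier_scheme()) {
  stopifnot(inherits(scheme, "tier_scheme"), all(fpkm >= 0))
  lab <- ifelse(fpkm == 0, scheme$labels[1],
         ifelse(fpkm < scheme$low_upper, scheme$labels[2],
         ifelse(fpkm <= scheme$high_lower, scheme$labels[3],
                scheme$labels[4])))
  factor(lab, levels = scheme$labels)
}

#' Classify expression records into tiers
#'
#' Every record falls into exactly one tier (the tiers partition
#' `[0, Inf)`).
#'
#' @param records Expression data.frame (needs an `fpkm` column).
#' @param scheme A [tier_scheme()].
#' @return A list with `records` (input plus a `tier` column), `tiers`
#'   (named list of per-tier data.frames) and `counts` (named integer
#'   vector).
#' @examples
#' tier_classify(ref_expression_table())$counts
#' @export
tier_classify <- function(records, scheme = tier_scheme()) {
  records$tier <- tier_of(records$fpkm, scheme)
  tiers <- split(records, records$tier)
  counts <- vapply(tiers, nrow, integer(1))
  list(records = records, tiers = tiers, counts = counts)
}

#' Ratio of FPKM values between two gene classes
#'
#' @param records Expression data.frame with `class` and `fpkm` columns.
#' @param numerator_class,denominator_class Gene-class labels; each must
#'   match exactly one record (or the per-class sum is used when several
#'   match).
#' @return The FPKM ratio (numerator / denominator).
#' @examples
#' expression_ratio(ref_expression_table(), "POPB", "POPA")  # ~25.5
#' @export
expression_ratio <- function(records, numerator_class, denominator_class) {
  num <- records$fpkm[records$class == numerator_class]
  den <- records$fpkm[records$class == denominator_class]
  if (!length(num)) stop("class not found: ", numerator_class)
  if (!length(den)) stop("class not found: ", denominator_class)
  num <- sum(num); den <- sum(den)
  if (den == 0) stop("denominator class '", denominator_class,
                     "' has zero FPKM")
  num / den
}

#' Join a mined census with expression records
#'
#' Summarizes expression per unique core: copies of the same core (class =
#' core sequence) are collapsed by maximum FPKM (per-copy values remain in
#' the expression table). Cores without expression data get `NA` FPKM and
#' tier `"unknown"`.
#'
#' @param census An `msdin_census` (ideally after [classify_cores()]).
#' @param records Expression data.frame whose `class` column holds core
#'   sequences for MSDIN genes.
#' @param scheme A [tier_scheme()].
#' @return A data.frame with columns `core`, `n_copies`, `fpkm_max`,
#'   `tier`, `label`, plus attributes `fpkm_range` (over matched MSDIN
#'   records) and `unmatched_cores`.
#' @export
census_expression_join <- function(census, records, scheme = tier_scheme()) {
  stopifnot(inherits(census, "msdin_census"))
  cores <- census$cores
  fpkm_max <- vapply(cores$core, function(cc) {
    v <- records$fpkm[records$class == cc]
    if (length(v)) max(v) else NA_real_
  }, 0)
  tier <- ifelse(is.na(fpkm_max), "unknown",
                 as.character(tier_of(ifelse(is.na(fpkm_max), 0, fpkm_max), scheme)))
  label <- if (!is.null(census$catalogue)) {
    ifelse(cores$core %in% names(census$catalogue),
           census$catalogue[cores$core], "novel")
  } else NA_character_
  out <- data.frame(core = cores$core, n_copies = cores$n_copies,
                    fpkm_max = fpkm_max, tier = tier, label = label,
                    row.names = NULL, stringsAsFactors = FALSE)
  matched <- records$fpkm[records$class %in% cores$core]
  attr(out, "fpkm_range") <- if (length(matched)) range(matched) else
    c(NA_real_, NA_real_)
  attr(out, "unmatched_cores") <- out$core[is.na(out$fpkm_max)]
  out
}
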