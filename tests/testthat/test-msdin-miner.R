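test_that("six-frame translation basics", {
  fr <- translate_six_frames("ATGTCA")
  expect_equal(fr[["+1"]], "MS")
  expect_equal(fr[["+2"]], "C")  # TGT CA. -> C
  expect_error(translate_six_frames("ATGU"), "position 4")
  # frame -1 equals frame +1 of the manual reverse complement
  set.seed(21)
  dna <- paste(sample(c("A", "C", "G", "T"), 90, replace = TRUE), collapse = "")
  rc <- paste(rev(strsplit(chartr("ACGT", "TGCA", dna), "")[[1]]), collapse = "")
  expect_equal(translate_six_frames(dna)[["-1"]],
               translate_six_frames(rc)[["+1"]])
})

test_that("the 21 published precursors decompose row-for-row", {
  t1 <- msdin_table1()
  hits <- find_msdin_precursors(msdin_precursor_seqs())
  expect_equal(nrow(hits), 21L)
  h <- hits[match(t1$gene_id, hits$source_id), ]
  expect_equal(h$leader, t1$leader)
  expect_equal(h$core, t1$core)
  expect_equal(h$follower, t1$follower)
  expect_true(all(h$start == 0L))
  expect_equal(h$end, nchar(t1$leader) + nchar(t1$core) + nchar(t1$follower))
  # reconstruction invariant
  expect_equal(paste0(h$leader, h$core, h$follower),
               unname(msdin_precursor_seqs()[t1$gene_id]))
})

test_that("internal follower-pattern look-alikes are rejected by follower length", {
  # the internal Cys of IWGIGCNP would imply a 20-aa follower
  hits <- find_msdin_precursors(c(x = "MSDINATRLPIWGIGCNPCVGDDVTTLLTRGEALC"))
  expect_equal(hits$core, "IWGIGCNP")
  expect_equal(nchar(hits$follower), 17L)
})

test_that("no hits without Met or leader match", {
  expect_equal(nrow(find_msdin_precursors(c(a = "GAVLIFPWSTCYNQDEKRH"))), 0L)
  expect_equal(nrow(find_msdin_precursors(
    c(a = "AAAAAGFGFIPYASGDVDYTLTRGESLS"))), 0L)
})

test_that("deduplication: 17 cores, 18 full sequences from the 21 rows", {
  hits <- find_msdin_precursors(msdin_precursor_seqs())
  by_core <- deduplicate(hits, key = "core")
  expect_equal(by_core$n_precursors, 21L)
  expect_equal(by_core$n_groups, 17L)
  expect_equal(length(by_core$unique_cores), 17L)
  by_full <- deduplicate(hits, key = "full_sequence")
  expect_equal(by_full$n_groups, 18L)
  empty <- deduplicate(find_msdin_precursors(c(a = "PPPPP")))
  expect_equal(empty$n_precursors, 0L)
  expect_equal(length(empty$unique_cores), 0L)
})

test_that("core classification against the known-core catalogue", {
  census <- deduplicate(find_msdin_precursors(msdin_precursor_seqs()))
  cls <- classify_cores(census)
  expect_equal(length(cls$novel_cores), 14L)
  all_known <- classify_cores(census,
                              stats::setNames(census$unique_cores,
                                              census$unique_cores))
  expect_equal(length(all_known$novel_cores), 0L)
  none_known <- classify_cores(census, character(0))
  expect_equal(length(none_known$novel_cores), 17L)
  expect_equal(sum(cls$cores$label == "novel"), 14L)
})

test_that("output order is (source_id, start) regardless of input order", {
  seqs <- msdin_precursor_seqs()
  shuffled <- seqs[rev(seq_along(seqs))]
  a <- find_msdin_precursors(seqs)
  b <- find_msdin_precursors(shuffled)
  expect_identical(a, b)
  expect_false(is.unsorted(a$source_id))
})

test_that("recovery on synthetic proteomes over 20 seeds, zero decoy hits", {
  model <- precursor_model()
  for (seed in 1:20) {
    cfg <- sim_config(seed = seed, n_decoy_proteins = 30L)
    sim <- make_proteome(cfg)
    hits <- find_msdin_precursors(sim$fasta, model)
    expect_equal(nrow(hits), nrow(sim$truth))
    key_hits <- paste(hits$source_id, hits$start)
    key_truth <- paste(sim$truth$protein_id, sim$truth$start)
    expect_setequal(key_hits, key_truth)
    h <- hits[match(key_truth, key_hits), ]
    expect_equal(paste0(h$leader, h$core, h$follower), sim$truth$sequence)
    # decoys alone are clean
    decoy_only <- make_proteome(sim_config(seed = seed, n_decoy_proteins = 30L,
                                           embedded_precursors = character(0)))
    expect_equal(nrow(find_msdin_precursors(decoy_only$fasta, model)), 0L)
  }
})

test_that("nucleotide mining via FASTA recovers precursors in one frame", {
  cfg <- sim_config(seed = 5, embedded_precursors = msdin_precursor_seqs()[1:4])
  sim <- make_contigs(cfg)
  path <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(sim$fasta, path)
  hits <- mine_fasta(path, type = "auto")
  expect_equal(nrow(hits), 4L)
  h <- hits[match(sim$truth$contig_id, hits$source_id), ]
  expect_equal(h$frame, sim$truth$frame)
  expect_equal(paste0(h$leader, h$core, h$follower), sim$truth$sequence)
  # the recovered nucleotide interval re-translates to the precursor
  for (i in seq_len(nrow(h))) {
    nt <- substr(sim$fasta[[h$source_id[i]]], h$nt_start[i] + 1L, h$nt_end[i])
    if (startsWith(h$frame[i], "-"))
      nt <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(nt)))
    aa <- as.character(Biostrings::translate(Biostrings::DNAString(nt)))
    expect_equal(aa, sim$truth$sequence[i])
  }
})

test_that("a stop codon mid-precursor kills recovery", {
  p <- msdin_precursor_seqs()[1]
  broken <- paste0(substr(p, 1, 15), "*", substr(p, 16, nchar(p)))
  expect_equal(nrow(find_msdin_precursors(c(x = broken))), 0L)
})
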