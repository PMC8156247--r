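test_that("generators are byte-identical under a fixed seed", {
  cfg <- sim_config(seed = 42, n_decoy_proteins = 25L,
                    embedded_precursors = msdin_precursor_seqs()[1:3])
  a <- make_proteome(cfg); b <- make_proteome(cfg)
  expect_identical(a, b)
  pa <- tempfile(); pb <- tempfile()
  write_fasta(a$fasta, pa); write_fasta(b$fasta, pb)
  expect_identical(readLines(pa), readLines(pb))

  ca <- make_contigs(cfg); cb <- make_contigs(cfg)
  expect_identical(ca, cb)

  sa <- make_spectra("GKVNPP", cfg); sb <- make_spectra("GKVNPP", cfg)
  ma <- tempfile(); mb <- tempfile()
  write_mgf(sa$spectra, ma); write_mgf(sb$spectra, mb)
  expect_identical(readLines(ma), readLines(mb))

  # different seeds: different decoys, identical embedded decompositions
  other <- make_proteome(sim_config(seed = 43, n_decoy_proteins = 25L,
                                    embedded_precursors = msdin_precursor_seqs()[1:3]))
  expect_false(identical(a$fasta, other$fasta))
  expect_identical(a$truth$sequence, other$truth$sequence)
})

test_that("proteome: full 21-precursor embedding is recovered by the miner", {
  sim <- make_proteome(sim_config(seed = 2))
  expect_equal(nrow(sim$truth), 21L)
  hits <- find_msdin_precursors(sim$fasta)
  expect_equal(nrow(hits), 21L)
  expect_setequal(paste(hits$source_id, hits$start),
                  paste(sim$truth$protein_id, sim$truth$start))
  none <- make_proteome(sim_config(seed = 2, embedded_precursors = character(0)))
  expect_equal(nrow(none$truth), 0L)
  expect_equal(nrow(find_msdin_precursors(none$fasta)), 0L)
})

test_that("proteome embedding errors when the insert cannot fit", {
  cfg <- sim_config(seed = 3, n_decoy_proteins = 1L,
                    decoy_length_range = c(10L, 10L),
                    embedded_precursors = msdin_precursor_seqs()[1])
  expect_error(make_proteome(cfg), "longer than host")
})

test_that("contigs: each precursor sits in exactly one frame", {
  cfg <- sim_config(seed = 6, embedded_precursors = msdin_precursor_seqs()[1:5])
  sim <- make_contigs(cfg)
  for (i in seq_len(nrow(sim$truth))) {
    frames <- translate_six_frames(sim$fasta[[sim$truth$contig_id[i]]])
    containing <- names(frames)[vapply(frames, function(f)
      grepl(sim$truth$sequence[i], f, fixed = TRUE), TRUE)]
    expect_equal(containing, sim$truth$frame[i])
  }
  # background GC stays near the configured value
  gc_cfg <- sim_config(seed = 7, embedded_precursors = character(0),
                       background_gc = 0.4)
  dna <- msdintools:::.random_dna(20000, 0.4)
  chars <- strsplit(dna, "")[[1]]
  expect_equal(mean(chars %in% c("G", "C")), 0.4, tolerance = 0.02)
})

test_that("spectra: jittered true ions stay inside the matching window", {
  cfg <- sim_config(seed = 8, spectrum_jitter_ppm = 2)
  sim <- make_spectra("GKVNPP", cfg, ion_spec = ion_preset("cylk2"))
  lib <- build_library("GKVNPP")
  ann <- annotate_fragments(sim$spectra[[1]], lib, tol_ppm = 10)
  expect_equal(ann$n_matched, sim$truth$n_true_ions)
  expect_error(make_spectra("GKVNPP", cfg, ion_spec = "y:WW"), "absent")
})

test_that("fpkm table: default reproduces the published tier counts", {
  sim <- make_fpkm_table(sim_config())
  expect_identical(sim$table, ref_expression_table())
  cls <- tier_classify(sim$table[1:21, ])
  expect_equal(unname(cls$counts[["high"]]), 2L)
  allzero <- make_fpkm_table(sim_config(fpkm_spec = list(
    mode = "lognormal", n_genes = 40, zero_fraction = 1)))
  expect_true(all(allzero$table$fpkm == 0))
})

test_that("fpkm table: log-normal tier counts match analytic tail probabilities", {
  meanlog <- 0; sdlog <- 2; n <- 200L; reps <- 200L
  p_high <- stats::pnorm((log(100) - meanlog) / sdlog, lower.tail = FALSE)
  p_low <- stats::pnorm((log(1) - meanlog) / sdlog)
  highs <- lows <- numeric(reps)
  for (r in seq_len(reps)) {
    sim <- make_fpkm_table(sim_config(seed = 1000L + r, fpkm_spec = list(
      mode = "lognormal", n_genes = n, meanlog = meanlog, sdlog = sdlog)))
    cls <- tier_classify(sim$table)
    highs[r] <- sum(cls$counts[["high"]])
    lows[r] <- sum(cls$counts[["low"]])
  }
  # mean counts within 5 binomial standard errors of the expectation
  se <- function(p) sqrt(n * p * (1 - p) / reps)
  expect_lt(abs(mean(highs) - n * p_high), 5 * se(p_high))
  expect_lt(abs(mean(lows) - n * p_low), 5 * se(p_low))
})
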