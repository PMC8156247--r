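make_mgf_fixture <- function(path) {
  writeLines(c(
    "BEGIN IONS",
    "TITLE=cylk1_ms1",
    "PEPMASS=619.3244 12345.6",
    "CHARGE=1+",
    "120.0808 10.0",
    "86.0967 8.0",
    "70.0651 1.5",
    "END IONS",
    "",
    "BEGIN IONS",
    "PEPMASS=920.3465",
    "500.1 1.0",
    "300.2 2.0",
    "700.3 0.5",
    "END IONS"), path)
  path
}

test_that("read_mgf parses blocks, defaults and sorts peaks", {
  path <- withr::local_tempfile(fileext = ".mgf")
  spectra <- read_mgf(make_mgf_fixture(path))
  expect_length(spectra, 2L)
  expect_equal(spectra[[1]]$id, "cylk1_ms1")
  expect_equal(spectra[[1]]$precursor_mz, 619.3244)
  expect_equal(spectra[[1]]$charge, 1L)
  expect_equal(nrow(spectra[[1]]$peaks), 3L)
  expect_false(is.unsorted(spectra[[2]]$peaks$mz))  # unsorted input sorted
  expect_equal(spectra[[2]]$charge, 1L)             # missing CHARGE -> 1+

  empty <- withr::local_tempfile(fileext = ".mgf")
  writeLines(character(0), empty)
  expect_length(read_mgf(empty), 0L)

  bad <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "PEPMASS=100", "oops peak"), bad)
  expect_error(read_mgf(bad), "line")
})

test_that("read_peaklist parses the PRECURSOR header dialect", {
  path <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("PRECURSOR 619.3244 1", "120.0808 10", "86.0967 8"), path)
  sp <- read_peaklist(path)
  expect_equal(sp$precursor_mz, 619.3244)
  expect_equal(nrow(sp$peaks), 2L)
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("120.0808 10"), bad)
  expect_error(read_peaklist(bad), "PRECURSOR")
})

test_that("precursor screening within ppm tolerance", {
  cands <- candidate_mass_list(unique(msdin_table1()$core))
  sp <- spectrum("s1", 619.3244, data.frame(mz = numeric(0), intensity = numeric(0)))
  hit <- screen_precursors(sp, cands, tol_ppm = 5)
  expect_equal(hit$core, "GFGFIP")
  # screening works at full precision; the printed 0.8073 ppm refers to the
  # 4-decimal rounded theoretical value (reproduced exactly in test-chem-core)
  expect_lt(abs(hit$ppm - 0.8073), 0.1)
  # beyond tolerance: nothing
  expect_equal(nrow(screen_precursors(sp, cands, tol_ppm = 0.5)), 0L)
  far <- spectrum("s2", 919.3616, data.frame(mz = 1, intensity = 1))
  hits <- screen_precursors(far, cands, tol_ppm = 5)
  expect_equal(hits$modification, "amatoxin")
  expect_equal(hits$core, "IWGIGCNP")
})

test_that("the CylK2 annotation fixture matches exactly 11 library entries", {
  lib <- build_library("GKVNPP")
  sim <- make_spectra("GKVNPP",
                      sim_config(seed = 1, spectrum_jitter_ppm = 0,
                                 n_noise_peaks = 0),
                      ion_spec = ion_preset("cylk2"))
  ann <- annotate_fragments(sim$spectra[[1]], lib)
  expect_equal(ann$n_matched, 11L)
  expect_equal(sum(ann$matches$kind == "immonium"), 1L)
  expect_equal(sum(ann$matches$kind == "y"), 7L)
  expect_equal(sum(ann$matches$kind == "y-NH3"), 3L)
  # with seeded 2 ppm jitter the 11 ions still fall inside the 10 ppm window
  sim2 <- make_spectra("GKVNPP",
                       sim_config(seed = 1, spectrum_jitter_ppm = 2,
                                  n_noise_peaks = 0),
                       ion_spec = ion_preset("cylk2"))
  expect_equal(annotate_fragments(sim2$spectra[[1]], lib)$n_matched, 11L)
})

test_that("empty peak list yields an empty annotation", {
  lib <- build_library("GKVNPP")
  sp <- spectrum("e", lib$precursor_mz,
                 data.frame(mz = numeric(0), intensity = numeric(0)))
  ann <- annotate_fragments(sp, lib)
  expect_equal(ann$n_matched, 0L)
  expect_equal(ann$coverage, 0)
})

test_that("property: n_matched is non-decreasing in the fragment tolerance", {
  lib <- build_library("GFGFIP")
  sim <- make_spectra("GFGFIP",
                      sim_config(seed = 9, spectrum_jitter_ppm = 6,
                                 n_noise_peaks = 20))
  sp <- sim$spectra[[1]]
  counts <- vapply(c(1, 2, 5, 10, 20, 50),
                   function(tol) annotate_fragments(sp, lib, tol_ppm = tol,
                                                    abs_tol_da = 0)$n_matched,
                   0L)
  expect_false(is.unsorted(counts))
})

test_that("noise-only spectra rarely match anything (decoy robustness)", {
  lib <- build_library("GKVNPP")
  set.seed(99)
  total <- 0L
  for (rep in 1:100) {
    noise <- data.frame(mz = runif(50, 500, 1700), intensity = runif(50, 0, 1))
    sp <- spectrum(paste0("noise", rep), 1000, noise)
    total <- total + annotate_fragments(sp, lib, tol_ppm = 10)$n_matched
  }
  # expected false matches per replicate ~1e-3; documented bound
  expect_lte(total, 3L)
})

test_that("round trip: 0-jitter spectra screen to their candidate with ppm 0", {
  cores <- c("GFGFIP", "GKVNPP")
  cands <- candidate_mass_list(cores)
  sim <- make_spectra(cores, sim_config(seed = 4, spectrum_jitter_ppm = 0,
                                        n_noise_peaks = 10))
  screens <- screen_precursors(sim$spectra, cands, tol_ppm = 5)
  expect_equal(nrow(screens), 2L)
  expect_equal(screens$ppm, c(0, 0), tolerance = 1e-9)
  for (sp in sim$spectra) {
    core <- sub("sim_", "", sp$id)
    ann <- annotate_fragments(sp, build_library(core))
    expect_equal(ann$coverage, 1.0)
  }
})

test_that("report has one row per candidate with N/A for misses", {
  cands <- candidate_mass_list(unique(msdin_table1()$core))
  measured <- c("IWGIGCNP/amatoxin" = 919.3616, "IWGIGCDP/amatoxin" = 920.3465,
                "GFGFIP/none" = 619.3244, "GKVNPP/none" = 593.3411)
  spectra <- lapply(seq_along(measured), function(i)
    spectrum(paste0("ms", i), measured[[i]],
             data.frame(mz = numeric(0), intensity = numeric(0))))
  screens <- screen_precursors(spectra, cands, tol_ppm = 5)
  rep <- build_report(screens, cands)
  expect_equal(nrow(rep), nrow(cands))
  expect_equal(sum(!is.na(rep$measured_mz)), 4L)
  expect_equal(sum(is.na(rep$measured_mz)), nrow(cands) - 4L)
  # no spectra -> all N/A
  rep0 <- build_report(screen_precursors(list(), cands), cands)
  expect_true(all(is.na(rep0$measured_mz)))
  # isobaric flag on equal-composition cores
  iso <- candidate_mass_list(c("GKVNPP", "KGVNPP"))
  rep_iso <- build_report(screen_precursors(list(), iso), iso)
  expect_true(all(rep_iso$isobaric))
  # writer renders the N/A convention
  path <- withr::local_tempfile(fileext = ".tsv")
  out <- write_report(rep, path)
  expect_true(any(out$measured_mz == "N/A"))
  expect_equal(sum(out$ppm != "N/A"), 4L)
})
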