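# spectra_io: window-scheme arithmetic, mzML/MGF/FASTA/annotation I/O.

test_that("build_window_scheme partitions the DIA range", {
  s <- build_window_scheme(400, 1000, 15)
  expect_equal(nrow(s$windows), 40)
  expect_equal(unname(unlist(s$windows[1])), c(400, 415))
  expect_equal(unname(unlist(s$windows[40])), c(985, 1000))

  expect_equal(nrow(build_window_scheme(0, 10, 10)$windows), 1)
  trunc <- build_window_scheme(400, 410, 15)
  expect_equal(nrow(trunc$windows), 1)
  expect_equal(unname(unlist(trunc$windows[1])), c(400, 410))

  expect_error(build_window_scheme(400, 1000, 0), "positive")
  expect_error(build_window_scheme(400, 400, 15), "greater")
})

test_that("window scheme covers the range with disjoint half-open windows", {
  set.seed(1)
  for (i in 1:20) {
    start <- runif(1, 100, 500); width <- runif(1, 5, 50)
    end <- start + runif(1, 1, 30) * width
    s <- build_window_scheme(start, end, width)
    w <- s$windows
    expect_equal(w$lower[1], start)
    expect_equal(w$upper[nrow(w)], end)
    if (nrow(w) > 1) {
      expect_equal(w$lower[-1], w$upper[-nrow(w)])  # consecutive, no gaps
      expect_true(all(diff(w$lower) > 0))
    }
  }
  # half-open membership: exact boundary belongs to the upper window
  s <- build_window_scheme(400, 1000, 15)
  expect_equal(window_for_mz(s, c(400, 414.999, 415, 999.999)), c(1L, 1L, 2L, 40L))
  expect_true(is.na(window_for_mz(s, 1000)))
  expect_true(is.na(window_for_mz(s, 399.9)))
})

test_that("mzML round-trip preserves spectra", {
  scheme <- build_window_scheme(400, 430, 15)
  run <- spectra_run("fix", list(
    spectrum_record(1L, 0.0, c(450.1, 500.123456), c(10, 20)),
    spectrum_record(2L, 0.5, c(200.5, 300.25, 400.75), c(1, 2, 3),
                    window = c(400, 415)),
    spectrum_record(2L, 1.0, numeric(0), numeric(0), window = c(415, 430))),
    scheme)
  f <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(run, f)
  back <- read_mzml(f)
  expect_length(back$spectra, 3)
  expect_equal(nrow(back$scheme$windows), 2)
  for (i in 1:3) {
    expect_equal(back$spectra[[i]]$ms_level, run$spectra[[i]]$ms_level)
    expect_equal(back$spectra[[i]]$rt, run$spectra[[i]]$rt, tolerance = 1e-6)
    expect_equal(back$spectra[[i]]$mz, run$spectra[[i]]$mz, tolerance = 1e-4)
    expect_equal(length(back$spectra[[i]]$intensity),
                 length(run$spectra[[i]]$intensity))
  }
  expect_equal(back$spectra[[2]]$window, c(400, 415))
})

test_that("read_mzml rejects profile data, missing windows, bad XML", {
  scheme <- build_window_scheme(400, 430, 15)
  run <- spectra_run("fix", list(
    spectrum_record(1L, 0, 500, 10),
    spectrum_record(2L, 1, 250, 5, window = c(400, 415))), scheme)
  f <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(run, f)

  txt <- readLines(f)
  # strip the isolation window metadata
  drop <- grep("isolationWindow|precursor", txt)
  writeLines(txt[-drop], f2 <- withr::local_tempfile(fileext = ".mzML"))
  expect_error(read_mzml(f2), "isolation-window")

  # mark spectra as profile mode
  prof <- sub('accession="MS:1000127" name="centroid spectrum"',
              'accession="MS:1000128" name="profile spectrum"', txt)
  writeLines(prof, f3 <- withr::local_tempfile(fileext = ".mzML"))
  expect_error(read_mzml(f3), "centroid required")

  writeLines(c(txt[1:5], "<<<not xml"), f4 <- withr::local_tempfile(fileext = ".mzML"))
  expect_error(read_mzml(f4), "malformed")

  # RT in minutes is converted to seconds
  mins <- sub('value="1.000000" unitCvRef="UO" unitAccession="UO:0000010" unitName="second"',
              'value="1.000000" unitCvRef="UO" unitAccession="UO:0000031" unitName="minute"',
              txt, fixed = TRUE)
  writeLines(mins, f5 <- withr::local_tempfile(fileext = ".mzML"))
  expect_equal(read_mzml(f5)$spectra[[2]]$rt, 60)
})

test_that("simulator-written mzML carries the 40-window scheme", {
  acq <- acquisition_spec(gradient_length = 100)
  comm <- assign_apexes(tiny_community(n_taxa = 2, ppt = 1L, ppp = 1L,
                                       acq = acq, seed = 3))
  sim <- simulate_run(comm, run_seed = 4)
  f <- withr::local_tempfile(fileext = ".mzML")
  write_mzml(sim$run, f)
  expect_equal(nrow(read_mzml(f)$scheme$windows), 40)
})

test_that("MGF writes one block per pseudospectrum and round-trips", {
  ps <- metadia:::new_pseudospectrum(500.25, 2L, 120.5,
                                     c(300.1, 200.2, 400.3), c(10, 5, 20),
                                     complementary = c(TRUE, FALSE, TRUE),
                                     provenance = "r.1")
  f <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(list(ps), f)
  txt <- readLines(f)
  expect_equal(sum(txt == "BEGIN IONS"), 1)
  expect_equal(sum(grepl("^[0-9]", txt)), 3)

  back <- read_mgf(f)[[1]]
  expect_equal(back$precursor_mz, 500.25, tolerance = 1e-4)
  expect_equal(back$charge, 2L)
  expect_equal(back$fragment_mz, sort(c(300.1, 200.2, 400.3)), tolerance = 1e-4)
  expect_equal(back$complementary, c(FALSE, TRUE, TRUE))  # m/z-sorted order

  write_mgf(list(), f)
  expect_equal(length(readLines(f)), 0)

  empty <- metadia:::new_pseudospectrum(500, 2L, 1, numeric(0), numeric(0))
  expect_error(write_mgf(list(empty), f), "no fragments")
})

test_that("spectrum_record enforces its invariants", {
  expect_error(spectrum_record(2L, 0, 100, 1), "isolation window")
  expect_error(spectrum_record(1L, 0, 100, 1, window = c(400, 415)), "must not")
  expect_error(spectrum_record(1L, 0, 100, -1), "negative")
  # unsorted input is sorted
  s <- spectrum_record(1L, 0, c(300, 100, 200), c(3, 1, 2))
  expect_equal(s$mz, c(100, 200, 300))
  expect_equal(s$intensity, c(1, 2, 3))
})

test_that("FASTA and annotation tables read correctly", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">P1 some description", "PEPTIDEK", ">P2", "MKAARPKW"), f)
  prot <- read_fasta(f)
  expect_equal(prot$protein_id, c("P1", "P2"))
  expect_equal(prot$sequence, c("PEPTIDEK", "MKAARPKW"))

  writeLines(c(">P1", "AAK", ">P1", "CCK"), f)
  expect_error(read_fasta(f), "duplicate")

  a <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_id\tphylum\tgenus\tkegg_category",
               "P1\tFirmicutes\tFaecalibacterium\tCarbohydrate metabolism",
               "P2\tBacteroidetes\t\t"), a)
  ann <- read_annotations(a)
  expect_equal(annotation_lookup(ann, "P1", "genus"), "Faecalibacterium")
  expect_equal(annotation_lookup(ann, "P2", "phylum"), "Bacteroidetes")
  expect_true(is.na(annotation_lookup(ann, "P2", "genus")))
  expect_true(is.na(annotation_lookup(ann, "NOPE", "genus")))
})
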