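# deconvolution: trace detection, charge estimation, elution correlation,
# grouping, complementary flagging, pseudospectrum assembly.

ms1_only <- function(peaks_by_scan, cycle_time = 1) {
  lapply(seq_along(peaks_by_scan), function(i)
    spectrum_record(1L, (i - 1) * cycle_time,
                    peaks_by_scan[[i]]$mz, peaks_by_scan[[i]]$int))
}

test_that("detect_ion_traces links a planted trace and applies the gap rule", {
  prof <- c(1, 5, 10, 5, 1)
  scans <- lapply(prof, function(v) list(mz = 500.000 * (1 + runif(1, -2e-6, 2e-6)),
                                         int = v))
  set.seed(11)
  traces <- detect_ion_traces(ms1_only(scans), min_trace_length = 4L)
  expect_length(traces, 1)
  expect_equal(traces[[1]]$apex_intensity, 10)
  expect_equal(traces[[1]]$apex_rt, 2)          # scan 3 at cycle_time 1
  expect_equal(traces[[1]]$mz, 500, tolerance = 500 * 5e-6)
  expect_length(traces[[1]]$intensities, 5)

  # gap rule: peak absent in scans 2-4, max_gap 1 -> fragments too short
  scans_gap <- scans
  for (i in 2:4) scans_gap[[i]] <- list(mz = numeric(0), int = numeric(0))
  expect_length(detect_ion_traces(ms1_only(scans_gap), min_trace_length = 4L,
                                  max_gap = 1L), 0)
})

test_that("each peak joins at most one trace, nearest m/z wins", {
  # two adjacent channels 30 ppm apart -> two separate traces
  scans <- lapply(1:5, function(i) list(mz = c(500.000, 500.015),
                                        int = c(10, 20)))
  traces <- detect_ion_traces(ms1_only(scans), trace_mz_tolerance = 10,
                              min_trace_length = 4L)
  expect_length(traces, 2)
  expect_equal(sort(vapply(traces, `[[`, 0, "mz")), c(500.000, 500.015))
  # all 10 peaks accounted for exactly once
  expect_equal(sum(lengths(lapply(traces, `[[`, "intensities"))), 10)
})

test_that("estimate_charge reads the isotope spacing", {
  mk <- function(mz, int) list(spectrum_record(1L, 0, mz, int))
  tr <- list(mz = 500.000, apex_rt = 0)
  expect_equal(estimate_charge(tr, mk(c(500.000, 500.5017), c(10, 5))), 2L)
  expect_equal(estimate_charge(tr, mk(c(500.000, 501.0034), c(10, 5))), 1L)
  expect_equal(estimate_charge(tr, mk(500.000, 10)), 2L)  # documented fallback
})

test_that("elution_correlation matches the textbook Pearson formula", {
  mk_trace <- function(int, cycles = seq_along(int))
    list(cycles = cycles, intensities = int)
  expect_equal(elution_correlation(mk_trace(c(1, 5, 10, 5, 1)),
                                   mk_trace(c(2, 10, 20, 10, 2))), 1.0)
  expect_lt(elution_correlation(mk_trace(c(1, 5, 10, 5, 1)),
                                mk_trace(c(10, 5, 1, 5, 10))), 0)
  set.seed(7)
  for (i in 1:25) {
    a <- mk_trace(runif(5, 1, 100))
    b <- mk_trace(runif(5, 1, 100))
    expect_equal(elution_correlation(a, b),
                 pearson_oracle(a$intensities, b$intensities),
                 tolerance = 1e-12)
  }
  # missing cycles resampled as zeros
  a <- mk_trace(c(1, 5, 10), cycles = c(1, 2, 3))
  b <- mk_trace(c(1, 10), cycles = c(1, 3))
  expect_equal(elution_correlation(a, b),
               pearson_oracle(c(1, 5, 10), c(1, 0, 10)), tolerance = 1e-12)
  # under 3 shared cycles or constant profile -> undefined
  expect_true(is.na(elution_correlation(mk_trace(c(1, 2), 1:2), mk_trace(c(1, 2), 1:2))))
  expect_true(is.na(elution_correlation(mk_trace(c(5, 5, 5)), mk_trace(c(1, 2, 3)))))
})

mk_full_trace <- function(mz, int, cycles = seq_along(int), cycle_time = 1,
                          level = 2L, window = NA_integer_) {
  rts <- (cycles - 1) * cycle_time
  metadia:::new_ion_trace(mz, rts, cycles, int, level, window)
}

test_that("group_fragments applies window, apex and correlation rules", {
  scheme <- build_window_scheme(400, 430, 15)
  prof <- c(1, 5, 10, 5, 1)
  prec <- mk_full_trace(405.2, prof, level = 1L)
  prec$charge <- 2L
  f1 <- mk_full_trace(210.1, prof * 2, window = 1L)
  f2 <- mk_full_trace(310.1, prof * 3, window = 1L)
  f3 <- mk_full_trace(410.1, prof * 5, window = 1L)
  g <- group_fragments(list(prec), list(f1, f2, f3), scheme,
                       corr_min = 0.8, apex_rt_tolerance = 1.5)
  expect_length(g, 1)
  expect_length(g[[1]]$fragments, 3)
  # fragments sorted by descending apex intensity
  expect_equal(vapply(g[[1]]$fragments, function(f) f$trace$apex_intensity, 0),
               c(50, 30, 20))
  expect_equal(g[[1]]$neutral_mass, 2 * (405.2 - 1.007276))

  # apex rule: one fragment shifted beyond tolerance drops out
  f3_late <- mk_full_trace(410.1, prof * 5, cycles = 4:8, window = 1L)
  g2 <- group_fragments(list(prec), list(f1, f2, f3_late), scheme,
                        corr_min = 0.8, apex_rt_tolerance = 1.5,
                        min_fragments = 2L)
  expect_length(g2[[1]]$fragments, 2)

  # fragment from the wrong window never joins
  f_wrong <- mk_full_trace(210.1, prof * 2, window = 2L)
  g3 <- group_fragments(list(prec), list(f1, f2, f_wrong), scheme,
                        corr_min = 0.8, apex_rt_tolerance = 1.5,
                        min_fragments = 2L)
  expect_length(g3[[1]]$fragments, 2)

  # a fragment may serve two co-eluting precursors
  prec2 <- mk_full_trace(406.9, prof, level = 1L); prec2$charge <- 2L
  g4 <- group_fragments(list(prec, prec2), list(f1, f2, f3), scheme,
                        corr_min = 0.8, apex_rt_tolerance = 1.5)
  expect_length(g4, 2)
})

test_that("flag_complementary detects b/y pairs against ladder enumeration", {
  scheme <- build_window_scheme(400, 1000, 15)
  prof <- c(1, 5, 10, 5, 1)
  # hand example: M = 1000, fragments summing to M + 2 protons
  prec <- mk_full_trace((1000 + 2 * 1.007276) / 2, prof, level = 1L)
  g <- structure(list(precursor = prec, charge = 2L, neutral_mass = 1000,
                      fragments = lapply(c(400.007276, 602.007276, 500.0),
                                         function(m) list(
                                           trace = mk_full_trace(m, prof, window = 1L),
                                           pearson_r = 1, apex_dt = 0,
                                           complementary = FALSE))),
                 class = "PrecursorGroup")
  g <- flag_complementary(g, 0.02)
  comp <- vapply(g$fragments, `[[`, logical(1), "complementary")
  expect_equal(comp, c(TRUE, TRUE, FALSE))

  # full b/y ladder of a tryptic peptide: every b_i/y_(n-i) pair flagged
  for (pep in c("SAMPLER", "VICTRESK", "AQPNTWDSR")) {
    fr <- theoretical_fragments(pep, 2L)
    M <- peptide_neutral_mass(pep)
    gg <- structure(list(
      precursor = mk_full_trace((M + 2 * 1.007276) / 2, prof, level = 1L),
      charge = 2L, neutral_mass = M,
      fragments = lapply(fr$mz, function(m) list(
        trace = mk_full_trace(m, prof, window = 1L),
        pearson_r = 1, apex_dt = 0, complementary = FALSE))),
      class = "PrecursorGroup")
    gg <- flag_complementary(gg, 0.001)
    comp <- vapply(gg$fragments, `[[`, logical(1), "complementary")
    # enumeration oracle: n-1 b ions + n-1 y ions all pair up
    expect_equal(sum(comp), 2 * (nchar(pep) - 1))
  }
})

test_that("build_pseudospectra orders output deterministically", {
  prof <- c(1, 5, 10, 5, 1)
  mk_group <- function(pmz, cycles = 1:5) {
    prec <- mk_full_trace(pmz, prof, cycles = cycles, level = 1L)
    structure(list(precursor = prec, charge = 2L,
                   neutral_mass = 2 * (pmz - 1.007276),
                   fragments = lapply(c(300.3, 150.1, 220.2), function(m) list(
                     trace = mk_full_trace(m, prof, cycles = cycles, window = 1L),
                     pearson_r = 1, apex_dt = 0, complementary = FALSE))),
              class = "PrecursorGroup")
  }
  ps <- build_pseudospectra(list(mk_group(420, 6:10), mk_group(410)), "r")
  expect_length(ps, 2)
  expect_equal(ps[[1]]$precursor_mz, 410)       # earlier RT first
  expect_equal(ps[[1]]$fragment_mz, c(150.1, 220.2, 300.3))  # m/z sorted
  expect_equal(build_pseudospectra(list()), list())
})

test_that("deisotoping removes M+1 satellite traces", {
  prof <- c(1, 5, 10, 5, 1)
  mono <- mk_full_trace(500.000, prof * 10, level = 1L)
  sat <- mk_full_trace(500.000 + 1.00335 / 2, prof * 5, level = 1L)
  other <- mk_full_trace(623.456, prof * 8, level = 1L)
  out <- deisotope_ms1_traces(list(mono, sat, other), apex_rt_tolerance = 5)
  expect_equal(sort(vapply(out, `[[`, 0, "mz")), c(500, 623.456))
})

test_that("deconvolution of an identical run is byte-identical (determinism)", {
  acq <- acquisition_spec(gradient_length = 150, noise_rate = 5)
  comm <- tiny_community(n_taxa = 2, ppt = 2L, ppp = 2L, acq = acq, seed = 9)
  comm <- assign_apexes(comm)
  sim <- simulate_run(comm, run_seed = 10)
  f1 <- withr::local_tempfile(fileext = ".mgf")
  f2 <- withr::local_tempfile(fileext = ".mgf")
  write_mgf(deconvolve_run(sim$run)$pseudospectra, f1)
  write_mgf(deconvolve_run(sim$run)$pseudospectra, f2)
  expect_identical(readLines(f1), readLines(f2))
  # peak conservation: no trace mixes windows or levels
  dec <- deconvolve_run(sim$run)
  expect_true(all(vapply(dec$ms2_traces, function(t)
    t$source_level == 2L && !is.na(t$window), logical(1))))
  expect_true(all(vapply(dec$ms1_traces, function(t)
    t$source_level == 1L, logical(1))))
})

test_that("deconvolution recovers planted precursors from a simulated run", {
  acq <- acquisition_spec(gradient_length = 400, noise_rate = 5)
  comm <- tiny_community(n_taxa = 4, ppt = 3L, ppp = 4L, acq = acq, seed = 12)
  comm <- assign_apexes(comm)
  sim <- simulate_run(comm, run_seed = 13)
  dec <- deconvolve_run(sim$run)
  rs <- recovery_stats(dec$pseudospectra, sim$manifest)
  expect_gte(mean(rs$recovered), 0.9)
})
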