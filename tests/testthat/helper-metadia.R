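# Shared fixtures and independent oracles. Everything is generated in code;
# no binary fixtures.

# Brute-force tryptic digestion oracle: enumerate all substrings and keep
# those consistent with the cleavage rule. Independent of digest()'s
# site-walking implementation.
brute_digest <- function(sequence, missed_cleavages = 2L, min_length = 7L,
                         max_length = 50L) {
  n <- nchar(sequence)
  res <- strsplit(sequence, "")[[1]]
  is_site <- function(i) i >= 1 && i < n && res[i] %in% c("K", "R") && res[i + 1] != "P"
  site_at <- vapply(seq_len(n), function(i)
    res[i] %in% c("K", "R") && (i == n || res[i + 1] != "P"), logical(1))
  out <- character(0)
  for (from in seq_len(n)) {
    if (from > 1 && !site_at[from - 1]) next      # must start after a site
    for (to in from:n) {
      if (to < n && !site_at[to]) next            # must end at a site or terminus
      len <- to - from + 1
      if (len < min_length || len > max_length) next
      internal <- if (to > from) sum(site_at[from:(to - 1)]) else 0L
      if (internal > missed_cleavages) next
      pep <- substr(sequence, from, to)
      if (grepl("X", pep, fixed = TRUE)) next
      out <- c(out, pep)
    }
  }
  unique(out)
}

# Textbook Pearson correlation, written out longhand.
pearson_oracle <- function(x, y) {
  mx <- sum(x) / length(x); my <- sum(y) / length(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}

# Random protein made of tryptic-looking blocks (for digest property tests:
# includes K/R internal sites, occasional P after K/R, occasional X).
random_protein <- function(n = 200, p_x = 0.01) {
  aa <- c("A","C","D","E","F","G","H","I","K","L","M","N","P","Q","R","S",
          "T","V","W","Y")
  s <- sample(aa, n, replace = TRUE)
  if (p_x > 0) s[runif(n) < p_x] <- "X"
  paste(s, collapse = "")
}

# Minimal hand-built run: one precursor trace + co-eluting fragments in one
# window, for unit tests that need full control over every peak.
toy_run <- function(run_id = "toy",
                    scheme = build_window_scheme(400, 430, 15),
                    cycles = 5, cycle_time = 1,
                    ms1_peaks = NULL, ms2_peaks = NULL) {
  # ms1_peaks / ms2_peaks: function(cycle) -> list(mz=, int=) per level /
  # (cycle, window) for MS2
  spectra <- list()
  for (cyc in seq_len(cycles)) {
    t0 <- (cyc - 1) * cycle_time
    p <- if (is.null(ms1_peaks)) list(mz = numeric(0), int = numeric(0))
         else ms1_peaks(cyc)
    spectra[[length(spectra) + 1L]] <- spectrum_record(1L, t0, p$mz, p$int)
    for (w in seq_len(nrow(scheme$windows))) {
      q <- if (is.null(ms2_peaks)) list(mz = numeric(0), int = numeric(0))
           else ms2_peaks(cyc, w)
      spectra[[length(spectra) + 1L]] <- spectrum_record(
        2L, t0 + w * cycle_time / (nrow(scheme$windows) + 1), q$mz, q$int,
        window = c(scheme$windows$lower[w], scheme$windows$upper[w]))
    }
  }
  spectra_run(run_id, spectra, scheme)
}

# Synthetic pseudospectrum straight from a peptide's theoretical ladder
# (noise and dropout optional) — used by search/FDR tests where the
# deconvolution stage is not under test.
synth_pseudospectrum <- function(peptide, charge = 2L, id = peptide,
                                 dropout = 0, n_noise = 0, rt = 100) {
  fr <- theoretical_fragments(peptide, 2L)
  mz <- fr$mz[fr$mz >= 100 & fr$mz <= 1500]
  if (dropout > 0) mz <- mz[runif(length(mz)) >= dropout]
  int <- rlnorm(length(mz), log(500), 0.7)
  if (n_noise > 0) {
    mz <- c(mz, runif(n_noise, 100, 1500))
    int <- c(int, rlnorm(n_noise, log(100), 1))
  }
  metadia:::new_pseudospectrum(
    (peptide_neutral_mass(peptide) + charge * 1.007276) / charge,
    charge, rt, mz, int, provenance = id)
}

# Small community presets used across test files (kept small for speed).
tiny_acq <- function(...) acquisition_spec(gradient_length = 300, ...)

tiny_community <- function(n_taxa = 4, ppt = 3L, ppp = 3L, shared = 0,
                           acq = tiny_acq(), seed = 42, ...) {
  generate_community(taxa = metadia:::default_taxa()[seq_len(n_taxa)],
                     proteins_per_taxon = ppt, peptides_per_protein = ppp,
                     shared_fraction = shared, acq = acq, seed = seed, ...)
}
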