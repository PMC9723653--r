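# Pseudospectrum deconvolution: 2-D ion-trace detection in MS1 and
# per-window MS2 maps, precursor-fragment grouping by elution-profile
# correlation and apex proximity, complementary y/b flagging.

#' Default deconvolution parameters
#'
#' Tolerances follow common DIA deconvolution practice and are all
#' overridable: 10 ppm trace m/z tolerance, minimum trace length 4 scans,
#' at most 1 missing scan inside a trace, Pearson correlation >= 0.8 for
#' precursor-fragment grouping, apex tolerance 1.5 cycles, and at least 3
#' fragments per pseudospectrum.
#'
#' @return named list of parameters
#' @export
deconvolution_defaults <- function() {
  list(trace_mz_tolerance = 10, min_trace_length = 4L, max_gap = 1L,
       min_intensity = 0, corr_min = 0.8, apex_rt_tolerance = NULL,
       min_fragments = 3L, isotope_tolerance = 10)
}

new_ion_trace <- function(mz, rts, cycles, intensities, level, window = NA_integer_) {
  apex <- which.max(intensities)
  structure(list(mz = mz, scan_rts = rts, cycles = cycles,
                 intensities = intensities,
                 apex_rt = rts[apex], apex_intensity = intensities[apex],
                 source_level = level, window = window),
            class = "IonTrace")
}

#' Detect chromatographic ion traces in one spectrum map
#'
#' Greedy two-dimensional feature detection on a time-ordered set of
#' centroided spectra from a single level (and, for MS2, a single isolation
#' window). Peaks in consecutive scans join an open trace when they fall
#' within `trace_mz_tolerance` ppm of the running intensity-weighted trace
#' m/z; the nearest peak wins a contested trace and the nearest trace wins a
#' contested peak (ties resolved toward lower m/z). A trace missing from
#' more than `max_gap` consecutive scans is closed. Traces shorter than
#' `min_trace_length` member scans, or whose apex is below `min_intensity`,
#' are discarded.
#'
#' @param spectra list of `SpectrumRecord`, all same level/window
#' @param cycles integer cycle index per spectrum (defaults to 1..n)
#' @param trace_mz_tolerance ppm tolerance for peak-to-trace linking
#' @param min_trace_length minimum member scans per reported trace
#' @param max_gap maximum consecutive missing scans inside a trace
#' @param min_intensity minimum apex intensity of a reported trace
#' @param level,window recorded on the output traces
#' @return list of `IonTrace`
#' @export
detect_ion_traces <- function(spectra, cycles = NULL,
                              trace_mz_tolerance = 10, min_trace_length = 4L,
                              max_gap = 1L, min_intensity = 0,
                              level = 1L, window = NA_integer_) {
  n <- length(spectra)
  if (n == 0) return(list())
  if (is.null(cycles)) cycles <- seq_len(n)
  # open traces kept in parallel lists; closed traces accumulated
  open <- list()   # each: list(wsum, isum, mz, rts, cyc, int, gap)
  done <- list()
  close_trace <- function(tr) {
    if (length(tr$int) >= min_trace_length && max(tr$int) >= min_intensity)
      done[[length(done) + 1L]] <<- new_ion_trace(tr$wsum / tr$isum, tr$rts,
                                                  tr$cyc, tr$int, level, window)
  }
  for (i in seq_len(n)) {
    s <- spectra[[i]]
    pmz <- s$mz; pint <- s$intensity
    keep <- pint > 0
    pmz <- pmz[keep]; pint <- pint[keep]
    matched_trace <- integer(0)
    assigned_peak <- rep(NA_integer_, length(pmz))
    if (length(open) && length(pmz)) {
      tmz <- vapply(open, function(t) t$wsum / t$isum, numeric(1))
      o <- order(tmz, method = "radix")
      tmz_s <- tmz[o]
      # candidate pairs: nearest open trace below/above each peak
      lo <- findInterval(pmz, tmz_s)
      cand <- data.table::data.table(
        peak = rep(seq_along(pmz), 2L),
        tpos = c(lo, lo + 1L))
      cand <- cand[tpos >= 1L & tpos <= length(tmz_s)]
      cand[, trace := o[tpos]]
      cand[, dist := abs(pmz[peak] - tmz[trace])]
      cand[, tol := tmz[trace] * trace_mz_tolerance * 1e-6]
      cand <- cand[dist <= tol]
      if (nrow(cand)) {
        # greedy: smallest distance first, ties toward lower m/z peak
        data.table::setorderv(cand, c("dist", "peak"))
        used_t <- logical(length(open)); used_p <- logical(length(pmz))
        for (r in seq_len(nrow(cand))) {
          tr <- cand$trace[r]; pk <- cand$peak[r]
          if (!used_t[tr] && !used_p[pk]) {
            used_t[tr] <- TRUE; used_p[pk] <- TRUE
            assigned_peak[pk] <- tr
          }
        }
        matched_trace <- assigned_peak[!is.na(assigned_peak)]
      }
    }
    # update matched traces, age the rest
    still_open <- vector("list", length(open))
    for (k in seq_along(open)) {
      tr <- open[[k]]
      pk <- which(assigned_peak == k)
      if (length(pk) == 1L) {
        tr$wsum <- tr$wsum + pmz[pk] * pint[pk]
        tr$isum <- tr$isum + pint[pk]
        tr$mzv <- c(tr$mzv, pmz[pk])
        tr$rts <- c(tr$rts, s$rt)
        tr$cyc <- c(tr$cyc, cycles[i])
        tr$int <- c(tr$int, pint[pk])
        tr$gap <- 0L
        still_open[[k]] <- tr
      } else {
        tr$gap <- tr$gap + 1L
        if (tr$gap > max_gap) close_trace(tr) else still_open[[k]] <- tr
      }
    }
    open <- Filter(Negate(is.null), still_open)
    # unassigned peaks open new traces
    for (pk in which(is.na(assigned_peak))) {
      open[[length(open) + 1L]] <- list(wsum = pmz[pk] * pint[pk], isum = pint[pk],
                                        mzv = pmz[pk], rts = s$rt,
                                        cyc = cycles[i], int = pint[pk], gap = 0L)
    }
  }
  for (tr in open) close_trace(tr)
  done
}

#' Drop MS1 traces explained as isotope satellites
#'
#' A trace whose m/z sits one isotope spacing (1.00335/z, z = 1..4) above a
#' stronger, co-apexing trace is the M+1 peak of that trace's envelope, not
#' an independent precursor; keeping it would duplicate pseudospectra.
#'
#' @param traces list of MS1 `IonTrace`
#' @param isotope_tolerance ppm tolerance on the spacing
#' @param apex_rt_tolerance max apex RT difference (seconds)
#' @return filtered trace list
#' @export
deisotope_ms1_traces <- function(traces, isotope_tolerance = 10,
                                 apex_rt_tolerance = 5) {
  if (length(traces) < 2) return(traces)
  mz <- vapply(traces, `[[`, numeric(1), "mz")
  apex_i <- vapply(traces, `[[`, numeric(1), "apex_intensity")
  apex_rt <- vapply(traces, `[[`, numeric(1), "apex_rt")
  is_iso <- logical(length(traces))
  for (k in seq_along(traces)) {
    for (z in 1:4) {
      target <- mz[k] - ISOTOPE_SPACING / z
      tol <- mz[k] * isotope_tolerance * 1e-6
      hit <- which(abs(mz - target) <= tol &
                     apex_i > apex_i[k] &
                     abs(apex_rt - apex_rt[k]) <= apex_rt_tolerance)
      if (length(hit)) { is_iso[k] <- TRUE; break }
    }
  }
  traces[!is_iso]
}

#' Estimate precursor charge from the isotope envelope
#'
#' Searches the apex MS1 scan for a companion peak one isotope spacing above
#' the trace m/z at charge 1–4 and returns the charge whose companion is
#' most intense. Falls back to 2+ (the dominant tryptic charge state) when
#' no companion is found.
#'
#' @param trace an MS1 `IonTrace`
#' @param ms1_spectra list of MS1 `SpectrumRecord` from the same run
#' @param isotope_tolerance ppm tolerance
#' @return integer charge
#' @export
estimate_charge <- function(trace, ms1_spectra, isotope_tolerance = 10) {
  rts <- vapply(ms1_spectra, function(s) s$rt, numeric(1))
  apex <- ms1_spectra[[which.min(abs(rts - trace$apex_rt))]]
  best_z <- 2L; best_int <- 0
  for (z in 1:4) {
    target <- trace$mz + ISOTOPE_SPACING / z
    tol <- target * isotope_tolerance * 1e-6
    sel <- which(abs(apex$mz - target) <= tol)
    if (length(sel)) {
      ci <- max(apex$intensity[sel])
      if (ci > best_int) { best_int <- ci; best_z <- as.integer(z) }
    }
  }
  best_z
}

#' Pearson correlation of two elution profiles
#'
#' Both traces are resampled onto the shared acquisition-cycle grid
#' (missing cycles count as zero intensity) and correlated. Returns `NA`
#' when the traces share fewer than 3 cycles or either resampled profile is
#' constant.
#'
#' @param a,b `IonTrace` objects from the same run
#' @return Pearson r in `[-1, 1]`, or `NA`
#' @export
elution_correlation <- function(a, b) {
  lo <- max(min(a$cycles), min(b$cycles))
  hi <- min(max(a$cycles), max(b$cycles))
  if (hi - lo + 1 < 3) return(NA_real_)
  grid <- lo:hi
  va <- numeric(length(grid)); vb <- numeric(length(grid))
  ia <- match(grid, a$cycles); ib <- match(grid, b$cycles)
  va[!is.na(ia)] <- a$intensities[ia[!is.na(ia)]]
  vb[!is.na(ib)] <- b$intensities[ib[!is.na(ib)]]
  if (stats::sd(va) == 0 || stats::sd(vb) == 0) return(NA_real_)
  stats::cor(va, vb)
}

#' Group fragment traces with precursor traces
#'
#' For every MS1 precursor trace, candidate fragments are the MS2 traces
#' from the isolation window containing the precursor m/z whose apex lies
#' within `apex_rt_tolerance` of the precursor apex and whose elution
#' profile correlates at `corr_min` or better. Fragment traces may join
#' several precursor groups — co-elution is the rule, not the exception, in
#' metaproteomes. Groups with fewer than `min_fragments` fragments are
#' dropped.
#'
#' @param ms1_traces MS1 `IonTrace` list, each optionally carrying `$charge`
#' @param ms2_traces MS2 `IonTrace` list with window indices set
#' @param scheme `DiaWindowScheme`
#' @param corr_min minimum Pearson r for membership
#' @param apex_rt_tolerance max apex RT difference (seconds)
#' @param min_fragments minimum fragments per retained group
#' @return list of `PrecursorGroup`
#' @export
group_fragments <- function(ms1_traces, ms2_traces, scheme,
                            corr_min = 0.8, apex_rt_tolerance,
                            min_fragments = 3L) {
  if (!length(ms1_traces) || !length(ms2_traces)) return(list())
  f_win <- vapply(ms2_traces, function(t) as.numeric(t$window), numeric(1))
  f_apex <- vapply(ms2_traces, `[[`, numeric(1), "apex_rt")
  groups <- list()
  for (p in ms1_traces) {
    w <- window_for_mz(scheme, p$mz)
    if (is.na(w)) next
    cand <- which(f_win == w & abs(f_apex - p$apex_rt) <= apex_rt_tolerance)
    if (length(cand) < min_fragments) next
    keep <- list()
    for (j in cand) {
      r <- elution_correlation(p, ms2_traces[[j]])
      if (!is.na(r) && r >= corr_min)
        keep[[length(keep) + 1L]] <- list(
          trace = ms2_traces[[j]], pearson_r = r,
          apex_dt = abs(f_apex[j] - p$apex_rt), complementary = FALSE)
    }
    if (length(keep) < min_fragments) next
    ord <- order(-vapply(keep, function(f) f$trace$apex_intensity, numeric(1)))
    charge <- p$charge %||% 2L
    groups[[length(groups) + 1L]] <- structure(
      list(precursor = p, charge = charge,
           neutral_mass = charge * (p$mz - PROTON_MASS),
           fragments = keep[ord]),
      class = "PrecursorGroup")
  }
  groups
}

#' Flag complementary y/b fragment pairs
#'
#' Any two fragments (both assumed singly charged) whose m/z sum matches the
#' precursor neutral mass plus two protons within `fragment_tolerance` are
#' flagged as a likely b_i / y_(n-i) pair. This is annotation only; nothing
#' is filtered on it — pseudospectra are filtered downstream by the database
#' search.
#'
#' @param group a `PrecursorGroup` with `neutral_mass` set
#' @param fragment_tolerance Da tolerance on the pair sum
#' @return the group with `complementary` flags updated
#' @export
flag_complementary <- function(group, fragment_tolerance = 0.02) {
  frs <- group$fragments
  n <- length(frs)
  if (n < 2) return(group)
  mz <- vapply(frs, function(f) f$trace$mz, numeric(1))
  target <- group$neutral_mass + 2 * PROTON_MASS
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (abs(mz[i] + mz[j] - target) <= fragment_tolerance) {
        frs[[i]]$complementary <- TRUE
        frs[[j]]$complementary <- TRUE
      }
    }
  }
  group$fragments <- frs
  group
}

new_pseudospectrum <- function(precursor_mz, charge, rt, fragment_mz,
                               fragment_intensity, complementary = NULL,
                               provenance = "") {
  o <- order(fragment_mz)
  structure(list(precursor_mz = precursor_mz, charge = as.integer(charge),
                 rt = rt, fragment_mz = fragment_mz[o],
                 fragment_intensity = fragment_intensity[o],
                 complementary = if (is.null(complementary)) logical(length(o))
                                 else complementary[o],
                 provenance = provenance),
            class = "Pseudospectrum")
}

#' Build pseudospectra from precursor-fragment groups
#'
#' One DDA-like pseudospectrum per group: precursor m/z, charge and apex RT
#' from the precursor trace; fragment peaks are the member traces with their
#' apex intensities, sorted by m/z. Output ordering is deterministic
#' (precursor RT, then m/z).
#'
#' @param groups list of `PrecursorGroup`
#' @param run_id provenance tag
#' @return list of `Pseudospectrum`
#' @export
build_pseudospectra <- function(groups, run_id = "run") {
  if (!length(groups)) return(list())
  key <- vapply(groups, function(g) c(g$precursor$apex_rt, g$precursor$mz), numeric(2))
  ord <- order(key[1, ], key[2, ])
  out <- vector("list", length(groups))
  for (k in seq_along(ord)) {
    g <- groups[[ord[k]]]
    out[[k]] <- new_pseudospectrum(
      precursor_mz = g$precursor$mz, charge = g$charge,
      rt = g$precursor$apex_rt,
      fragment_mz = vapply(g$fragments, function(f) f$trace$mz, numeric(1)),
      fragment_intensity = vapply(g$fragments, function(f) f$trace$apex_intensity, numeric(1)),
      complementary = vapply(g$fragments, `[[`, logical(1), "complementary"),
      provenance = sprintf("%s.%d", run_id, k))
  }
  out
}

#' Deconvolve a DIA run into pseudospectra
#'
#' Full deconvolution stage: MS1 trace detection and de-isotoping, charge
#' estimation, per-window MS2 trace detection, precursor-fragment grouping
#' by elution correlation and apex proximity, complementary-ion flagging,
#' and pseudospectrum assembly.
#'
#' @param run a `SpectraRun`
#' @param params parameter list, see [deconvolution_defaults()]
#' @return list with `pseudospectra`, `groups`, `ms1_traces`, `ms2_traces`,
#'   and a `report` data.table (one row per pseudospectrum)
#' @export
deconvolve_run <- function(run, params = deconvolution_defaults()) {
  params <- utils::modifyList(deconvolution_defaults(), params)
  lev <- vapply(run$spectra, function(s) s$ms_level, integer(1))
  ms1_idx <- which(lev == 1L)
  ms1_spectra <- run$spectra[ms1_idx]
  cycle_time <- if (length(ms1_idx) > 1)
    stats::median(diff(vapply(ms1_spectra, function(s) s$rt, numeric(1)))) else 1
  apex_tol <- params$apex_rt_tolerance %||% (1.5 * cycle_time)

  ms1_traces <- detect_ion_traces(
    ms1_spectra, cycles = run$cycle[ms1_idx],
    trace_mz_tolerance = params$trace_mz_tolerance,
    min_trace_length = params$min_trace_length,
    max_gap = params$max_gap, min_intensity = params$min_intensity,
    level = 1L)
  ms1_traces <- deisotope_ms1_traces(ms1_traces,
                                     isotope_tolerance = params$isotope_tolerance,
                                     apex_rt_tolerance = apex_tol)
  for (k in seq_along(ms1_traces))
    ms1_traces[[k]]$charge <- estimate_charge(ms1_traces[[k]], ms1_spectra,
                                              params$isotope_tolerance)

  win_of <- rep(NA_integer_, length(run$spectra))
  for (i in which(lev == 2L))
    win_of[i] <- window_for_mz(run$scheme, mean(run$spectra[[i]]$window))
  ms2_traces <- list()
  for (w in seq_len(nrow(run$scheme$windows))) {
    idx <- which(win_of == w)
    if (!length(idx)) next
    tw <- detect_ion_traces(
      run$spectra[idx], cycles = run$cycle[idx],
      trace_mz_tolerance = params$trace_mz_tolerance,
      min_trace_length = params$min_trace_length,
      max_gap = params$max_gap, min_intensity = params$min_intensity,
      level = 2L, window = w)
    ms2_traces <- c(ms2_traces, tw)
  }

  groups <- group_fragments(ms1_traces, ms2_traces, run$scheme,
                            corr_min = params$corr_min,
                            apex_rt_tolerance = apex_tol,
                            min_fragments = params$min_fragments)
  groups <- lapply(groups, flag_complementary)
  ps <- build_pseudospectra(groups, run_id = run$run_id)
  report <- data.table::rbindlist(lapply(ps, function(p) data.table::data.table(
    run_id = run$run_id, precursor_mz = p$precursor_mz, charge = p$charge,
    rt = p$rt, n_fragments = length(p$fragment_mz),
    n_complementary = sum(p$complementary))))
  list(pseudospectra = ps, groups = groups, ms1_traces = ms1_traces,
       ms2_traces = ms2_traces, report = report)
}
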