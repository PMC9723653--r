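# Targeted quantification: fragment XIC extraction, peak-group picking,
# median-shift RT alignment, and the peptide x run quantity matrix.

#' Default quantification parameters
#'
#' Extraction half-window 150 s around the library retention time, 0.02 Da
#' fragment tolerance, anchor group-score 0.9 for RT alignment.
#'
#' @return named list
#' @export
quantify_defaults <- function() {
  list(rt_half_window = 150, fragment_tolerance = 0.02,
       anchor_score = 0.9, min_anchors = 3L)
}

#' Index the MS2 spectra of a run by isolation window
#'
#' Precomputes, per isolation window, the spectrum indices and retention
#' times of its MS2 scans so targeted extraction only touches the relevant
#' scans. Built once per run by [quantify_all()] and [align_runs()].
#'
#' @param run a `SpectraRun`
#' @return list with one `(idx, rt)` pair per isolation window
#' @export
ms2_index <- function(run) {
  n_win <- nrow(run$scheme$windows)
  win <- rep(NA_integer_, length(run$spectra))
  rts <- numeric(length(run$spectra))
  for (i in seq_along(run$spectra)) {
    s <- run$spectra[[i]]
    rts[i] <- s$rt
    if (s$ms_level == 2L) win[i] <- window_for_mz(run$scheme, mean(s$window))
  }
  lapply(seq_len(n_win), function(w) {
    idx <- which(!is.na(win) & win == w)
    list(idx = idx, rt = rts[idx])
  })
}

#' Extract fragment chromatograms for one library entry
#'
#' Per-cycle summed intensity within +/- `fragment_tolerance` of each
#' library fragment m/z, taken from the MS2 spectra of the isolation window
#' containing the entry precursor (half-open window convention, so a
#' boundary precursor is extracted from exactly one window), restricted to
#' `reference_rt + shift +/- rt_half_window`.
#'
#' @param run a `SpectraRun`
#' @param entry one library row
#' @param rt_half_window seconds
#' @param fragment_tolerance Da
#' @param shift run RT shift (seconds) added to the reference RT
#' @param index optional precomputed [ms2_index()] of the run
#' @return list with `rt` (cycle times) and `xic` (cycles x fragments
#'   matrix), or NULL when the precursor is outside the window scheme
#' @export
extract_xic <- function(run, entry, rt_half_window = 150,
                        fragment_tolerance = 0.02, shift = 0, index = NULL) {
  w <- window_for_mz(run$scheme, entry$precursor_mz)
  if (is.na(w)) {
    warning(sprintf("precursor %.4f outside window scheme; entry skipped",
                    entry$precursor_mz))
    return(NULL)
  }
  frag <- entry_fragments(entry)
  centre <- entry$reference_rt + shift
  if (is.null(index)) index <- ms2_index(run)
  wi <- index[[w]]
  keep <- wi$rt >= centre - rt_half_window & wi$rt <= centre + rt_half_window
  sel <- wi$idx[keep]
  if (!length(sel)) return(list(rt = numeric(0),
                                xic = matrix(0, 0, length(frag$mz))))
  xic <- matrix(0, length(sel), length(frag$mz))
  rts <- numeric(length(sel))
  for (k in seq_along(sel)) {
    s <- run$spectra[[sel[k]]]
    rts[k] <- s$rt
    for (j in seq_along(frag$mz)) {
      lo <- findInterval(frag$mz[j] - fragment_tolerance, s$mz)
      hi <- findInterval(frag$mz[j] + fragment_tolerance, s$mz)
      if (hi > lo) xic[k, j] <- sum(s$intensity[(lo + 1L):hi])
    }
  }
  list(rt = rts, xic = xic)
}

# local maxima / minima of a vector (interior, plus flat-shoulder tolerant)
local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] >= x[3:n]) + 1L
}

#' Pick the best peak group from extracted chromatograms
#'
#' Candidate apexes are the local maxima of the summed chromatogram. For
#' each candidate the peak bounds are the nearest flanking valleys (or
#' where the summed signal drops to 5% of the apex, whichever is closer);
#' the group score is the mean pairwise Pearson correlation of the fragment
#' chromatograms over the peak span. Candidates are ranked by a composite
#' of three sub-scores — fragment co-elution correlation, similarity of the
#' candidate fragment areas to the library relative intensities, and a
#' penalty on distance from the library RT — because a co-eluting
#' interferent can match the co-elution score of the true peak but rarely
#' reproduces its fragment intensity pattern at its retention time.
#' Fragment areas are trapezoidal over the bounds.
#'
#' @param chrom output of [extract_xic()]
#' @param reference_rt library RT of the assay
#' @param lib_intensity optional library relative fragment intensities
#'   (same order as the chromatogram columns) for the similarity sub-score
#' @param rt_half_window extraction half-window, scales the RT penalty
#' @return a `PeakGroup` list (`apex_rt`, `areas`, `total_area`,
#'   `group_score`, `lib_cor`, `bounds`) or NULL when no signal peak exists
#' @export
pick_peak_group <- function(chrom, reference_rt, lib_intensity = NULL,
                            rt_half_window = 150) {
  if (is.null(chrom) || !length(chrom$rt)) return(NULL)
  raw_total <- rowSums(chrom$xic)
  if (all(raw_total <= 0)) return(NULL)
  # light 3-point smoothing for apex/bound detection only; peaks more than
  # 20x below the base peak are not credible candidate apexes
  total <- raw_total
  if (length(total) >= 3)
    total <- c(total[1],
               (utils::head(total, -2) + total[2:(length(total) - 1)] * 2 +
                  utils::tail(total, -2)) / 4,
               total[length(total)])
  apexes <- local_maxima(total)
  if (!length(apexes)) apexes <- which.max(total)
  apexes <- apexes[total[apexes] >= 0.05 * max(total)]
  if (!length(apexes)) apexes <- which.max(total)
  cands <- list()
  for (a in apexes) {
    if (total[a] <= 0) next
    # bounds: descend monotonically to the nearest valley, or to where the
    # summed signal falls to 5% of the apex
    floor_lvl <- 0.05 * total[a]
    lb <- a
    while (lb > 1 && total[lb - 1] <= total[lb] && total[lb] > floor_lvl)
      lb <- lb - 1L
    ub <- a
    while (ub < length(total) && total[ub + 1] <= total[ub] && total[ub] > floor_lvl)
      ub <- ub + 1L
    span <- lb:ub
    gs <- NA_real_
    if (ncol(chrom$xic) >= 2 && length(span) >= 3) {
      sub <- chrom$xic[span, , drop = FALSE]
      keep <- which(apply(sub, 2, stats::sd) > 0)
      if (length(keep) >= 2) {
        cm <- stats::cor(sub[, keep, drop = FALSE])
        gs <- mean(cm[upper.tri(cm)])
      }
    }
    # library intensity similarity over the candidate span
    lc <- NA_real_
    if (!is.null(lib_intensity) && ncol(chrom$xic) >= 3) {
      frag_area <- vapply(seq_len(ncol(chrom$xic)), function(j)
        sum(chrom$xic[span, j]), numeric(1))
      if (stats::sd(frag_area) > 0 && stats::sd(lib_intensity) > 0)
        lc <- stats::cor(frag_area, lib_intensity)
    }
    cands[[length(cands) + 1L]] <- list(apex = a, span = span, score = gs,
                                        lib_cor = lc)
  }
  if (!length(cands)) return(NULL)
  composite <- vapply(cands, function(cc) {
    gs0 <- if (is.na(cc$score)) 0 else cc$score
    lc0 <- if (is.na(cc$lib_cor)) 0 else cc$lib_cor
    dt <- abs(chrom$rt[cc$apex] - reference_rt)
    gs0 + lc0 - 0.5 * dt / rt_half_window
  }, numeric(1))
  best <- cands[[which.max(composite)]]
  span <- best$span
  areas <- vapply(seq_len(ncol(chrom$xic)), function(j) {
    y <- chrom$xic[span, j]
    if (length(span) < 2) return(0)
    sum(diff(chrom$rt[span]) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
  }, numeric(1))
  list(apex_rt = chrom$rt[best$apex], areas = areas,
       total_area = sum(areas), group_score = best$score,
       lib_cor = best$lib_cor, bounds = range(chrom$rt[span]))
}

#' Estimate per-run retention-time shifts
#'
#' Anchor peptides are library entries confidently found in every run
#' (group score at or above `anchor_score`); the per-run shift is the
#' median of apex RT minus reference RT over the anchors. With fewer than
#' `min_anchors` anchors the shift falls back to 0 with a warning.
#'
#' @param runs list of `SpectraRun`
#' @param library library data.table
#' @param params see [quantify_defaults()]
#' @return named numeric vector of shifts (seconds), one per run
#' @export
align_runs <- function(runs, library, params = quantify_defaults()) {
  params <- utils::modifyList(quantify_defaults(), params)
  run_ids <- vapply(runs, `[[`, "", "run_id")
  deltas <- vector("list", length(runs))
  names(deltas) <- run_ids
  found <- matrix(FALSE, nrow(library), length(runs))
  delta_mat <- matrix(NA_real_, nrow(library), length(runs))
  for (r in seq_along(runs)) {
    idx <- ms2_index(runs[[r]])
    for (i in seq_len(nrow(library))) {
      chrom <- suppressWarnings(extract_xic(runs[[r]], library[i],
                                            params$rt_half_window,
                                            params$fragment_tolerance,
                                            index = idx))
      pg <- pick_peak_group(chrom, library$reference_rt[i],
                            entry_fragments(library[i])$intensity,
                            params$rt_half_window)
      if (!is.null(pg) && !is.na(pg$group_score) &&
          pg$group_score >= params$anchor_score) {
        found[i, r] <- TRUE
        delta_mat[i, r] <- pg$apex_rt - library$reference_rt[i]
      }
    }
  }
  anchors <- which(rowSums(found) == length(runs))
  shifts <- stats::setNames(numeric(length(runs)), run_ids)
  if (length(anchors) < params$min_anchors) {
    warning(sprintf("only %d alignment anchors (< %d); using zero RT shift",
                    length(anchors), params$min_anchors))
    return(shifts)
  }
  for (r in seq_along(runs))
    shifts[r] <- stats::median(delta_mat[anchors, r])
  shifts
}

#' Quantify all library peptides across runs
#'
#' Runs are first aligned ([align_runs()]), then every library entry is
#' re-extracted with the per-run shift and its best peak group integrated.
#' Peptide quantity per run is the summed fragment area of the best peak
#' group, summed over charge states of the same (modified) peptide.
#'
#' @param runs list of `SpectraRun`
#' @param library library data.table
#' @param params see [quantify_defaults()]
#' @param align apply RT alignment (default TRUE)
#' @return a `QuantMatrix`: numeric matrix, peptides x runs, NA = missing;
#'   attribute `shifts` carries the per-run RT shifts
#' @export
quantify_all <- function(runs, library, params = quantify_defaults(),
                         align = TRUE) {
  params <- utils::modifyList(quantify_defaults(), params)
  run_ids <- vapply(runs, `[[`, "", "run_id")
  peptides <- sort(unique(library$peptide))
  mat <- matrix(NA_real_, length(peptides), length(runs),
                dimnames = list(peptides, run_ids))
  if (!nrow(library) || !length(runs)) {
    attr(mat, "shifts") <- stats::setNames(numeric(length(runs)), run_ids)
    class(mat) <- c("QuantMatrix", class(mat))
    return(mat)
  }
  shifts <- if (align) align_runs(runs, library, params)
            else stats::setNames(numeric(length(runs)), run_ids)
  for (r in seq_along(runs)) {
    idx <- ms2_index(runs[[r]])
    for (i in seq_len(nrow(library))) {
      chrom <- suppressWarnings(extract_xic(runs[[r]], library[i],
                                            params$rt_half_window,
                                            params$fragment_tolerance,
                                            shift = shifts[r], index = idx))
      pg <- pick_peak_group(chrom, library$reference_rt[i] + shifts[r],
                            entry_fragments(library[i])$intensity,
                            params$rt_half_window)
      if (is.null(pg) || pg$total_area <= 0) next
      pep <- library$peptide[i]
      cur <- mat[pep, r]
      mat[pep, r] <- if (is.na(cur)) pg$total_area else cur + pg$total_area
    }
  }
  attr(mat, "shifts") <- shifts
  class(mat) <- c("QuantMatrix", class(mat))
  mat
}

#' Write a quantity matrix as TSV
#' @param mat `QuantMatrix`
#' @param path output file; empty cells mark missing values
#' @export
write_quant_matrix <- function(mat, path) {
  dt <- data.table::data.table(peptide = rownames(mat))
  for (cn in colnames(mat)) dt[[cn]] <- mat[, cn]
  utils::write.table(dt, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}
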