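# Pseudospectral library assembly and the transition-list TSV dialect.

#' Build a pseudospectral library from accepted matches
#'
#' Groups FDR-accepted matches by (peptide, charge) and keeps the
#' best-scoring supporting pseudospectrum per group. Library fragments are
#' the observed peaks matched to theoretical b/y ions only, the top `top_n`
#' by intensity, with relative intensities normalized so the strongest is
#' 1. Entries with fewer than `min_fragments` matched fragments are
#' dropped. The precursor m/z stored is the theoretical
#' (mass + z * proton) / z, which stabilises downstream extraction windows.
#'
#' @param accepted data.table of FDR-accepted matches (from [search_run()])
#' @param pseudospectra the pseudospectra that were searched (the pool the
#'   `spectrum_id` provenance refers to)
#' @param top_n maximum fragments kept per entry
#' @param min_fragments minimum matched fragments for a usable entry
#' @param fragment_tolerance Da tolerance used to re-derive matched ions
#' @return data.table of library entries: `peptide`, `charge`,
#'   `precursor_mz`, `reference_rt`, `fragment_mz`, `fragment_intensity`
#'   (semicolon-joined), `protein_ids`
#' @export
build_library <- function(accepted, pseudospectra, top_n = 6L,
                          min_fragments = 3L, fragment_tolerance = 0.02) {
  empty <- data.table::data.table(
    peptide = character(0), charge = integer(0), precursor_mz = numeric(0),
    reference_rt = numeric(0), fragment_mz = character(0),
    fragment_intensity = character(0), protein_ids = character(0))
  if (!nrow(accepted)) return(empty)
  ps_by_id <- stats::setNames(pseudospectra,
                              vapply(pseudospectra, `[[`, "", "provenance"))
  acc <- data.table::copy(accepted)
  data.table::setorderv(acc, c("peptide", "charge", "score", "spectrum_id"),
                        c(1, 1, -1, 1))
  best <- acc[, .SD[1], by = .(peptide, charge)]
  rows <- vector("list", nrow(best))
  for (i in seq_len(nrow(best))) {
    ps <- ps_by_id[[best$spectrum_id[i]]]
    if (is.null(ps)) next
    sc <- score_match(ps, best$peptide[i], best$charge[i], fragment_tolerance)
    if (length(sc$matched) < min_fragments) next
    fmz <- ps$fragment_mz[sc$matched]
    fint <- ps$fragment_intensity[sc$matched]
    keep <- utils::head(order(-fint), top_n)
    keep <- keep[order(fmz[keep])]
    fint_rel <- fint[keep] / max(fint[keep])
    mass <- peptide_neutral_mass(best$peptide[i])
    rows[[i]] <- data.table::data.table(
      peptide = best$peptide[i], charge = best$charge[i],
      precursor_mz = (mass + best$charge[i] * PROTON_MASS) / best$charge[i],
      reference_rt = ps$rt,
      fragment_mz = paste(sprintf("%.4f", fmz[keep]), collapse = ";"),
      fragment_intensity = paste(sprintf("%.3f", fint_rel), collapse = ";"),
      protein_ids = best$protein_ids[i])
  }
  out <- data.table::rbindlist(Filter(Negate(is.null), rows))
  if (!nrow(out)) return(empty)
  data.table::setorderv(out, c("peptide", "charge"))
  out
}

#' Write a library to its TSV dialect
#' @param entries library data.table (see [build_library()])
#' @param path output file
#' @export
write_library <- function(entries, path) {
  utils::write.table(entries, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a library TSV
#'
#' Validates the column layout and the per-row semicolon-list arity;
#' malformed rows are reported with their line number.
#'
#' @param path library TSV
#' @return library data.table
#' @export
read_library <- function(path) {
  need <- c("peptide", "charge", "precursor_mz", "reference_rt",
            "fragment_mz", "fragment_intensity", "protein_ids")
  lines <- readLines(path)
  hdr <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(hdr, need))
    stop("library TSV header must be: ", paste(need, collapse = ", "))
  if (length(lines) > 1) {
    nf <- lengths(strsplit(lines[-1], "\t", fixed = TRUE))
    bad <- which(nf != length(need))
    if (length(bad))
      stop(sprintf("malformed library row at line %d: expected %d columns, got %d",
                   bad[1] + 1L, length(need), nf[bad[1]]))
  }
  dt <- data.table::fread(path, sep = "\t", header = TRUE,
                          colClasses = list(character = c("peptide", "fragment_mz",
                                                          "fragment_intensity",
                                                          "protein_ids")))
  nmz <- lengths(strsplit(dt$fragment_mz, ";", fixed = TRUE))
  nint <- lengths(strsplit(dt$fragment_intensity, ";", fixed = TRUE))
  if (any(nmz != nint)) {
    bad <- which(nmz != nint)[1]
    stop(sprintf("malformed library row at line %d: %d fragment m/z vs %d intensities",
                 bad + 1L, nmz[bad], nint[bad]))
  }
  dt
}

# numeric fragment vectors of one library entry row
entry_fragments <- function(entry) {
  list(mz = as.numeric(strsplit(entry$fragment_mz, ";", fixed = TRUE)[[1]]),
       intensity = as.numeric(strsplit(entry$fragment_intensity, ";", fixed = TRUE)[[1]]))
}

#' Peptide-level overlap between two libraries
#'
#' Jaccard fraction |shared peptides| / |union| at the sequence level,
#' optionally after stripping modifications.
#'
#' @param a,b library data.tables
#' @param strip_mods drop modification markers before comparing
#' @return fraction in `[0, 1]`
#' @export
library_overlap <- function(a, b, strip_mods = TRUE) {
  strip <- function(x) if (strip_mods) gsub("M(ox)", "M", x, fixed = TRUE) else x
  pa <- unique(strip(a$peptide)); pb <- unique(strip(b$peptide))
  u <- length(union(pa, pb))
  if (u == 0) return(NA_real_)
  length(intersect(pa, pb)) / u
}
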