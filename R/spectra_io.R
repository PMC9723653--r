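# Standard-format I/O and the internal run model.

#' Build a DIA isolation-window scheme
#'
#' Partitions `[start, end)` into consecutive half-open windows of the given
#' width. A precursor at exactly a window boundary belongs to the upper
#' window, so membership is always unambiguous. The last window is truncated
#' at `end` when the range is not divisible by the width.
#'
#' @param start,end m/z range covered by the DIA isolation scheme (Th).
#' @param width isolation window width (Th).
#' @return An object of class `DiaWindowScheme`: a list with `start`, `end`,
#'   `width` and a data.table `windows` with columns `lower`, `upper`.
#' @examples
#' scheme <- build_window_scheme(400, 1000, 15)
#' nrow(scheme$windows)  # 40
#' @export
build_window_scheme <- function(start, end, width) {
  if (!is.numeric(width) || length(width) != 1 || width <= 0)
    stop("window width must be a positive number")
  if (end <= start) stop("end must be greater than start")
  n_win <- ceiling((end - start) / width - 1e-9)
  lower <- start + width * (seq_len(n_win) - 1)
  upper <- pmin(lower + width, end)
  scheme <- list(start = start, end = end, width = width,
                 windows = data.table::data.table(lower = lower, upper = upper))
  class(scheme) <- "DiaWindowScheme"
  scheme
}

#' @export
print.DiaWindowScheme <- function(x, ...) {
  cat(sprintf("DiaWindowScheme: %d windows of %g m/z over [%g, %g)\n",
              nrow(x$windows), x$width, x$start, x$end))
  invisible(x)
}

#' Window index containing an m/z value
#'
#' Half-open convention: returns the index i with lower_i <= mz < upper_i,
#' or `NA` when the m/z falls outside the scheme.
#'
#' @param scheme a `DiaWindowScheme`
#' @param mz numeric vector of m/z values (Th)
#' @return integer vector of window indices (NA outside the scheme)
#' @export
window_for_mz <- function(scheme, mz) {
  idx <- findInterval(mz, scheme$windows$lower)
  idx[idx < 1L] <- NA_integer_
  out <- ifelse(!is.na(idx) & mz < scheme$windows$upper[pmax(idx, 1L)], idx, NA_integer_)
  as.integer(out)
}

#' Construct a single spectrum record
#'
#' @param ms_level 1 or 2
#' @param rt retention time in seconds
#' @param mz,intensity peak arrays; m/z must be (or will be) sorted ascending
#' @param window for MS2, the isolation window `c(lower, upper)`; NULL for MS1
#' @return A `SpectrumRecord` list.
#' @export
spectrum_record <- function(ms_level, rt, mz, intensity, window = NULL) {
  ms_level <- as.integer(ms_level)
  if (!ms_level %in% c(1L, 2L)) stop("ms_level must be 1 or 2")
  if (ms_level == 2L && is.null(window))
    stop("MS2 spectrum requires an isolation window")
  if (ms_level == 1L && !is.null(window))
    stop("MS1 spectrum must not carry an isolation window")
  if (length(mz) != length(intensity)) stop("mz and intensity lengths differ")
  if (any(intensity < 0)) stop("negative intensity")
  if (is.unsorted(mz)) {
    o <- order(mz)
    mz <- mz[o]; intensity <- intensity[o]
  }
  structure(list(ms_level = ms_level, rt = as.numeric(rt),
                 mz = as.numeric(mz), intensity = as.numeric(intensity),
                 window = window),
            class = "SpectrumRecord")
}

#' Construct a DIA run from spectrum records
#'
#' Assigns each spectrum a cycle index (incremented at every MS1 survey
#' scan) and, when no scheme is supplied, infers the isolation-window scheme
#' from the distinct MS2 windows observed.
#'
#' @param run_id run identifier string
#' @param spectra time-ordered list of `SpectrumRecord`
#' @param scheme optional `DiaWindowScheme`; inferred when NULL
#' @return A `SpectraRun` list with elements `run_id`, `spectra`, `scheme`,
#'   `cycle` (integer per spectrum).
#' @export
spectra_run <- function(run_id, spectra, scheme = NULL) {
  rts <- vapply(spectra, function(s) s$rt, numeric(1))
  if (is.unsorted(rts)) stop("spectra must be time-ordered")
  lev <- vapply(spectra, function(s) s$ms_level, integer(1))
  cycle <- cumsum(lev == 1L)
  cycle[cycle == 0L] <- 1L
  if (is.null(scheme)) {
    wins <- unique(do.call(rbind, lapply(spectra[lev == 2L], function(s) s$window)))
    if (is.null(wins) || nrow(wins) == 0)
      stop("cannot infer window scheme: no MS2 spectra")
    wins <- wins[order(wins[, 1]), , drop = FALSE]
    widths <- wins[, 2] - wins[, 1]
    scheme <- build_window_scheme(min(wins[, 1]), max(wins[, 2]),
                                  stats::median(widths))
  }
  for (s in spectra[lev == 2L]) {
    if (is.na(window_for_mz(scheme, mean(s$window))))
      stop("MS2 isolation window outside the window scheme")
  }
  structure(list(run_id = run_id, spectra = spectra, scheme = scheme,
                 cycle = as.integer(cycle)),
            class = "SpectraRun")
}

#' @export
print.SpectraRun <- function(x, ...) {
  lev <- vapply(x$spectra, function(s) s$ms_level, integer(1))
  cat(sprintf("SpectraRun '%s': %d spectra (%d MS1 / %d MS2), %d cycles, %d windows\n",
              x$run_id, length(x$spectra), sum(lev == 1), sum(lev == 2),
              max(x$cycle), nrow(x$scheme$windows)))
  invisible(x)
}

## ---- mzML ----------------------------------------------------------------
# Minimal mzML 1.1 subset: centroided spectra, scan start time, isolation
# windows, uncompressed 64-bit float binary arrays. No vendor extras.

b64_encode_doubles <- function(x) {
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8L, endian = "little"))
}

b64_decode_doubles <- function(s, n) {
  raw <- jsonlite::base64_dec(gsub("[\r\n ]", "", s))
  readBin(raw, "double", n = n, size = 8L, endian = "little")
}

#' Write a run to mzML
#'
#' Serializes a `SpectraRun` as a minimal, standard-conformant mzML 1.1
#' document (centroided spectra, uncompressed 64-bit float peak arrays,
#' retention times in seconds, MS2 isolation-window metadata).
#'
#' @param run a `SpectraRun`
#' @param path output file path
#' @return `path`, invisibly.
#' @export
write_mzml <- function(run, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  n <- length(run$spectra)
  writeLines(c(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    '  <cvList count="2">',
    '    <cv id="MS" fullName="Proteomics Standards Initiative Mass Spectrometry Ontology" URI="https://raw.githubusercontent.com/HUPO-PSI/psi-ms-CV/master/psi-ms.obo"/>',
    '    <cv id="UO" fullName="Unit Ontology" URI="https://raw.githubusercontent.com/bio-ontology-research-group/unit-ontology/master/unit.obo"/>',
    '  </cvList>',
    sprintf('  <run id="%s">', run$run_id),
    sprintf('    <spectrumList count="%d">', n)), con)
  for (i in seq_len(n)) {
    s <- run$spectra[[i]]
    np <- length(s$mz)
    lines <- c(
      sprintf('      <spectrum index="%d" id="scan=%d" defaultArrayLength="%d">', i - 1L, i, np),
      sprintf('        <cvParam cvRef="MS" accession="MS:1000511" name="ms level" value="%d"/>', s$ms_level),
      '        <cvParam cvRef="MS" accession="MS:1000127" name="centroid spectrum" value=""/>',
      '        <scanList count="1">',
      '          <scan>',
      sprintf('            <cvParam cvRef="MS" accession="MS:1000016" name="scan start time" value="%.6f" unitCvRef="UO" unitAccession="UO:0000010" unitName="second"/>', s$rt),
      '          </scan>',
      '        </scanList>')
    if (s$ms_level == 2L) {
      ctr <- mean(s$window)
      lines <- c(lines,
        '        <precursorList count="1">',
        '          <precursor>',
        '            <isolationWindow>',
        sprintf('              <cvParam cvRef="MS" accession="MS:1000827" name="isolation window target m/z" value="%.6f"/>', ctr),
        sprintf('              <cvParam cvRef="MS" accession="MS:1000828" name="isolation window lower offset" value="%.6f"/>', ctr - s$window[1]),
        sprintf('              <cvParam cvRef="MS" accession="MS:1000829" name="isolation window upper offset" value="%.6f"/>', s$window[2] - ctr),
        '            </isolationWindow>',
        '          </precursor>',
        '        </precursorList>')
    }
    lines <- c(lines,
      '        <binaryDataArrayList count="2">',
      '          <binaryDataArray>',
      '            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '            <cvParam cvRef="MS" accession="MS:1000514" name="m/z array" value=""/>',
      sprintf('            <binary>%s</binary>', b64_encode_doubles(s$mz)),
      '          </binaryDataArray>',
      '          <binaryDataArray>',
      '            <cvParam cvRef="MS" accession="MS:1000523" name="64-bit float" value=""/>',
      '            <cvParam cvRef="MS" accession="MS:1000576" name="no compression" value=""/>',
      '            <cvParam cvRef="MS" accession="MS:1000515" name="intensity array" value=""/>',
      sprintf('            <binary>%s</binary>', b64_encode_doubles(s$intensity)),
      '          </binaryDataArray>',
      '        </binaryDataArrayList>',
      '      </spectrum>')
    writeLines(lines, con)
  }
  writeLines(c('    </spectrumList>', '  </run>', '</mzML>'), con)
  invisible(path)
}

#' Read an mzML file into a run
#'
#' Parses centroided mzML 1.1 into the internal `SpectraRun` model. The
#' isolation-window scheme is inferred from the MS2 isolation windows
#' observed in the file. Retention times are normalized to seconds.
#'
#' Profile-mode spectra and MS2 spectra lacking isolation-window metadata
#' are rejected with explicit errors.
#'
#' @param path mzML file path
#' @param run_id run identifier; defaults to the mzML run id or file stem
#' @return A `SpectraRun`.
#' @export
read_mzml <- function(path, run_id = NULL) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop(sprintf(
                    "malformed mzML '%s': %s", path, conditionMessage(e)), call. = FALSE))
  xml2::xml_ns_strip(doc)
  if (is.null(run_id)) {
    run_id <- xml2::xml_attr(xml2::xml_find_first(doc, ".//run"), "id")
    if (is.na(run_id)) run_id <- sub("\\.mzML$", "", basename(path), ignore.case = TRUE)
  }
  # vectorized extraction: one global XPath per field, aligned by document
  # order (each spectrum carries each field exactly once)
  nodes <- xml2::xml_find_all(doc, ".//spectrumList/spectrum")
  n <- length(nodes)
  if (n == 0) stop("no spectra in ", path)
  if (length(xml2::xml_find_all(doc, ".//spectrum/cvParam[@accession='MS:1000128']")))
    stop("centroid required: profile-mode spectra in ", path, call. = FALSE)
  lev_nodes <- xml2::xml_find_all(doc, ".//spectrum/cvParam[@accession='MS:1000511']")
  if (length(lev_nodes) != n) stop("spectrum without ms level in ", path)
  lev <- as.integer(xml2::xml_attr(lev_nodes, "value"))
  rt_nodes <- xml2::xml_find_all(doc, ".//spectrum/scanList/scan/cvParam[@accession='MS:1000016']")
  if (length(rt_nodes) != n) stop("spectrum without scan start time in ", path)
  rt <- as.numeric(xml2::xml_attr(rt_nodes, "value"))
  rt_min <- grepl("minute", xml2::xml_attr(rt_nodes, "unitName"))
  rt[rt_min %in% TRUE] <- rt[rt_min %in% TRUE] * 60
  iso_of <- function(acc) as.numeric(xml2::xml_attr(xml2::xml_find_all(
    doc, sprintf(".//spectrum//isolationWindow/cvParam[@accession='%s']", acc)), "value"))
  ctr <- iso_of("MS:1000827"); off_lo <- iso_of("MS:1000828"); off_hi <- iso_of("MS:1000829")
  n_ms2 <- sum(lev == 2L)
  if (length(ctr) != n_ms2 || length(off_lo) != n_ms2 || length(off_hi) != n_ms2)
    stop("MS2 spectrum without isolation-window metadata in ", path, call. = FALSE)
  mz_bin <- xml2::xml_text(xml2::xml_find_all(
    doc, ".//binaryDataArray[cvParam/@accession='MS:1000514']/binary"))
  int_bin <- xml2::xml_text(xml2::xml_find_all(
    doc, ".//binaryDataArray[cvParam/@accession='MS:1000515']/binary"))
  if (length(mz_bin) != n || length(int_bin) != n)
    stop("spectrum without m/z or intensity array in ", path)
  nlen <- as.integer(xml2::xml_attr(nodes, "defaultArrayLength"))
  spectra <- vector("list", n)
  w <- 0L
  for (i in seq_len(n)) {
    window <- NULL
    if (lev[i] == 2L) {
      w <- w + 1L
      window <- c(ctr[w] - off_lo[w], ctr[w] + off_hi[w])
    }
    spectra[[i]] <- spectrum_record(lev[i], rt[i],
                                    b64_decode_doubles(mz_bin[i], nlen[i]),
                                    b64_decode_doubles(int_bin[i], nlen[i]),
                                    window)
  }
  spectra_run(run_id, spectra)
}

## ---- MGF -----------------------------------------------------------------

#' Write pseudospectra to an MGF peak list
#'
#' One `BEGIN IONS` block per pseudospectrum, with PEPMASS, CHARGE,
#' RTINSECONDS and TITLE headers. Indices of complementary-flagged fragments
#' are carried in a comment line so the annotation survives a round-trip.
#'
#' @param pseudospectra list of `Pseudospectrum`
#' @param path output file
#' @return `path`, invisibly. An empty list yields an empty file.
#' @export
write_mgf <- function(pseudospectra, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (ps in pseudospectra) {
    if (length(ps$fragment_mz) < 1)
      stop("pseudospectrum with no fragments cannot be serialized")
    comp <- which(ps$complementary %||% logical(length(ps$fragment_mz)))
    writeLines(c(
      "BEGIN IONS",
      sprintf("TITLE=%s", ps$provenance),
      sprintf("PEPMASS=%.6f", ps$precursor_mz),
      sprintf("CHARGE=%d+", ps$charge),
      sprintf("RTINSECONDS=%.4f", ps$rt),
      if (length(comp)) sprintf("# COMPLEMENTARY=%s", paste(comp, collapse = ";")),
      sprintf("%.6f %.4f", ps$fragment_mz, ps$fragment_intensity),
      "END IONS"), con)
  }
  invisible(path)
}

#' Read an MGF peak list into pseudospectra
#'
#' @param path MGF file
#' @return list of `Pseudospectrum`
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  starts <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(starts) != length(ends)) stop("unbalanced IONS blocks in ", path)
  out <- vector("list", length(starts))
  for (k in seq_along(starts)) {
    block <- lines[(starts[k] + 1L):(ends[k] - 1L)]
    hdr <- grepl("=", block) & !grepl("^#", block)
    fields <- block[hdr]
    kv <- strsplit(fields, "=", fixed = TRUE)
    keys <- vapply(kv, `[`, "", 1L)
    vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), "")
    comp_line <- grep("^# COMPLEMENTARY=", block, value = TRUE)
    peaks <- block[!hdr & !grepl("^#", block) & nzchar(block)]
    pm <- do.call(rbind, lapply(strsplit(peaks, "[ \t]+"), as.numeric))
    comp <- logical(nrow(pm))
    if (length(comp_line)) {
      idx <- as.integer(strsplit(sub("^# COMPLEMENTARY=", "", comp_line), ";")[[1]])
      comp[idx] <- TRUE
    }
    out[[k]] <- new_pseudospectrum(
      precursor_mz = as.numeric(vals[keys == "PEPMASS"]),
      charge = as.integer(sub("\\+$", "", vals[keys == "CHARGE"])),
      rt = as.numeric(vals[keys == "RTINSECONDS"]),
      fragment_mz = pm[, 1], fragment_intensity = pm[, 2],
      complementary = comp,
      provenance = vals[keys == "TITLE"])
  }
  out
}

## ---- FASTA and annotations -----------------------------------------------

#' Read a protein FASTA
#'
#' IDs are the header token up to the first whitespace. Duplicate IDs and
#' empty sequences are errors; the input order is preserved. Sequences must
#' use the 20 standard residues plus X.
#'
#' @param path FASTA file
#' @return data.table with columns `protein_id`, `sequence`
#' @export
read_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aa))
  seqs <- toupper(as.character(aa))
  if (anyDuplicated(ids))
    stop("duplicate FASTA IDs: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(seqs))) stop("empty sequence in FASTA: ", path)
  bad <- grepl(sprintf("[^%sX]", paste(names(AA_MONO), collapse = "")), seqs)
  if (any(bad))
    stop("non-standard residues in: ", paste(ids[bad][1:min(3, sum(bad))], collapse = ", "))
  data.table::data.table(protein_id = ids, sequence = unname(seqs))
}

#' Write a protein table to FASTA
#' @param proteins data.table with `protein_id`, `sequence`
#' @param path output file
#' @export
write_fasta <- function(proteins, path) {
  aa <- Biostrings::AAStringSet(proteins$sequence)
  names(aa) <- proteins$protein_id
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

#' Read a protein annotation table
#'
#' Tab-separated with columns `protein_id`, `phylum`, `genus`,
#' `kegg_category`; empty cells mean unannotated. Lookups of unknown
#' proteins return `NA` rather than erroring.
#'
#' @param path TSV file
#' @return An `AnnotationTable` (keyed data.table)
#' @export
read_annotations <- function(path) {
  dt <- data.table::fread(path, sep = "\t", header = TRUE, colClasses = "character",
                          na.strings = c("", "NA"))
  need <- c("protein_id", "phylum", "genus", "kegg_category")
  if (!all(need %in% names(dt)))
    stop("annotation TSV must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(dt$protein_id)) stop("duplicate protein_id in annotation table")
  data.table::setkey(dt, protein_id)
  class(dt) <- c("AnnotationTable", class(dt))
  dt
}

#' Look up an annotation label
#'
#' @param table an `AnnotationTable`
#' @param protein_id protein identifier(s)
#' @param rank one of "phylum", "genus", "kegg_category"
#' @return character vector of labels; `NA` when the protein is absent or
#'   unannotated at that rank.
#' @export
annotation_lookup <- function(table, protein_id, rank) {
  rank <- match.arg(rank, c("phylum", "genus", "kegg_category"))
  table[protein_id, on = "protein_id"][[rank]]
}
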