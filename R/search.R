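# Database search: in-silico tryptic digestion, theoretical b/y ladders,
# hyperscore-style fragment matching, target-decoy FDR at 1%.

#' Default digestion configuration
#'
#' Trypsin, up to 2 missed cleavages, peptide length 7–50,
#' carbamidomethyl-C fixed (+57.02146 Da), at most one oxidized methionine
#' (+15.99491 Da) as a variable modification.
#'
#' @return named list
#' @export
digest_defaults <- function() {
  list(missed_cleavages = 2L, min_length = 7L, max_length = 50L,
       oxidation = TRUE)
}

#' Default search configuration
#'
#' Parent ion tolerance 10 ppm, fragment tolerance 0.02 Da, FDR threshold
#' 1%, decoy prefix `DECOY_`.
#'
#' @return named list
#' @export
search_defaults <- function() {
  list(parent_tolerance = 10, fragment_tolerance = 0.02,
       fdr_threshold = 0.01, decoy_prefix = "DECOY_")
}

#' In-silico tryptic digestion of one protein
#'
#' Cleaves after K or R except when the next residue is P; emits all
#' products with at most `missed_cleavages` internal cleavage sites and
#' length within bounds. Peptides containing X are excluded.
#'
#' @param sequence protein amino-acid string
#' @param missed_cleavages maximum internal cleavage sites
#' @param min_length,max_length length bounds (residues)
#' @return character vector of unique peptide sequences
#' @export
digest <- function(sequence, missed_cleavages = 2L, min_length = 7L,
                   max_length = 50L) {
  n <- nchar(sequence)
  if (n == 0) return(character(0))
  res <- strsplit(sequence, "", fixed = TRUE)[[1]]
  # cleavage after position i: residue K/R and successor not P
  cut <- which(res %in% c("K", "R"))
  cut <- cut[cut == n | res[pmin(cut + 1L, n)] != "P"]
  bounds <- c(0L, cut, if (!n %in% cut) n)
  bounds <- unique(bounds)
  peps <- character(0)
  nb <- length(bounds)
  for (i in seq_len(nb - 1L)) {
    for (j in (i + 1L):min(nb, i + 1L + missed_cleavages)) {
      from <- bounds[i] + 1L; to <- bounds[j]
      len <- to - from + 1L
      if (len < min_length || len > max_length) next
      pep <- substr(sequence, from, to)
      if (grepl("X", pep, fixed = TRUE)) next
      peps <- c(peps, pep)
    }
  }
  unique(peps)
}

#' Monoisotopic neutral mass of a (modified) peptide
#'
#' Accepts plain sequences and the in-package modified notation where an
#' oxidized methionine is written `M(ox)`. Cysteine always carries the fixed
#' carbamidomethyl group (+57.02146 Da), mirroring iodoacetamide alkylation.
#'
#' @param peptide peptide string, e.g. `"PEPTIDE"` or `"AM(ox)DEK"`
#' @return neutral monoisotopic mass in Da
#' @export
peptide_neutral_mass <- function(peptide) {
  vapply(peptide, function(p) {
    n_ox <- lengths(regmatches(p, gregexpr("M(ox)", p, fixed = TRUE)))
    plain <- gsub("M(ox)", "M", p, fixed = TRUE)
    res <- strsplit(plain, "", fixed = TRUE)[[1]]
    m <- AA_MONO[res]
    if (anyNA(m)) stop("unknown residue in peptide: ", p)
    sum(m) + WATER_MASS + n_ox * OXIDATION +
      sum(res == "C") * CARBAMIDOMETHYL
  }, numeric(1), USE.NAMES = FALSE)
}

# residue masses including fixed/variable mods, in sequence order
residue_masses <- function(peptide) {
  plain <- gsub("M(ox)", "m", peptide, fixed = TRUE)
  res <- strsplit(plain, "", fixed = TRUE)[[1]]
  m <- ifelse(res == "m", AA_MONO[["M"]] + OXIDATION,
              AA_MONO[res] + ifelse(res == "C", CARBAMIDOMETHYL, 0))
  if (anyNA(m)) stop("unknown residue in peptide: ", peptide)
  unname(m)
}

#' Theoretical b/y fragment ions of a peptide
#'
#' Singly charged b and y ions for the full ladder; doubly charged ions are
#' added when the precursor charge is 3 or higher. The complementarity
#' identity b_i + y_(n-i) = M + 2 x 1.007276 holds exactly for the singly
#' charged series.
#'
#' @param peptide (modified) peptide string
#' @param charge precursor charge
#' @return data.table with columns `series` ("b"/"y"), `index`, `z`, `mz`,
#'   sorted by `mz`
#' @export
theoretical_fragments <- function(peptide, charge = 2L) {
  m <- residue_masses(peptide)
  n <- length(m)
  if (n < 2) return(data.table::data.table(series = character(0), index = integer(0),
                                           z = integer(0), mz = numeric(0)))
  bsum <- cumsum(m)[-n]
  ysum <- cumsum(rev(m))[-n]   # y_i = sum of the C-terminal i residues
  frag_z <- if (charge >= 3L) 1:2 else 1L
  out <- data.table::rbindlist(lapply(frag_z, function(z) {
    data.table::data.table(
      series = rep(c("b", "y"), each = n - 1L),
      index = rep(seq_len(n - 1L), 2L),
      z = z,
      mz = c((bsum + z * PROTON_MASS) / z,
             (ysum + WATER_MASS + z * PROTON_MASS) / z))
  }))
  data.table::setorderv(out, "mz")
  out
}

#' Hyperscore-style match score
#'
#' Observed intensities are normalized so the base peak is 100; each
#' observed fragment is matched to at most one theoretical ion (the nearest
#' within `fragment_tolerance`, each theoretical ion consumed once). The
#' score is ln of (summed matched intensity) x Nb! x Ny! with both
#' factorials capped at 20!, and 0 when nothing matches.
#'
#' @param pseudospectrum a `Pseudospectrum`
#' @param peptide (modified) peptide string
#' @param charge precursor charge used for the theoretical ladder
#' @param fragment_tolerance Da
#' @return list with `score`, `n_b`, `n_y`, `matched` (indices into the
#'   pseudospectrum fragment list)
#' @export
score_match <- function(pseudospectrum, peptide, charge = NULL,
                        fragment_tolerance = 0.02) {
  charge <- charge %||% pseudospectrum$charge
  theo <- theoretical_fragments(peptide, charge)
  obs_mz <- pseudospectrum$fragment_mz
  obs_int <- pseudospectrum$fragment_intensity
  if (!length(obs_mz) || !nrow(theo))
    return(list(score = 0, n_b = 0L, n_y = 0L, matched = integer(0)))
  obs_int <- obs_int / max(obs_int) * 100
  # candidate (obs, theo) pairs within tolerance, greedy nearest-first
  lo <- findInterval(obs_mz, theo$mz)
  cand <- data.table::data.table(obs = rep(seq_along(obs_mz), 2L),
                                 tpos = c(lo, lo + 1L))
  cand <- cand[tpos >= 1L & tpos <= nrow(theo)]
  cand[, dist := abs(obs_mz[obs] - theo$mz[tpos])]
  cand <- cand[dist <= fragment_tolerance]
  if (!nrow(cand)) return(list(score = 0, n_b = 0L, n_y = 0L, matched = integer(0)))
  data.table::setorderv(cand, c("dist", "obs"))
  used_o <- logical(length(obs_mz)); used_t <- logical(nrow(theo))
  m_obs <- integer(0); m_theo <- integer(0)
  for (r in seq_len(nrow(cand))) {
    o <- cand$obs[r]; t <- cand$tpos[r]
    if (!used_o[o] && !used_t[t]) {
      used_o[o] <- TRUE; used_t[t] <- TRUE
      m_obs <- c(m_obs, o); m_theo <- c(m_theo, t)
    }
  }
  n_b <- length(unique(theo$index[m_theo][theo$series[m_theo] == "b"]))
  n_y <- length(unique(theo$index[m_theo][theo$series[m_theo] == "y"]))
  s <- log(sum(obs_int[m_obs])) + lfactorial(min(n_b, 20L)) + lfactorial(min(n_y, 20L))
  list(score = s, n_b = n_b, n_y = n_y, matched = sort(m_obs))
}

#' Generate reversed decoy proteins
#'
#' Full-sequence reversal with the decoy prefix prepended to the ID; one
#' decoy per target, so target and decoy search spaces are the same size.
#'
#' @param proteins data.table with `protein_id`, `sequence`
#' @param decoy_prefix prefix string
#' @return data.table of decoy records
#' @export
make_decoys <- function(proteins, decoy_prefix = "DECOY_") {
  rev_seq <- vapply(strsplit(proteins$sequence, "", fixed = TRUE),
                    function(x) paste(rev(x), collapse = ""), "")
  data.table::data.table(protein_id = paste0(decoy_prefix, proteins$protein_id),
                         sequence = rev_seq)
}

#' Target-decoy FDR filtering with q-values
#'
#' Input is the best-scoring match per pseudospectrum. At a score cutoff s
#' the FDR estimate is (#decoys >= s + 1) / max(#targets >= s, 1); the
#' q-value of a match is the minimum estimate over all cutoffs at or below
#' its score (a running minimum from low to high score), which makes
#' q-values monotone non-increasing in score. Targets with q-value <=
#' `threshold` are accepted.
#'
#' @param matches data.table with at least `score` and `is_decoy`
#' @param threshold FDR threshold in (0, 1)
#' @return list with `matches` (input plus `q_value`) and `accepted`
#'   (accepted target rows)
#' @export
fdr_filter <- function(matches, threshold = 0.01) {
  if (!nrow(matches)) {
    m <- data.table::copy(matches)[, q_value := numeric(0)]
    return(list(matches = m, accepted = m))
  }
  m <- data.table::copy(matches)
  cuts <- sort(unique(m$score))
  n_dec <- vapply(cuts, function(s) sum(m$is_decoy & m$score >= s), numeric(1))
  n_tar <- vapply(cuts, function(s) sum(!m$is_decoy & m$score >= s), numeric(1))
  fdr_hat <- (n_dec + 1) / pmax(n_tar, 1)
  q_at_cut <- cummin(fdr_hat)          # running min from low to high score
  m[, q_value := pmin(q_at_cut[match(score, cuts)], 1)]
  list(matches = m,
       accepted = m[is_decoy == FALSE & q_value <= threshold])
}

# Build the searchable peptide index: digest targets + decoys, expand
# oxidation variants, attach target protein ids, sort by neutral mass.
build_peptide_index <- function(proteins, digest_cfg = digest_defaults(),
                                decoy_prefix = "DECOY_") {
  decoys <- make_decoys(proteins, decoy_prefix)
  all_prot <- rbind(proteins[, .(protein_id, sequence)],
                    decoys[, .(protein_id, sequence)])
  pep_list <- lapply(seq_len(nrow(all_prot)), function(i)
    digest(all_prot$sequence[i], digest_cfg$missed_cleavages,
           digest_cfg$min_length, digest_cfg$max_length))
  dt <- data.table::data.table(
    protein_id = rep(all_prot$protein_id, lengths(pep_list)),
    peptide = unlist(pep_list))
  dt[, from_decoy := startsWith(protein_id, decoy_prefix)]
  idx <- dt[, .(
    is_decoy = all(from_decoy),
    protein_ids = paste(sort(protein_id[!from_decoy]), collapse = ";")
  ), by = peptide]
  # oxidation variants: one modified form per methionine position
  variants <- idx[, {
    pep <- peptide
    forms <- pep
    if (isTRUE(digest_cfg$oxidation)) {
      mpos <- gregexpr("M", pep, fixed = TRUE)[[1]]
      if (mpos[1] != -1) {
        forms <- c(forms, vapply(mpos, function(p)
          paste0(substr(pep, 1, p - 1), "M(ox)",
                 substr(pep, p + 1, nchar(pep))), ""))
      }
    }
    .(modpep = forms)
  }, by = .(peptide, is_decoy, protein_ids)]
  variants[, mass := peptide_neutral_mass(modpep)]
  data.table::setorderv(variants, "mass")
  variants
}

#' Search pseudospectra against a protein database
#'
#' Digests targets and reversed decoys, indexes candidate peptides by
#' neutral mass, scores every candidate within the parent tolerance window
#' against each pseudospectrum, keeps the best match per pseudospectrum
#' (ties broken toward targets, then lexicographically), and applies
#' target-decoy FDR filtering.
#'
#' @param pseudospectra list of `Pseudospectrum`
#' @param proteins data.table with `protein_id`, `sequence` (targets)
#' @param digest_cfg see [digest_defaults()]
#' @param search_cfg see [search_defaults()]
#' @param index optional precomputed peptide index (from repeated searches)
#' @return list with `accepted` (FDR-accepted target matches), `matches`
#'   (best match per spectrum with q-values), `index`
#' @export
search_run <- function(pseudospectra, proteins,
                       digest_cfg = digest_defaults(),
                       search_cfg = search_defaults(),
                       index = NULL) {
  digest_cfg <- utils::modifyList(digest_defaults(), digest_cfg)
  search_cfg <- utils::modifyList(search_defaults(), search_cfg)
  empty <- data.table::data.table(
    spectrum_id = character(0), peptide = character(0), base_peptide = character(0),
    charge = integer(0), score = numeric(0), is_decoy = logical(0),
    protein_ids = character(0), n_matched = integer(0), q_value = numeric(0))
  if (!length(pseudospectra))
    return(list(accepted = empty, matches = empty, index = index))
  if (is.null(index))
    index <- build_peptide_index(proteins, digest_cfg, search_cfg$decoy_prefix)
  masses <- index$mass
  rows <- vector("list", length(pseudospectra))
  for (k in seq_along(pseudospectra)) {
    ps <- pseudospectra[[k]]
    obs_mass <- ps$charge * (ps$precursor_mz - PROTON_MASS)
    tol <- obs_mass * search_cfg$parent_tolerance * 1e-6
    lo <- findInterval(obs_mass - tol, masses) + 1L
    hi <- findInterval(obs_mass + tol, masses)
    if (hi < lo) next
    cand <- index[lo:hi]
    best <- NULL
    for (i in seq_len(nrow(cand))) {
      sc <- score_match(ps, cand$modpep[i], ps$charge,
                        search_cfg$fragment_tolerance)
      if (sc$score <= 0) next
      better <- is.null(best) ||
        sc$score > best$score ||
        (sc$score == best$score && best$is_decoy && !cand$is_decoy[i]) ||
        (sc$score == best$score && best$is_decoy == cand$is_decoy[i] &&
           cand$modpep[i] < best$peptide)
      if (better) {
        best <- list(peptide = cand$modpep[i], base = cand$peptide[i],
                     score = sc$score, is_decoy = cand$is_decoy[i],
                     protein_ids = cand$protein_ids[i],
                     n_matched = length(sc$matched))
      }
    }
    if (!is.null(best)) {
      rows[[k]] <- data.table::data.table(
        spectrum_id = ps$provenance, peptide = best$peptide,
        base_peptide = best$base, charge = ps$charge, score = best$score,
        is_decoy = best$is_decoy, protein_ids = best$protein_ids,
        n_matched = best$n_matched)
    }
  }
  matches <- data.table::rbindlist(Filter(Negate(is.null), rows))
  if (!nrow(matches))
    return(list(accepted = empty, matches = empty, index = index))
  res <- fdr_filter(matches, search_cfg$fdr_threshold)
  list(accepted = res$accepted, matches = res$matches, index = index)
}

#' Write search results as TSV
#' @param matches data.table from [search_run()]
#' @param path output file
#' @param header optional comment header lines (prefixed with `#`)
#' @export
write_search_results <- function(matches, path, header = NULL) {
  con <- file(path, "wt"); on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  utils::write.table(matches, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
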