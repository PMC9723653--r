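# Ground-truth simulator: synthetic microbial community (FASTA +
# annotations) and DIA acquisitions with the survey/window geometry of a
# 40 x 15 m/z SWATH-style scheme, plus a complete truth manifest.

#' Default acquisition geometry
#'
#' MS1 survey scans of 375–1500 m/z interleaved with 40 consecutive 15 m/z
#' isolation windows covering 400–1000 m/z. Desk-scale chromatography:
#' 3 s cycle, 600 s gradient, Gaussian elution with sigma 6 s. Noise is a
#' Poisson number of uniform-m/z peaks per scan; fragment dropout is the
#' per-peak probability that a fragment peak fails to register.
#'
#' @param ... overrides for individual fields
#' @return named list (class `AcquisitionSpec`)
#' @export
acquisition_spec <- function(...) {
  spec <- list(ms1_range = c(375, 1500), dia_start = 400, dia_end = 1000,
               dia_width = 15, cycle_time = 3, gradient_length = 600,
               peak_sigma = 6, noise_rate = 20, noise_meanlog = log(30),
               ms2_range = c(100, 1500), dropout = 0.05,
               intensity_floor = 1)
  spec <- utils::modifyList(spec, list(...))
  stopifnot(all(unlist(spec[c("dia_width", "cycle_time", "gradient_length",
                              "peak_sigma")]) > 0))
  spec$scheme <- build_window_scheme(spec$dia_start, spec$dia_end, spec$dia_width)
  class(spec) <- "AcquisitionSpec"
  spec
}

default_taxa <- function() {
  data.table::data.table(
    phylum = c("Bacteroidetes", "Bacteroidetes", "Actinobacteria",
               "Actinobacteria", "Proteobacteria", "Firmicutes",
               "Bacteroidetes", "Bacteroidetes", "Actinobacteria",
               "Firmicutes", "Firmicutes", "Actinobacteria"),
    genus = c("Bacteroides", "Parabacteroides", "Enterorhabdus",
              "Bifidobacterium", "Escherichia", "Streptococcus",
              "Prevotella", "Alistipes", "Collinsella",
              "Clostridium", "Eubacterium", "Adlercreutzia"),
    weight = rep(1, 12))
}

default_kegg <- function() {
  data.table::data.table(
    category = c("Carbohydrate metabolism", "Translation",
                 "Energy metabolism", "Amino acid metabolism",
                 "Nucleotide metabolism", "Membrane transport"),
    weight = c(0.30, 0.15, 0.10, 0.20, 0.10, 0.15))
}

# one random tryptic peptide: internal residues exclude K/R/P-start, ends
# K or R, 2+ precursor inside the DIA range, ladder fragments resolvable
random_tryptic_peptide <- function(acq, min_len = 8L, max_len = 16L) {
  inner_pool <- setdiff(names(AA_MONO), c("K", "R"))
  repeat {
    len <- sample(min_len:max_len, 1L)
    body <- sample(inner_pool, len - 1L, replace = TRUE)
    if (body[1] == "P") next
    pep <- paste0(paste(body, collapse = ""), sample(c("K", "R"), 1L))
    mass <- peptide_neutral_mass(pep)
    mz2 <- (mass + 2 * PROTON_MASS) / 2
    if (mz2 < acq$dia_start + 2 || mz2 >= acq$dia_end - 2) next
    frag <- theoretical_fragments(pep, 2L)
    frag <- frag$mz[frag$mz >= acq$ms2_range[1] & frag$mz <= acq$ms2_range[2]]
    if (length(frag) < 6) next
    # resolvable ladder: fragments separated well beyond the 0.02 Da
    # matching tolerance, so distinct ions yield distinct traces
    if (min(diff(sort(frag))) < 0.05) next
    return(pep)
  }
}

#' Generate a synthetic microbial community
#'
#' Builds random protein sequences as concatenations of tryptic peptide
#' blocks, a protein annotation table (phylum, genus, KEGG category), and a
#' truth-manifest skeleton listing every planted peptide with its source
#' proteins, taxon, function, charge, precursor m/z, fragment ladder and
#' abundance. A `shared_fraction` of peptides is additionally inserted into
#' a protein of a different genus to exercise ambiguous annotation.
#'
#' Everything is deterministic given `seed`.
#'
#' @param taxa data.table of `phylum`, `genus`, `weight` (default: a
#'   12-strain gut community)
#' @param proteins_per_taxon proteins per taxon
#' @param peptides_per_protein planted peptide blocks per protein
#' @param shared_fraction fraction of peptides shared across two genera
#' @param unannotated_fraction fraction of proteins left unannotated
#' @param kegg KEGG category weights (data.table `category`, `weight`)
#' @param acq an `AcquisitionSpec` (geometry constrains peptide masses)
#' @param charge3_fraction fraction of planted precursors at 3+
#' @param abundance_meanlog,abundance_sdlog log-normal abundance model
#' @param seed random seed (mandatory for reproducibility)
#' @return list (class `Community`): `proteins`, `annotations`, `manifest`,
#'   `taxa`, `acq`, `seed`
#' @export
generate_community <- function(taxa = default_taxa(), proteins_per_taxon = 20L,
                               peptides_per_protein = 8L, shared_fraction = 0.1,
                               unannotated_fraction = 0, kegg = default_kegg(),
                               acq = acquisition_spec(),
                               charge3_fraction = 0.1,
                               abundance_meanlog = log(2e4),
                               abundance_sdlog = 1.0,
                               seed) {
  if (missing(seed)) stop("generate_community requires an explicit seed")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed)

  n_taxa <- nrow(taxa)
  prot_rows <- list(); pep_rows <- list()
  seen_pep <- new.env(hash = TRUE)
  for (t in seq_len(n_taxa)) {
    for (p in seq_len(proteins_per_taxon)) {
      pid <- sprintf("%s_P%03d", substr(taxa$genus[t], 1, 4), (t - 1L) * proteins_per_taxon + p)
      peps <- character(peptides_per_protein)
      for (k in seq_len(peptides_per_protein)) {
        repeat {
          cand <- random_tryptic_peptide(acq)
          if (is.null(seen_pep[[cand]])) { assign(cand, TRUE, seen_pep); break }
        }
        peps[k] <- cand
      }
      cat_k <- sample(kegg$category, 1L, prob = kegg$weight)
      prot_rows[[length(prot_rows) + 1L]] <- data.table::data.table(
        protein_id = pid, taxon = t, kegg_category = cat_k,
        peptides = list(peps))
      pep_rows[[length(pep_rows) + 1L]] <- data.table::data.table(
        sequence = peps, protein_id = pid, taxon = t, kegg_category = cat_k)
    }
  }
  prot <- data.table::rbindlist(prot_rows)
  peps <- data.table::rbindlist(pep_rows)

  # shared peptides: re-insert a Bernoulli(shared_fraction) subset into one
  # protein of a different genus
  shared <- runif(nrow(peps)) < shared_fraction
  for (i in which(shared)) {
    other <- which(prot$taxon != peps$taxon[i])
    j <- sample(other, 1L)
    prot$peptides[[j]] <- c(prot$peptides[[j]], peps$sequence[i])
  }
  prot[, sequence := vapply(peptides, paste, "", collapse = "")]

  # protein -> peptide containment after sharing
  containment <- prot[, .(sequence_pep = peptides[[1]]), by = protein_id]
  data.table::setnames(containment, "sequence_pep", "pep")
  pep_prot <- containment[, .(protein_ids = paste(sort(protein_id), collapse = ";")),
                          by = pep]

  manifest <- peps[, .(sequence, origin_protein = protein_id, taxon, kegg_category)]
  manifest[, `:=`(phylum = taxa$phylum[taxon], genus = taxa$genus[taxon])]
  manifest <- merge(manifest, pep_prot, by.x = "sequence", by.y = "pep", sort = FALSE)
  manifest[, shared := shared]
  manifest[, charge := ifelse(runif(.N) < charge3_fraction, 3L, 2L)]
  manifest[, mass := peptide_neutral_mass(sequence)]
  manifest[, mz := (mass + charge * PROTON_MASS) / charge]
  # 3+ precursors of short peptides can fall below the DIA range; keep 2+
  manifest[mz < acq$dia_start | mz >= acq$dia_end, `:=`(charge = 2L)]
  manifest[, mz := (mass + charge * PROTON_MASS) / charge]
  manifest[, window := window_for_mz(acq$scheme, mz)]
  manifest[, abundance := rlnorm(.N, abundance_meanlog, abundance_sdlog) *
             taxa$weight[taxon] / max(taxa$weight)]
  manifest[, fragments := lapply(seq_len(.N), function(i) {
    fr <- theoretical_fragments(sequence[i], 2L)
    mz_ok <- fr$mz >= acq$ms2_range[1] & fr$mz <= acq$ms2_range[2]
    fmz <- fr$mz[mz_ok]
    rel <- pmin(pmax(rlnorm(length(fmz), 0, 0.6), 0.05), 1)
    rel <- rel / max(rel)
    list(mz = fmz, relint = rel)
  })]

  annotations <- prot[, .(protein_id, phylum = taxa$phylum[taxon],
                          genus = taxa$genus[taxon], kegg_category)]
  if (unannotated_fraction > 0) {
    blank <- runif(nrow(annotations)) < unannotated_fraction
    annotations[blank, `:=`(phylum = NA_character_, genus = NA_character_,
                            kegg_category = NA_character_)]
  }

  structure(list(
    proteins = prot[, .(protein_id, sequence)],
    annotations = annotations,
    manifest = manifest,
    taxa = taxa, acq = acq, seed = seed), class = "Community")
}

#' Assign elution apexes to the planted peptides
#'
#' Either uniformly at random over the usable gradient (co-eluting, the
#' realistic default) or stratified per isolation window with apexes spaced
#' at least `min_spacing_sigmas` elution sigmas apart (the idealized
#' non-co-eluting layout used by exact-recovery checks).
#'
#' @param community a `Community`
#' @param co_elution allow random co-elution (default TRUE)
#' @param min_spacing_sigmas spacing between apexes in the same window for
#'   the non-co-eluting layout
#' @param seed layout seed (defaults to the community seed)
#' @return the community with `manifest$apex_rt` filled in
#' @export
assign_apexes <- function(community, co_elution = TRUE,
                          min_spacing_sigmas = 8, seed = community$seed) {
  acq <- community$acq
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(seed + 1L)
  margin <- 4 * acq$peak_sigma
  usable <- c(margin, acq$gradient_length - margin)
  man <- community$manifest
  if (co_elution) {
    man[, apex_rt := runif(.N, usable[1], usable[2])]
  } else {
    man[, apex_rt := NA_real_]
    for (w in unique(man$window)) {
      idx <- which(man$window == w)
      spacing <- max(min_spacing_sigmas * acq$peak_sigma,
                     diff(usable) / length(idx))
      if (spacing * length(idx) > diff(usable))
        stop(sprintf(
          "window %d holds %d peptides; gradient too short for non-co-eluting layout",
          w, length(idx)))
      slots <- usable[1] + spacing * (seq_along(idx) - 0.5)
      man[idx, apex_rt := slots[sample.int(length(idx))]]
    }
  }
  community$manifest <- man
  community
}

#' Simulate one DIA acquisition of a community
#'
#' Each planted peptide elutes as a Gaussian profile around its apex; MS1
#' survey scans carry the monoisotopic peak plus an M+1 isotope companion
#' (half intensity) for charge estimation; the MS2 scans of the precursor's
#' isolation window carry the b/y ladder scaled by the same elution profile
#' with per-peak dropout. A Poisson number of uniform-m/z noise peaks is
#' added to every scan. Cycles interleave one MS1 survey with one MS2 scan
#' per isolation window.
#'
#' @param community a `Community` with apexes assigned (see
#'   [assign_apexes()]; called automatically when missing)
#' @param run_id run identifier
#' @param run_seed seed for this run's noise, jitter and dropout
#' @param rt_shift global retention-time shift of this run (seconds)
#' @param abundance_scale multiplies all planted abundances
#' @param jitter_sigma per-peptide log-normal abundance jitter (0 = exact
#'   technical replicate)
#' @param noise include noise peaks (and dropout) at the acquisition spec's
#'   rates; FALSE forces both to zero
#' @return list with `run` (a `SpectraRun`) and `manifest` (per-run truth:
#'   shifted apexes, jittered abundances)
#' @export
simulate_run <- function(community, run_id = "run1", run_seed = 1L,
                         rt_shift = 0, abundance_scale = 1,
                         jitter_sigma = 0, noise = TRUE) {
  acq <- community$acq
  man <- data.table::copy(community$manifest)
  if (!"apex_rt" %in% names(man) || anyNA(man$apex_rt))
    stop("community has no elution apexes; call assign_apexes() first")
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  set.seed(run_seed)

  man[, apex_rt := apex_rt + rt_shift]
  jit <- if (jitter_sigma > 0) rlnorm(nrow(man), 0, jitter_sigma) else rep(1, nrow(man))
  man[, run_abundance := abundance * abundance_scale * jit]
  noise_rate <- if (noise) acq$noise_rate else 0
  dropout <- if (noise) acq$dropout else 0

  scheme <- acq$scheme
  n_win <- nrow(scheme$windows)
  cycle_starts <- seq(0, acq$gradient_length, by = acq$cycle_time)
  spectra <- vector("list", length(cycle_starts) * (n_win + 1L))
  si <- 0L
  sigma <- acq$peak_sigma
  active_span <- 4 * sigma

  add_noise <- function(mz_range) {
    k <- if (noise_rate > 0) rpois(1L, noise_rate) else 0L
    if (k == 0L) return(list(mz = numeric(0), int = numeric(0)))
    list(mz = runif(k, mz_range[1], mz_range[2]),
         int = rlnorm(k, acq$noise_meanlog, 1))
  }

  for (t0 in cycle_starts) {
    # MS1 survey
    act <- which(abs(man$apex_rt - t0) <= active_span)
    g <- man$run_abundance[act] *
      exp(-(t0 - man$apex_rt[act])^2 / (2 * sigma^2))
    on_peaks <- g >= acq$intensity_floor
    act <- act[on_peaks]; g <- g[on_peaks]
    nz <- add_noise(acq$ms1_range)
    mz1 <- c(man$mz[act], man$mz[act] + ISOTOPE_SPACING / man$charge[act], nz$mz)
    int1 <- c(g, 0.5 * g, nz$int)
    inr <- mz1 >= acq$ms1_range[1] & mz1 <= acq$ms1_range[2]
    si <- si + 1L
    spectra[[si]] <- spectrum_record(1L, t0, mz1[inr], int1[inr])
    # MS2 per window
    for (w in seq_len(n_win)) {
      rt <- t0 + w * acq$cycle_time / (n_win + 1)
      act2 <- which(man$window == w & abs(man$apex_rt - rt) <= active_span)
      mzs <- numeric(0); ints <- numeric(0)
      for (i in act2) {
        gi <- man$run_abundance[i] *
          exp(-(rt - man$apex_rt[i])^2 / (2 * sigma^2))
        if (gi < acq$intensity_floor) next
        fr <- man$fragments[[i]]
        keep <- if (dropout > 0) runif(length(fr$mz)) >= dropout
                else rep(TRUE, length(fr$mz))
        fi <- gi * fr$relint[keep]
        ok <- fi >= acq$intensity_floor
        mzs <- c(mzs, fr$mz[keep][ok]); ints <- c(ints, fi[ok])
      }
      nz <- add_noise(acq$ms2_range)
      si <- si + 1L
      spectra[[si]] <- spectrum_record(2L, rt, c(mzs, nz$mz), c(ints, nz$int),
                                       window = c(scheme$windows$lower[w],
                                                  scheme$windows$upper[w]))
    }
  }
  run <- spectra_run(run_id, spectra[seq_len(si)], scheme = scheme)
  list(run = run, manifest = man)
}

#' Simulate replicate DIA runs
#'
#' Same community and elution layout in every run; per-run abundances are
#' multiplied by log-normal jitter (`jitter_sigma = 0` gives technical
#' replicates that differ only in noise).
#'
#' @param community a `Community` with apexes assigned
#' @param n number of replicates
#' @param jitter_sigma log-normal abundance jitter between replicates
#' @param rt_shifts per-run RT shifts (seconds), recycled
#' @param seed base seed; run i uses `seed + i`
#' @param ... passed to [simulate_run()]
#' @return list of [simulate_run()] results
#' @export
replicate_runs <- function(community, n = 3L, jitter_sigma = 0,
                           rt_shifts = 0, seed = community$seed, ...) {
  rt_shifts <- rep_len(rt_shifts, n)
  lapply(seq_len(n), function(i)
    simulate_run(community, run_id = sprintf("rep%d", i),
                 run_seed = seed + i, rt_shift = rt_shifts[i],
                 jitter_sigma = jitter_sigma, ...))
}

#' Compare recovered pseudospectra with the truth manifest
#'
#' Matches every manifest peptide to the nearest pseudospectrum of the same
#' charge within `ppm` of its planted precursor m/z and within
#' `rt_tolerance` of its apex, and reports per-peptide fragment recovery.
#'
#' @param pseudospectra list of `Pseudospectrum`
#' @param manifest per-run manifest (from [simulate_run()])
#' @param ppm precursor matching tolerance
#' @param rt_tolerance apex matching tolerance (seconds)
#' @param fragment_tolerance Da tolerance for fragment recovery
#' @return data.table with one row per planted peptide: `recovered`,
#'   `n_fragments_planted`, `n_fragments_recovered`
#' @export
recovery_stats <- function(pseudospectra, manifest, ppm = 10,
                           rt_tolerance = 10, fragment_tolerance = 0.02) {
  ps_mz <- vapply(pseudospectra, `[[`, numeric(1), "precursor_mz")
  ps_rt <- vapply(pseudospectra, `[[`, numeric(1), "rt")
  rows <- lapply(seq_len(nrow(manifest)), function(i) {
    mz <- manifest$mz[i]
    tol <- mz * ppm * 1e-6
    hit <- which(abs(ps_mz - mz) <= tol &
                   abs(ps_rt - manifest$apex_rt[i]) <= rt_tolerance)
    planted <- manifest$fragments[[i]]$mz
    if (!length(hit))
      return(data.table::data.table(sequence = manifest$sequence[i],
                                    recovered = FALSE,
                                    n_fragments_planted = length(planted),
                                    n_fragments_recovered = 0L))
    best <- hit[which.min(abs(ps_mz[hit] - mz))]
    obs <- pseudospectra[[best]]$fragment_mz
    nrec <- sum(vapply(planted, function(f)
      any(abs(obs - f) <= fragment_tolerance), logical(1)))
    data.table::data.table(sequence = manifest$sequence[i], recovered = TRUE,
                           n_fragments_planted = length(planted),
                           n_fragments_recovered = as.integer(nrec))
  })
  data.table::rbindlist(rows)
}

#' Ground-truth library from a manifest
#'
#' Builds a pseudospectral-library table directly from the truth manifest
#' (top fragments by planted relative intensity), bypassing deconvolution
#' and search. Used to exercise the quantification stage in isolation.
#'
#' @param community a `Community` with apexes assigned
#' @param top_n fragments kept per entry
#' @return library data.table in the [build_library()] dialect
#' @export
manifest_library <- function(community, top_n = 6L) {
  man <- community$manifest
  if (!"apex_rt" %in% names(man)) stop("assign_apexes() first")
  rows <- lapply(seq_len(nrow(man)), function(i) {
    fr <- man$fragments[[i]]
    keep <- utils::head(order(-fr$relint), top_n)
    keep <- keep[order(fr$mz[keep])]
    data.table::data.table(
      peptide = man$sequence[i], charge = man$charge[i],
      precursor_mz = man$mz[i], reference_rt = man$apex_rt[i],
      fragment_mz = paste(sprintf("%.4f", fr$mz[keep]), collapse = ";"),
      fragment_intensity = paste(sprintf("%.3f", fr$relint[keep] / max(fr$relint[keep])),
                                 collapse = ";"),
      protein_ids = man$protein_ids[i])
  })
  out <- data.table::rbindlist(rows)
  data.table::setorderv(out, c("peptide", "charge"))
  out
}

#' Write the truth manifest as JSON
#' @param manifest manifest data.table
#' @param path output file
#' @export
write_manifest <- function(manifest, path) {
  out <- lapply(seq_len(nrow(manifest)), function(i) {
    m <- manifest[i]
    list(sequence = m$sequence, protein_ids = m$protein_ids,
         phylum = m$phylum, genus = m$genus, kegg_category = m$kegg_category,
         charge = m$charge, mz = m$mz,
         apex_rt = if ("apex_rt" %in% names(m)) m$apex_rt else NULL,
         abundance = m$abundance,
         fragment_mz = m$fragments[[1]]$mz,
         fragment_relint = m$fragments[[1]]$relint)
  })
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
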