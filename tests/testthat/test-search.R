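# search: digestion, masses, fragment ladders, scoring, decoys, FDR.

test_that("digest applies the trypsin rule", {
  expect_setequal(digest("MKAARPK", missed_cleavages = 0L, min_length = 1L),
                  c("MK", "AARPK"))
  expect_setequal(digest("AAAKBBBK", missed_cleavages = 1L, min_length = 1L),
                  c("AAAK", "BBBK", "AAAKBBBK"))
  # X-containing peptides are excluded
  expect_setequal(digest("AAXKCCCK", missed_cleavages = 1L, min_length = 1L),
                  c("CCCK"))
  expect_equal(digest(""), character(0))
})

test_that("digest equals the brute-force substring oracle", {
  set.seed(21)
  for (i in 1:30) {
    prot <- random_protein(150)
    for (mc in 0:2) {
      expect_setequal(digest(prot, mc, 7L, 50L), brute_digest(prot, mc, 7L, 50L))
    }
    expect_setequal(digest(prot, 2L, 1L, 12L), brute_digest(prot, 2L, 1L, 12L))
  }
})

test_that("peptide masses match the independent monoisotopic calculator", {
  # frozen from an independent residue-table + water computation
  expect_equal(peptide_neutral_mass("PEPTIDE"), 799.35995, tolerance = 1e-4)
  expect_equal(peptide_neutral_mass("SAMPLER"), 802.40072, tolerance = 1e-4)
  # fixed carbamidomethyl on C, variable oxidation on M
  expect_equal(peptide_neutral_mass("ACDK") - peptide_neutral_mass("ADDK"),
               103.00919 + 57.02146 - 115.02694, tolerance = 1e-5)
  expect_equal(peptide_neutral_mass("AM(ox)DK") - peptide_neutral_mass("AMDK"),
               15.99491, tolerance = 1e-5)
  expect_error(peptide_neutral_mass("AB1K"), "unknown residue")
})

test_that("theoretical fragments: frozen b/y values and the complementarity identity", {
  fr <- theoretical_fragments("SAMPLER", 2L)
  b <- fr[series == "b"][order(index)]$mz
  y <- fr[series == "y"][order(index)]$mz
  expect_equal(b, c(88.03931, 159.07642, 290.11691, 387.16967, 500.25373,
                    629.29632), tolerance = 1e-4)
  expect_equal(y, c(175.11895, 304.16154, 417.2456, 514.29836, 645.33885,
                    716.37596), tolerance = 1e-4)
  # b1 of P... = proline residue + proton
  expect_equal(theoretical_fragments("PEPTIDE", 2L)[series == "b" & index == 1]$mz,
               97.05276 + 1.007276, tolerance = 1e-5)
  # identity b_i + y_(n-i) = M + 2 protons, all ladders
  set.seed(22)
  aa <- setdiff(names(metadia:::AA_MONO), character(0))
  for (i in 1:20) {
    pep <- paste(sample(aa, sample(7:15, 1), replace = TRUE), collapse = "")
    fr <- theoretical_fragments(pep, 2L)
    M <- peptide_neutral_mass(pep)
    n <- nchar(pep)
    b <- fr[series == "b"][order(index)]$mz
    y <- fr[series == "y"][order(index)]$mz
    expect_equal(b + rev(y), rep(M + 2 * 1.007276, n - 1), tolerance = 1e-9)
  }
  # charge >= 3 adds doubly charged fragments
  expect_equal(nrow(theoretical_fragments("SAMPLER", 3L)),
               2 * nrow(theoretical_fragments("SAMPLER", 2L)))
})

test_that("score_match reproduces the closed-form hyperscore", {
  fr <- theoretical_fragments("SAMPLER", 2L)
  ps <- metadia:::new_pseudospectrum(
    (peptide_neutral_mass("SAMPLER") + 2 * 1.007276) / 2, 2L, 10,
    fr$mz, rep(50, nrow(fr)), provenance = "s1")
  sc <- score_match(ps, "SAMPLER", 2L)
  # all 12 ions matched at normalized intensity 100:
  # ln(1200) + ln(6!) + ln(6!) computed independently
  expect_equal(sc$n_b, 6); expect_equal(sc$n_y, 6)
  expect_equal(sc$score, 20.24858, tolerance = 1e-4)

  # nothing within tolerance -> 0
  ps0 <- metadia:::new_pseudospectrum(ps$precursor_mz, 2L, 10,
                                      fr$mz + 0.5, rep(50, nrow(fr)))
  expect_equal(score_match(ps0, "SAMPLER", 2L)$score, 0)

  # an unmatched noise peak never increases the score
  set.seed(23)
  for (i in 1:10) {
    noise_mz <- runif(1, 100, 1500)
    if (any(abs(fr$mz - noise_mz) < 0.05)) next
    psn <- metadia:::new_pseudospectrum(ps$precursor_mz, 2L, 10,
                                        c(fr$mz, noise_mz),
                                        c(rep(50, nrow(fr)), runif(1, 1, 500)))
    expect_lte(score_match(psn, "SAMPLER", 2L)$score, sc$score)
  }
})

test_that("decoy generation reverses sequences and preserves digest size", {
  prot <- data.table::data.table(protein_id = "P1", sequence = "ABCK")
  d <- make_decoys(prot)
  expect_equal(d$protein_id, "DECOY_P1")
  expect_equal(d$sequence, "KCBA")
  # decoy of decoy restores the original
  expect_equal(make_decoys(d, "X_")$sequence, "ABCK")

  set.seed(24)
  db <- data.table::data.table(protein_id = sprintf("P%d", 1:20),
                               sequence = replicate(20, random_protein(300, p_x = 0)))
  n_t <- length(unique(unlist(lapply(db$sequence, digest))))
  n_d <- length(unique(unlist(lapply(make_decoys(db)$sequence, digest))))
  expect_lt(abs(n_t - n_d) / n_t, 0.05)
})

test_that("fdr_filter matches brute-force FDR over all cutoffs", {
  m <- data.table::data.table(score = c(10, 9, 8, 7, 6, 5),
                              is_decoy = c(FALSE, FALSE, FALSE, FALSE, TRUE, TRUE))
  res <- fdr_filter(m, 0.01)
  # hand-computed: min FDR over cutoffs <= each target score is 0.25
  expect_equal(res$matches[is_decoy == FALSE]$q_value, rep(0.25, 4))
  expect_equal(nrow(res$accepted), 0)

  # boundary: 99 targets at 10, 1 decoy at 5 -> q = 1/99 > 0.01, none pass
  m2 <- data.table::data.table(score = c(rep(10, 99), 5),
                               is_decoy = c(rep(FALSE, 99), TRUE))
  res2 <- fdr_filter(m2, 0.01)
  expect_equal(unique(res2$matches[is_decoy == FALSE]$q_value), 1 / 99)
  expect_equal(nrow(res2$accepted), 0)
  # at 100 targets the same configuration passes (1/100 <= 0.01)
  m3 <- data.table::data.table(score = c(rep(10, 100), 5),
                               is_decoy = c(rep(FALSE, 100), TRUE))
  expect_equal(nrow(fdr_filter(m3, 0.01)$accepted), 100)

  # all decoys -> nothing accepted
  m4 <- data.table::data.table(score = 1:5, is_decoy = TRUE)
  expect_equal(nrow(fdr_filter(m4, 0.01)$accepted), 0)
  expect_equal(nrow(fdr_filter(m4[0], 0.01)$accepted), 0)

  # brute-force oracle on random score sets: q is the running min of the
  # estimator and monotone non-increasing in score
  set.seed(25)
  for (i in 1:10) {
    n <- 50
    mr <- data.table::data.table(score = round(runif(n, 0, 20), 1),
                                 is_decoy = runif(n) < 0.4)
    q <- fdr_filter(mr, 0.05)$matches
    for (k in sample(n, 10)) {
      s <- q$score[k]
      cuts <- unique(mr$score[mr$score <= s])
      fdr_at <- vapply(cuts, function(cc)
        (sum(mr$is_decoy & mr$score >= cc) + 1) /
          max(sum(!mr$is_decoy & mr$score >= cc), 1), 0)
      expect_equal(q$q_value[k], min(c(fdr_at, 1)), tolerance = 1e-12)
    }
    o <- order(q$score)
    expect_true(all(diff(q$q_value[o]) <= 1e-12))
  }
})

test_that("search_run identifies synthetic ladders and records proteins", {
  set.seed(26)
  comm <- tiny_community(n_taxa = 4, ppt = 3L, ppp = 3L, seed = 27)
  peps <- comm$manifest$sequence
  ps <- lapply(seq_along(peps), function(i)
    synth_pseudospectrum(peps[i], comm$manifest$charge[i],
                         id = sprintf("s%d", i), dropout = 0.1, n_noise = 3))
  res <- search_run(ps, comm$proteins, search_cfg = list(fdr_threshold = 0.05))
  expect_gt(nrow(res$matches), 0)
  # matched peptides overwhelmingly correct
  ok <- res$matches$base_peptide == peps[as.integer(sub("s", "", res$matches$spectrum_id))]
  expect_gte(mean(ok), 0.95)
  # protein_ids point back at true source proteins
  i1 <- which(res$matches$base_peptide == peps[1])[1]
  expect_true(grepl(strsplit(comm$manifest$protein_ids[1], ";")[[1]][1],
                    res$matches$protein_ids[i1]))
  # q-values: accepted set is a prefix of the score-sorted target list
  tm <- res$matches[is_decoy == FALSE][order(-score)]
  acc_in_order <- tm$q_value <= 0.05
  if (any(!acc_in_order)) {
    expect_true(all(which(acc_in_order) < min(which(!acc_in_order))) ||
                  all(acc_in_order[seq_len(sum(acc_in_order))]))
  }
  expect_equal(nrow(search_run(list(), comm$proteins)$matches), 0)
})
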