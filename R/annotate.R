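# Peptide-centric taxonomic/functional annotation, profile aggregation,
# and the replicate reproducibility metrics.

#' Consensus annotation of one peptide
#'
#' A peptide is assigned to all its possible source proteins; the labels of
#' those proteins at the requested rank decide the peptide label.
#' Unannotated source proteins do not conflict with existing annotations
#' and are ignored. Exactly one annotated label -> that label; none ->
#' `"unknown"`; two or more distinct labels -> `"ambiguous"`.
#'
#' @param protein_ids character vector of source (target) proteins; must be
#'   non-empty
#' @param table an `AnnotationTable`
#' @param rank `"phylum"`, `"genus"` or `"kegg_category"`
#' @return a single label string
#' @export
annotate_peptide <- function(protein_ids, table, rank) {
  if (!length(protein_ids) || all(!nzchar(protein_ids)))
    stop("annotate_peptide requires at least one source protein")
  labels <- annotation_lookup(table, protein_ids, rank)
  labels <- labels[!is.na(labels) & nzchar(labels)]
  u <- unique(labels)
  if (length(u) == 0) "unknown"
  else if (length(u) == 1) u
  else "ambiguous"
}

#' Annotate a peptide table at all ranks
#'
#' @param peptides data.table with columns `peptide` and `protein_ids`
#'   (semicolon-joined source proteins)
#' @param table an `AnnotationTable`
#' @return data.table with `peptide`, `phylum`, `genus`, `kegg_category`
#' @export
annotate_peptides <- function(peptides, table) {
  ids <- strsplit(peptides$protein_ids, ";", fixed = TRUE)
  data.table::data.table(
    peptide = peptides$peptide,
    phylum = vapply(ids, annotate_peptide, "", table, "phylum"),
    genus = vapply(ids, annotate_peptide, "", table, "genus"),
    kegg_category = vapply(ids, annotate_peptide, "", table, "kegg_category"))
}

#' Aggregate labels into a percentage profile
#'
#' Label percentages over all peptides; named labels holding strictly less
#' than `threshold` of the total are merged into `"other"` (a label at
#' exactly the threshold is retained). `"ambiguous"` and `"unknown"` are
#' always reported as their own categories, never merged into `"other"`.
#'
#' @param labels character vector of per-peptide labels
#' @param threshold aggregation threshold as a fraction (default 0.005,
#'   i.e. < 0.5% of total)
#' @return named numeric vector of percentages summing to 100, sorted
#'   descending with `other`, `ambiguous`, `unknown` last
#' @export
build_profile <- function(labels, threshold = 0.005) {
  if (!length(labels)) return(stats::setNames(numeric(0), character(0)))
  counts <- table(labels)
  pct <- 100 * as.numeric(counts) / length(labels)
  names(pct) <- names(counts)
  special <- names(pct) %in% c("ambiguous", "unknown")
  small <- !special & pct < threshold * 100
  out <- pct[!small & !special]
  out <- out[order(-out)]
  if (any(small)) out <- c(out, other = sum(pct[small]))
  out <- c(out, pct[names(pct) == "ambiguous"], pct[names(pct) == "unknown"])
  out
}

#' Peptide-identification overlap between two replicates
#'
#' Shared peptides divided by the total identified in the replicate pair
#' (Jaccard fraction of the union).
#'
#' @param ids_a,ids_b character vectors of peptide identifications
#' @return fraction in `[0, 1]`
#' @export
replicate_overlap <- function(ids_a, ids_b) {
  a <- unique(ids_a); b <- unique(ids_b)
  u <- length(union(a, b))
  if (u == 0) return(NA_real_)
  length(intersect(a, b)) / u
}

#' Pearson correlation of quantifications between two runs
#'
#' Correlation of log10(area + 1) over peptides quantified in both runs.
#'
#' @param mat a `QuantMatrix`
#' @param run_a,run_b column names
#' @return list with `r` and `n_shared`
#' @export
quant_correlation <- function(mat, run_a, run_b) {
  x <- mat[, run_a]; y <- mat[, run_b]
  shared <- which(!is.na(x) & !is.na(y))
  if (length(shared) < 3)
    stop("fewer than 3 peptides quantified in both runs")
  list(r = stats::cor(log10(x[shared] + 1), log10(y[shared] + 1)),
       n_shared = length(shared))
}

#' Genus distribution within one functional category
#'
#' Cross-tabulates the genus labels of the peptides annotated to the named
#' KEGG category; `ambiguous` and `unknown` genera are kept as rows. Counts
#' over all rows equal the number of peptides in the category.
#'
#' @param annotations data.table from [annotate_peptides()]
#' @param category KEGG category name to restrict to
#' @return data.table with `genus`, `n_peptides`, sorted by count
#' @export
genus_by_function_table <- function(annotations, category) {
  sel <- annotations[kegg_category == category]
  if (!nrow(sel))
    return(data.table::data.table(genus = character(0), n_peptides = integer(0)))
  out <- sel[, .(n_peptides = .N), by = genus]
  data.table::setorderv(out, c("n_peptides", "genus"), c(-1, 1))
  out
}

#' Pairwise reproducibility metrics for a set of runs
#'
#' For every run pair: identification overlap (shared / union of peptides
#' quantified) and Pearson correlation of log10 quantities over shared
#' peptides.
#'
#' @param mat a `QuantMatrix`
#' @return data.table with `run_a`, `run_b`, `overlap`, `pearson_r`,
#'   `n_shared`
#' @export
replicate_metrics <- function(mat) {
  runs <- colnames(mat)
  rows <- list()
  if (length(runs) >= 2) {
    for (i in seq_len(length(runs) - 1)) {
      for (j in (i + 1):length(runs)) {
        ia <- rownames(mat)[!is.na(mat[, i])]
        ib <- rownames(mat)[!is.na(mat[, j])]
        qc <- tryCatch(quant_correlation(mat, runs[i], runs[j]),
                       error = function(e) list(r = NA_real_, n_shared = 0L))
        rows[[length(rows) + 1L]] <- data.table::data.table(
          run_a = runs[i], run_b = runs[j],
          overlap = replicate_overlap(ia, ib),
          pearson_r = qc$r, n_shared = qc$n_shared)
      }
    }
  }
  data.table::rbindlist(rows)
}
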