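# End-to-end orchestration: config validation, staged execution,
# self-describing artifacts, logging.

PIPELINE_KEYS <- c("runs", "fasta", "annotations", "library", "out_dir",
                   "seed", "deconvolution", "digest", "search",
                   "library_build", "quantify", "annotate")

#' Read and validate a pipeline configuration
#'
#' YAML with top-level keys: `runs` (list of mzML paths), `fasta`,
#' optional `annotations` (TSV), optional `library` (external library TSV;
#' when present the deconvolution and search stages are skipped),
#' `out_dir`, `seed`, and per-stage parameter blocks `deconvolution`,
#' `digest`, `search`, `library_build`, `quantify`, `annotate`. Unknown
#' keys are rejected before any compute.
#'
#' @param path YAML file
#' @return validated config list
#' @export
read_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' @rdname read_config
#' @param cfg config list (already parsed)
#' @export
validate_config <- function(cfg) {
  unknown <- setdiff(names(cfg), PIPELINE_KEYS)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  if (is.null(cfg$runs) || !length(cfg$runs)) stop("config requires 'runs'")
  if (is.null(cfg[["library"]]) && is.null(cfg$fasta))
    stop("config requires 'fasta' (or an external 'library')")
  if (is.null(cfg$out_dir)) stop("config requires 'out_dir'")
  cfg$seed <- cfg$seed %||% 1L
  for (blk in c("deconvolution", "digest", "search", "library_build",
                "quantify", "annotate"))
    cfg[[blk]] <- cfg[[blk]] %||% list()
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

artifact_header <- function(cfg_hash) {
  sprintf("metadia %s config_hash=%s",
          as.character(utils::packageVersion("metadia")), cfg_hash)
}

write_tsv_artifact <- function(dt, path, header) {
  con <- file(path, "wt"); on.exit(close(con))
  writeLines(paste0("# ", header), con)
  utils::write.table(dt, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read a TSV artifact, skipping comment headers
#' @param path TSV written by the pipeline
#' @return data.table
#' @export
read_tsv_artifact <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, skip = "peptide\t",
                    na.strings = "")
}

#' Run the full untargeted DIA pipeline
#'
#' Stages: deconvolve each run into pseudospectra, pool them, identify by
#' database search with target-decoy FDR, assemble the pseudospectral
#' library, quantify every run against it, and annotate. Each stage writes
#' its artifact into `out_dir` with a self-describing header (tool version
#' + config hash) and logs a count line. When `cfg$library` names an
#' external library TSV, deconvolution and search are skipped and the
#' supplied library drives quantification directly. When no annotation
#' table is configured the annotation stage is skipped with a warning and
#' the quantity matrix is still produced.
#'
#' Reruns on identical inputs produce byte-identical artifacts (only the
#' log carries timestamps).
#'
#' @param cfg validated config list (see [read_config()])
#' @return `out_dir`, invisibly; artifacts: `pseudospectra.mgf`,
#'   `deconvolution_report.tsv`, `search_results.tsv`, `library.tsv`,
#'   `quant_matrix.tsv`, `annotations.tsv`, `profile_*.tsv`, `metrics.tsv`,
#'   `pipeline.log`
#' @export
run_pipeline <- function(cfg) {
  cfg <- validate_config(cfg)
  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(cfg[setdiff(names(cfg), "out_dir")])
  hdr <- artifact_header(hash)
  log_path <- file.path(out, "pipeline.log")
  logf <- function(stage, fmt, ...) {
    line <- sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage,
                    sprintf(fmt, ...))
    message(line)
    cat(line, "\n", file = log_path, append = TRUE)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  runs <- stage("read", lapply(cfg$runs, read_mzml))
  logf("read", "%d runs loaded", length(runs))

  if (is.null(cfg[["library"]])) {
    pool <- list()
    report <- list()
    for (r in runs) {
      dec <- stage("deconvolve", deconvolve_run(r, cfg$deconvolution))
      pool <- c(pool, dec$pseudospectra)
      report[[length(report) + 1L]] <- dec$report
      logf("deconvolve", "run %s: %d pseudospectra", r$run_id,
           length(dec$pseudospectra))
    }
    stage("deconvolve", {
      write_mgf(pool, file.path(out, "pseudospectra.mgf"))
      write_tsv_artifact(data.table::rbindlist(report),
                         file.path(out, "deconvolution_report.tsv"), hdr)
    })
    proteins <- stage("search", read_fasta(cfg$fasta))
    res <- stage("search", search_run(pool, proteins,
                                      digest_cfg = cfg$digest,
                                      search_cfg = cfg$search))
    logf("search", "%d spectra matched, %d accepted at FDR",
         nrow(res$matches), nrow(res$accepted))
    stage("search", write_tsv_artifact(
      res$matches[, .(spectrum_id, peptide, charge, score, is_decoy,
                      q_value, protein_ids)],
      file.path(out, "search_results.tsv"), hdr))
    lib_args <- cfg$library_build
    lib <- stage("build-library", do.call(build_library,
      c(list(accepted = res$accepted, pseudospectra = pool), lib_args)))
    logf("build-library", "%d library entries", nrow(lib))
  } else {
    lib <- stage("build-library", read_library(cfg[["library"]]))
    logf("build-library", "external library: %d entries (deconvolution and search skipped)",
         nrow(lib))
  }
  stage("build-library", write_tsv_artifact(lib, file.path(out, "library.tsv"), hdr))

  quant <- stage("quantify", do.call(quantify_all,
    c(list(runs = runs, library = lib), list(params = cfg$quantify))))
  logf("quantify", "%d peptides x %d runs", nrow(quant), ncol(quant))
  stage("quantify", {
    dt <- data.table::data.table(peptide = rownames(quant))
    for (cn in colnames(quant)) dt[[cn]] <- quant[, cn]
    write_tsv_artifact(dt, file.path(out, "quant_matrix.tsv"), hdr)
  })

  if (is.null(cfg$annotations)) {
    warning("no annotation table configured; annotation stage skipped")
    logf("annotate", "skipped (no annotation table)")
  } else {
    ann_table <- stage("annotate", read_annotations(cfg$annotations))
    pep_prot <- unique(lib[, .(peptide, protein_ids)])
    pep_prot <- pep_prot[, .(protein_ids = paste(
      unique(unlist(strsplit(protein_ids, ";", fixed = TRUE))), collapse = ";")),
      by = peptide]
    ann <- stage("annotate", annotate_peptides(pep_prot, ann_table))
    stage("annotate", write_tsv_artifact(ann, file.path(out, "annotations.tsv"), hdr))
    thr <- cfg$annotate$threshold %||% 0.005
    for (rank in c("phylum", "genus", "kegg_category")) {
      prof <- build_profile(ann[[rank]], threshold = thr)
      stage("annotate", write_tsv_artifact(
        data.table::data.table(label = names(prof), percent = as.numeric(prof)),
        file.path(out, sprintf("profile_%s.tsv", rank)), hdr))
    }
    logf("annotate", "%d peptides annotated", nrow(ann))
  }

  metrics <- stage("metrics", replicate_metrics(quant))
  stage("metrics", write_tsv_artifact(metrics, file.path(out, "metrics.tsv"), hdr))
  logf("metrics", "%d replicate pairs", nrow(metrics))
  invisible(out)
}
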