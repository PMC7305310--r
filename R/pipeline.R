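#' @importFrom yaml read_yaml
NULL

## small FNV-1a hash so outputs can be traced to their configuration
configHash <- function(config) {
  bytes <- as.integer(serialize(config, NULL, ascii = TRUE))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

DEFAULT_THRESHOLDS <- list(peptide_q = 0.01, protein_q = 0.005,
                           min_psms = 2L, combined_pep = 0.01,
                           length_min = 6L, length_max = 50L,
                           semi_min_psms = 5L, window_size = 249L)

#' Read and validate a pipeline run configuration
#'
#' Configurations are declarative YAML with nested sections: `paths`
#' (`proteome`, `annotations`, `psm_tables`, `predictions`), `thresholds`
#' (defaulting to peptide q 1%, protein q 0.5%, 2 PSMs minimum, combined
#' PEP 1%, peptide lengths 6–50, 5 PSMs for semi-enzymatic evidence),
#' `enzyme`, `seed` and `mode` (`per-dataset`, `combined` or `both`).
#'
#' @param path YAML file path, or a list with the same structure.
#' @return Validated config list with defaults filled in.
#' @export
readRunConfig <- function(path) {
  config <- if (is.character(path)) read_yaml(path) else path
  config$thresholds <- utils::modifyList(DEFAULT_THRESHOLDS,
                                         config$thresholds %||% list())
  th <- config$thresholds
  if (th$peptide_q < 0 || th$peptide_q > 1 ||
      th$protein_q < 0 || th$protein_q > 1) {
    stop("q-value thresholds must lie in [0, 1]")
  }
  config$enzyme <- config$enzyme %||% "trypsin"
  config$seed <- config$seed %||% 1L
  config$mode <- config$mode %||% "combined"
  if (!config$mode %in% c("per-dataset", "combined", "both")) {
    stop("mode must be per-dataset, combined or both")
  }
  for (p in unlist(config$paths)) {
    if (!file.exists(p)) stop("configured path does not exist: ", p)
  }
  config
}

runFdrStages <- function(psms, db, th, log) {
  pep <- collapseToPeptides(psms)
  pep <- pep[pep$length >= th$length_min & pep$length <= th$length_max, ,
             drop = FALSE]
  log(sprintf("collapse: %d PSMs -> %d peptides within length bounds",
              nrow(psms), nrow(pep)))
  pep <- computePeptideQvalues(pep)
  conf <- pep[!is.na(pep$q_value) & pep$q_value <= th$peptide_q, ,
              drop = FALSE]
  groups <- inferProteins(conf, db)
  groups <- scoreProteins(groups, pep, th$peptide_q)
  groups <- computePickedProteinQvalues(groups)
  log(sprintf("inference: %d protein groups scored and ranked",
              nrow(groups)))
  filtered <- applyConfidenceFilters(pep, groups, th$peptide_q,
                                     th$protein_q, th$min_psms,
                                     countedSize = countedSize(db))
  list(peptides = pep, groups = groups, filtered = filtered)
}

#' Run the aggregation pipeline end to end
#'
#' Executes the stages in order — combined PEP, spectrum sanitization,
#' peptide collapse, length-grouped peptide q-values, protein inference,
#' scoring, picked protein q-values, confidence filters — for the
#' combined data and/or each dataset separately, then the annotation and
#' comparative stages. A stage failure aborts with the failing stage
#' named. Identical configuration (and therefore config hash) yields
#' identical output.
#'
#' @param config Config list from [readRunConfig()].
#' @param db,psms Pre-loaded database and PSM table; when `NULL` they are
#'   read from `config$paths`.
#' @param predictions Optional prediction table for the localization
#'   stage.
#' @return list: `summary` (counts per stage and dataset, config hash),
#'   `combined` and/or `per_dataset` result bundles, `annotation`
#'   (per-protein table for confident proteins), `discrepancy` (proteins
#'   confident only in the combined or only in a per-dataset run, when
#'   `mode = "both"`), and `log`.
#' @export
runPipeline <- function(config, db = NULL, psms = NULL, predictions = NULL) {
  config <- readRunConfig(config)
  th <- config$thresholds
  logLines <- character(0)
  log <- function(msg) logLines <<- c(logLines, msg)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  if (is.null(db)) {
    db <- stage("load", {
      d <- loadProteome(config$paths$proteome, config$paths$annotations,
                        seed = config$seed)
      generateDecoys(d, config$enzyme, seed = config$seed)
    })
  }
  if (is.null(psms)) {
    psms <- stage("read-psms", {
      do.call(rbind, lapply(unlist(config$paths$psm_tables), readPsmTable))
    })
  }
  log(sprintf("input: %d PSM rows, %d datasets, counted database size %d",
              nrow(psms), length(unique(psms$dataset_id)), countedSize(db)))

  psms <- stage("combine", combinePep(psms, windowSize = th$window_size))
  psms <- psms[psms$combined_pep <= th$combined_pep | psms$is_decoy, ,
               drop = FALSE]
  psms <- stage("sanitize", sanitizePsms(psms))
  log(sprintf("combine+sanitize: %d PSMs kept", nrow(psms)))

  out <- list(summary = list(config_hash = configHash(config),
                             thresholds = th), log = NULL)
  if (config$mode %in% c("combined", "both")) {
    out$combined <- stage("fdr-combined", runFdrStages(psms, db, th, log))
    out$summary$combined <- out$combined$filtered$summary
  }
  if (config$mode %in% c("per-dataset", "both")) {
    out$per_dataset <- lapply(split(psms, psms$dataset_id), function(p) {
      stage(paste0("fdr-", p$dataset_id[1]), runFdrStages(p, db, th, log))
    })
    out$summary$per_dataset <- lapply(out$per_dataset, function(r)
      r$filtered$summary)
  }
  if (config$mode == "both") {
    comb <- out$combined$filtered$proteins$representative
    per <- unique(unlist(lapply(out$per_dataset, function(r)
      r$filtered$proteins$representative)))
    out$discrepancy <- list(combined_only = setdiff(comb, per),
                            per_dataset_only = setdiff(per, comb))
    log(sprintf("discrepancy: %d combined-only, %d per-dataset-only proteins",
                length(out$discrepancy$combined_only),
                length(out$discrepancy$per_dataset_only)))
  }

  ref <- out$combined %||% out$per_dataset[[1]]
  if (!is.null(ref)) {
    out$annotation <- stage("annotate", {
      prot <- ref$filtered$proteins
      e <- db@entries
      rows <- lapply(prot$representative, function(a) {
        s <- e$sequence[match(a, e$accession)]
        phys <- computePhysicochemical(s)
        peps <- strsplit(prot$peptides[prot$representative == a], ";")[[1]]
        starts <- vapply(peps, function(p)
          as.integer(regexpr(p, s, fixed = TRUE)), integer(1))
        keep <- starts > 0
        cov <- computeSequenceCoverage(nchar(s), starts[keep],
                                       nchar(peps)[keep])
        data.frame(accession = a, mw = phys$mw, pi = phys$pi,
                   gravy = phys$gravy, coverage = cov,
                   stringsAsFactors = FALSE)
      })
      tab <- do.call(rbind, rows)
      if (!is.null(predictions)) {
        lens <- setNames(nchar(e$sequence[match(tab$accession,
                                                e$accession)]),
                         tab$accession)
        tab$localization <- unname(classifyLocalization(predictions, lens))
      }
      tab
    })
    out$summary$median_coverage_percent <-
      roundHalfUp(100 * stats::median(out$annotation$coverage), 0)

    out$comparative <- stage("compare", {
      e <- dbEntries(db, targetsOnly = TRUE)
      e <- e[!e$is_spurious, , drop = FALSE]
      identified <- e$accession %in% ref$filtered$proteins$representative
      islands <- lapply(split(seq_len(nrow(e)), e$replicon_id), function(i) {
        o <- i[order(e$gene_index[i])]
        scanLowIdentificationIslands(identified[o],
                                     circular = db@circular[e$replicon_id[o[1]]])
      })
      list(islands = islands)
    })
    out$summary$n_islands <- sum(vapply(out$comparative$islands, function(x)
      nrow(x$islands), integer(1)))
  }
  out$log <- logLines
  out
}
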