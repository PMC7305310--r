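#' Grouped validation of semi-enzymatic searches
#'
#' PSMs from a semi-enzymatic search are split into fully enzymatic and
#' semi-enzymatic groups and the error-rate machinery (combined PEP,
#' sanitization, peptide collapse, q-values) runs independently on each
#' group, which yields more accurate error estimates than pooling the two
#' search spaces. Results are merged with their group recorded; by
#' convention the semi results never contribute to headline
#' identification counts — they only serve cleavage-site validation.
#'
#' @param psms PSM data.frame with the `specificity` column set.
#' @param windowSize Window for [combinePep()].
#' @param groupByLength Length-grouped peptide q-values?
#' @return list with `psms` (sanitized, combined PEPs, plus a
#'   `validation_group` column) and `peptides` (collapsed evidence with
#'   q-values and `validation_group`).
#' @export
validateSemiEnzymatic <- function(psms, windowSize = 249L,
                                  groupByLength = TRUE) {
  validatePsmTable(psms)
  groups <- ifelse(psms$specificity == "full", "full", "semi")
  outPsms <- list(); outPep <- list()
  for (g in unique(groups)) {
    sub <- psms[groups == g, , drop = FALSE]
    sub <- sanitizePsms(combinePep(sub, windowSize = windowSize))
    pep <- computePeptideQvalues(collapseToPeptides(sub),
                                 groupByLength = groupByLength)
    sub$validation_group <- g
    pep$validation_group <- g
    outPsms[[g]] <- sub
    outPep[[g]] <- pep
  }
  list(psms = do.call(rbind, outPsms), peptides = do.call(rbind, outPep))
}

## Is a semi-enzymatic peptide of length 5-50 starting at `cs` possible?
## Its C-terminus must sit at a cleavage site or the protein end.
theoreticalSemiPeptidePossible <- function(sequence, cs, enzyme,
                                           lengthBounds = c(5L, 50L)) {
  n <- nchar(sequence)
  ends <- c(cleavagePositions(sequence, enzyme), n)
  len <- ends - cs + 1L
  any(len >= lengthBounds[1] & len <= lengthBounds[2])
}

#' Classify a predicted signal-peptide cleavage site
#'
#' Confronts a predicted cleavage site (CS; 1-based first mature residue)
#' with peptide evidence from a grouped semi-enzymatic search. A
#' qualifying semi-enzymatic peptide starting exactly at the CS confirms
#' the prediction (`correct`); one starting within three residues of it
#' refines it (`refined`, with the observed start reported); failing
#' both, a fully enzymatic peptide starting at least three residues
#' N-terminal of the CS contradicts it (`incorrect`). Predictions for
#' which no theoretical enzymatic peptide of 5-50 residues can start at
#' the CS, or which carry an N-terminal lipid anchor (lipobox pathways),
#' are `unclassifiable` — the evidence could never exist. Otherwise no
#' call is made. Precedence: correct > refined > incorrect >
#' unclassifiable.
#'
#' @param sequence Protein sequence.
#' @param predictedCs Predicted CS position.
#' @param pathway One of `"Sec(SPI)"`, `"Tat(SPI)"`, `"Sec(SPII)"`,
#'   `"Tat(lipobox)"`. The lipobox pathways imply a lipid-modified
#'   N-terminus.
#' @param semiStarts Start positions of qualifying semi-enzymatic
#'   peptides (confident, and supported by the required PSM minimum).
#' @param fullStarts Start positions of confident fully enzymatic
#'   peptides.
#' @param enzyme Protease (`"trypsin"`; GluC data are excluded upstream).
#' @param refineRange Maximum refinement distance (residues).
#' @return list: `verdict` (`correct`/`refined`/`incorrect`/
#'   `unclassifiable`/`no_call`) and `refined_cs` (`NA` unless refined).
#' @export
classifyCleavageSites <- function(sequence, predictedCs, pathway,
                                  semiStarts, fullStarts,
                                  enzyme = "trypsin", refineRange = 3L) {
  if (predictedCs < 1 || predictedCs > nchar(sequence)) {
    stop("predicted cleavage site outside the protein")
  }
  lipid <- pathway %in% c("Sec(SPII)", "Tat(lipobox)", "Sec(lipobox)")
  if (any(semiStarts == predictedCs)) {
    return(list(verdict = "correct", refined_cs = NA_integer_))
  }
  near <- semiStarts[abs(semiStarts - predictedCs) <= refineRange &
                       semiStarts != predictedCs]
  if (length(near) > 0) {
    ## nearest observed start wins; upstream start on distance ties
    near <- near[order(abs(near - predictedCs), near)]
    return(list(verdict = "refined", refined_cs = near[1]))
  }
  if (any(fullStarts <= predictedCs - 3L)) {
    return(list(verdict = "incorrect", refined_cs = NA_integer_))
  }
  if (lipid ||
      !theoreticalSemiPeptidePossible(sequence, predictedCs, enzyme)) {
    return(list(verdict = "unclassifiable", refined_cs = NA_integer_))
  }
  list(verdict = "no_call", refined_cs = NA_integer_)
}

#' Cleavage-site calls for a set of predictions
#'
#' Applies [classifyCleavageSites()] across a prediction table, using the
#' grouped-validation output: semi-enzymatic peptide evidence qualifies
#' only at the peptide q-value threshold and with at least `semiMinPsms`
#' supporting spectra; fully enzymatic evidence at the same q-value
#' threshold. TatLipo positives override Tat(SPI) predictions. Proteins
#' with more semi- than fully enzymatic peptides are skipped (digestion
#' artifacts rather than processing), as are excluded datasets
#' (enrichment experiments).
#'
#' @param db [ProteinDb-class].
#' @param csPredictions data.frame: `accession`, `pathway`,
#'   `predicted_cs`.
#' @param validated Output of [validateSemiEnzymatic()].
#' @param peptideQ Peptide q-value threshold for qualifying evidence.
#' @param semiMinPsms Minimum PSMs for a semi-enzymatic peptide.
#' @param excludeDatasets Dataset ids whose evidence is ignored.
#' @return data.frame: `accession`, `pathway`, `predicted_cs`, `verdict`,
#'   `refined_cs`, `n_semi_psms`.
#' @export
callCleavageSites <- function(db, csPredictions, validated,
                              peptideQ = 0.01, semiMinPsms = 5L,
                              excludeDatasets = character(0)) {
  e <- db@entries
  pep <- validated$peptides
  pep <- pep[!pep$is_decoy & !is.na(pep$q_value) &
               pep$q_value <= peptideQ, , drop = FALSE]
  psms <- validated$psms
  if (length(excludeDatasets) > 0) {
    psms <- psms[!(psms$dataset_id %in% excludeDatasets), , drop = FALSE]
    counts <- table(psms$peptide)
    pep$psm_count <- as.integer(counts[pep$peptide])
    pep$psm_count[is.na(pep$psm_count)] <- 0L
    pep <- pep[pep$psm_count > 0, , drop = FALSE]
  }
  semiPep <- pep[pep$validation_group == "semi" &
                   pep$psm_count >= semiMinPsms, , drop = FALSE]
  fullPep <- pep[pep$validation_group == "full", , drop = FALSE]

  ## TatLipo overrides Tat(SPI) for the same protein
  tatlipoAcc <- csPredictions$accession[
    csPredictions$pathway == "Tat(lipobox)"]
  drop <- csPredictions$pathway == "Tat(SPI)" &
    csPredictions$accession %in% tatlipoAcc
  csPredictions <- csPredictions[!drop, , drop = FALSE]

  peptideStarts <- function(peps, accession, sequence) {
    hit <- peps[vapply(strsplit(peps$accessions, ";"), function(a)
      accession %in% a, logical(1)), , drop = FALSE]
    if (nrow(hit) == 0) return(list(starts = integer(0), psms = integer(0)))
    starts <- vapply(hit$peptide, function(p)
      as.integer(regexpr(p, sequence, fixed = TRUE)), integer(1),
      USE.NAMES = FALSE)
    keep <- starts > 0
    list(starts = starts[keep], psms = hit$psm_count[keep])
  }

  rows <- lapply(seq_len(nrow(csPredictions)), function(i) {
    acc <- csPredictions$accession[i]
    seqRow <- e$sequence[match(acc, e$accession)]
    if (is.na(seqRow)) stop("prediction for unknown accession: ", acc)
    semi <- peptideStarts(semiPep, acc, seqRow)
    full <- peptideStarts(fullPep, acc, seqRow)
    ## more semi than full peptides: unspecific proteolysis, skip
    nSemiAll <- sum(vapply(strsplit(
      pep$accessions[pep$validation_group == "semi"], ";"),
      function(a) acc %in% a, logical(1)))
    nFullAll <- sum(vapply(strsplit(
      pep$accessions[pep$validation_group == "full"], ";"),
      function(a) acc %in% a, logical(1)))
    if (nSemiAll > nFullAll) return(NULL)
    call <- classifyCleavageSites(seqRow, csPredictions$predicted_cs[i],
                                  csPredictions$pathway[i],
                                  semi$starts, full$starts)
    data.frame(accession = acc, pathway = csPredictions$pathway[i],
               predicted_cs = csPredictions$predicted_cs[i],
               verdict = call$verdict, refined_cs = call$refined_cs,
               n_semi_psms = sum(semi$psms), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(accession = character(0), pathway = character(0),
                      predicted_cs = integer(0), verdict = character(0),
                      refined_cs = integer(0), n_semi_psms = integer(0))
  }
  rownames(out) <- NULL
  out
}
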