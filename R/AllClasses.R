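#' @import methods
NULL

#' Protein database with genomic and functional annotations
#'
#' Container for a duplicate-merged, spurious-flagged protein database.
#' Each row of `entries` is one protein (target or decoy) with its sequence,
#' genomic layout (replicon, gene order, strand) and arCOG class. Decoy
#' entries pair one-to-one with non-spurious targets via
#' `partner_accession`.
#'
#' @slot entries data.frame with columns `accession`, `sequence`,
#'   `is_spurious`, `duplicate_members` (comma-separated merged accessions),
#'   `replicon_id`, `gene_index` (0-based order along the replicon),
#'   `strand`, `arcog_class` (single letter or `NA`), `is_decoy`,
#'   `partner_accession`.
#' @slot circular Named logical, one flag per replicon.
#'
#' @seealso [loadProteome()], [generateDecoys()], [countedSize()]
#' @export
setClass("ProteinDb",
  representation(entries = "data.frame", circular = "logical"))

setValidity("ProteinDb", function(object) {
  e <- object@entries
  required <- c("accession", "sequence", "is_spurious", "duplicate_members",
                "replicon_id", "gene_index", "strand", "arcog_class",
                "is_decoy", "partner_accession")
  missing <- setdiff(required, names(e))
  if (length(missing) > 0) {
    return(paste("entries missing columns:", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(e$accession)) {
    return("duplicate accessions in entries")
  }
  if (any(nchar(e$sequence) == 0)) {
    return("empty sequences are not allowed")
  }
  bad <- grepl(paste0("[^", paste(AA_ALPHABET20, collapse = ""), "]"),
               e$sequence)
  if (any(bad)) {
    return(sprintf("sequence of %s contains residues outside the 20-letter alphabet",
                   e$accession[which(bad)[1]]))
  }
  dec <- e[e$is_decoy, , drop = FALSE]
  if (nrow(dec) > 0) {
    tgt <- e$accession[!e$is_decoy & !e$is_spurious]
    if (!all(dec$partner_accession %in% tgt)) {
      return("decoy entries must pair with non-spurious target accessions")
    }
    if (anyDuplicated(dec$partner_accession)) {
      return("more than one decoy for the same target")
    }
  }
  TRUE
})

#' Ground truth for a synthetic proteomics study
#'
#' Records, for data produced by the synthetic generator, which
#' peptide-spectrum matches are correct, which proteins are present in each
#' dataset, where signal-peptide cleavage sites were planted, which gene
#' runs were planted absent, and the full generator parameters (including
#' the seed), so that calibration tests can compare nominal error rates
#' with the truth.
#'
#' @slot psmLabels data.frame: `spectrum_id`, `label`
#'   (`"true_match"`/`"false_match"`).
#' @slot proteinPresence data.frame: `dataset_id`, `accession`, `present`.
#' @slot plantedCs data.frame: `accession`, `pathway`, `cs` (1-based first
#'   mature residue), `case`, `delta`.
#' @slot plantedIslands data.frame: `replicon_id`, `start` (0-based gene
#'   index), `length`.
#' @slot params list of generator parameters, including `seed`.
#'
#' @seealso [simulateStudy()], [writeTruth()], [readTruth()]
#' @export
setClass("SyntheticTruth",
  representation(psmLabels = "data.frame", proteinPresence = "data.frame",
                 plantedCs = "data.frame", plantedIslands = "data.frame",
                 params = "list"))

setValidity("SyntheticTruth", function(object) {
  if (nrow(object@psmLabels) > 0 &&
      !all(object@psmLabels$label %in% c("true_match", "false_match"))) {
    return("psmLabels$label must be true_match or false_match")
  }
  TRUE
})
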