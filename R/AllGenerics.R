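#' Number of counted proteins in a database
#'
#' The counted size of a protein database: target entries after merging
#' identical duplicates to one representative and excluding spurious
#' annotations. Identification rates are always reported against this
#' number.
#'
#' @param x A [ProteinDb-class] object.
#' @return Integer count.
#' @export
setGeneric("countedSize", function(x) standardGeneric("countedSize"))

#' Database entry table
#'
#' @param x A [ProteinDb-class] object.
#' @param targetsOnly Drop decoy entries?
#' @return data.frame of entries.
#' @export
setGeneric("dbEntries", function(x, targetsOnly = FALSE)
  standardGeneric("dbEntries"))

#' Counted target accessions
#'
#' Accessions of non-spurious, duplicate-merged target entries (the
#' denominator of identification rates), ordered by replicon and gene
#' index.
#'
#' @param x A [ProteinDb-class] object.
#' @return Character vector.
#' @export
setGeneric("countedAccessions", function(x)
  standardGeneric("countedAccessions"))
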