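#' Merge per-engine PSM rows into engine-set rows
#'
#' Search engines report their matches independently; rows describing the
#' same match (same dataset, spectrum, peptide and modifications) are
#' merged into a single PSM whose `engine_ids` is the set of agreeing
#' engines and whose `engine_peps` collects each engine's PEP. These
#' engine sets are the grouping that [combinePep()] operates on.
#'
#' @param psms PSM data.frame, one row per engine observation.
#' @return PSM data.frame, one row per (spectrum, peptidoform) match.
#' @export
mergeEngineRows <- function(psms) {
  validatePsmTable(psms)
  key <- paste(psms$dataset_id, psms$spectrum_id, psms$peptide,
               psms$modifications, sep = "\r")
  idx <- split(seq_len(nrow(psms)), key)
  rows <- lapply(idx, function(i) {
    r <- psms[i[1], , drop = FALSE]
    engines <- unlist(strsplit(psms$engine_ids[i], ";"))
    peps <- unlist(lapply(parseEnginePeps(psms$engine_peps[i]), function(p) p))
    peps <- peps[!duplicated(names(peps))]
    o <- order(names(peps))
    r$engine_ids <- paste(sort(unique(engines)), collapse = ";")
    r$engine_peps <- formatEnginePeps(list(peps[o]))
    r$accessions <- paste(sort(unique(unlist(strsplit(psms$accessions[i],
                                                      ";")))), collapse = ";")
    r
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$dataset_id, out$spectrum_id, out$peptide), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}
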