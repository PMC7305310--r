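#' Combined posterior error probabilities from engine overlap
#'
#' Rescores PSMs by how many search engines agree on them. PSMs are
#' partitioned into groups by the exact set of engines that produced the
#' match (matched on spectrum, peptide and modifications upstream), each
#' group is ranked by joint score (sum of \eqn{-\log_{10}} engine PEPs,
#' best first), and the combined PEP at each rank is estimated from the
#' local decoy density: twice the number of decoys in a centered window,
#' divided by the window size. Windows truncate at the group edges; groups
#' smaller than the window fall back to the whole-group ratio. Estimates
#' are floored at `1e-6`, capped at 1, and monotonized along the ranking
#' by a bottom-up minimum-so-far traversal. PSMs shared by several engines sit in windows with few decoys and
#' so receive smaller combined PEPs — the increased confidence in shared
#' matches that motivates multi-engine searches.
#'
#' @param psms PSM data.frame (see [psmTable()]); `engine_peps` set.
#' @param windowSize Odd window width, at least 3.
#' @return The PSM table with `combined_pep` filled in, original row order
#'   preserved. The result is invariant to the input row order.
#' @export
combinePep <- function(psms, windowSize = 249L) {
  validatePsmTable(psms)
  stopifnot(windowSize >= 3L, windowSize %% 2L == 1L)
  if (nrow(psms) == 0) return(psms)

  peps <- parseEnginePeps(psms$engine_peps)
  joint <- vapply(peps, function(p) sum(-log10(pmax(p, PEP_EPS))), numeric(1))
  key <- engineSetKey(psms$engine_ids)

  ## canonical order: group, best joint score first, deterministic ties
  ord <- order(key, -joint, psms$is_decoy, psms$peptide, psms$spectrum_id)
  combined <- numeric(nrow(psms))
  h <- (windowSize - 1L) %/% 2L

  for (idx in split(ord, key[ord])) {
    n <- length(idx)
    dec <- as.numeric(psms$is_decoy[idx])
    if (n < windowSize) {
      est <- rep(2 * sum(dec) / n, n)
    } else {
      cum <- c(0, cumsum(dec))
      lo <- pmax(seq_len(n) - h, 1L)
      hi <- pmin(seq_len(n) + h, n)
      est <- 2 * (cum[hi + 1L] - cum[lo]) / (hi - lo + 1L)
    }
    est <- pmin(pmax(est, PEP_EPS), 1)
    ## bottom-up min-so-far: monotone non-decreasing toward worse ranks
    ## without letting truncated top-edge windows inflate the best PSMs
    combined[idx] <- rev(cummin(rev(est)))
  }
  psms$combined_pep <- combined
  psms
}

#' Resolve conflicting identifications of the same spectrum
#'
#' When several engines assign different peptides (or peptidoforms) to the
#' same spectrum, the best PSM is kept only if it is unambiguous or its
#' combined PEP is at least an order of magnitude better than the best
#' conflicting one; otherwise every PSM of that spectrum is rejected.
#' Unambiguous spectra keep their single lowest-PEP record.
#'
#' @param psms PSM data.frame with `combined_pep` set.
#' @param foldRule Required PEP ratio between best and runner-up
#'   peptidoform (default one order of magnitude).
#' @return The kept PSMs, one row per surviving spectrum.
#' @export
sanitizePsms <- function(psms, foldRule = 0.1) {
  validatePsmTable(psms)
  if (nrow(psms) == 0) return(psms)
  if (anyNA(psms$combined_pep)) stop("combined_pep must be set; run combinePep()")
  grp <- paste(psms$dataset_id, psms$spectrum_id, sep = "\r")
  keep <- unlist(lapply(split(seq_len(nrow(psms)), grp), function(idx) {
    form <- paste(psms$peptide[idx], psms$modifications[idx], sep = "\r")
    o <- idx[order(psms$combined_pep[idx], psms$engine_ids[idx])]
    if (length(unique(form)) == 1L) return(o[1L])
    best <- o[1L]
    bestForm <- paste(psms$peptide[best], psms$modifications[best], sep = "\r")
    rival <- o[paste(psms$peptide[o], psms$modifications[o], sep = "\r") !=
                 bestForm][1L]
    if (psms$combined_pep[best] <= foldRule * psms$combined_pep[rival]) {
      best
    } else {
      integer(0)
    }
  }), use.names = FALSE)
  out <- psms[sort(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Select search tolerances and per-file instrument offsets from a sweep
#'
#' Given grid-search summaries (peptides identified at a fixed threshold
#' for every combination of precursor tolerance, fragment tolerance,
#' instrument offset and raw file), picks the global tolerance pair that
#' maximizes the total number of identified peptides over all files (each
#' file contributing its best offset), then, with the pair fixed, the
#' best-performing offset for each raw file separately. Ties prefer the
#' smaller precursor, then the smaller fragment tolerance; offset ties
#' prefer the offset closest to zero.
#'
#' @param grid data.frame with columns `precursor_tol`, `fragment_tol`,
#'   `offset`, `raw_file`, `n_peptides`.
#' @return list with `precursor_tol`, `fragment_tol`, `offsets` (named by
#'   raw file) and `total_peptides`.
#' @export
selectOptimalParameters <- function(grid) {
  req <- c("precursor_tol", "fragment_tol", "offset", "raw_file", "n_peptides")
  stopifnot(all(req %in% names(grid)))
  cells <- expand.grid(precursor_tol = unique(grid$precursor_tol),
                       fragment_tol = unique(grid$fragment_tol),
                       offset = unique(grid$offset),
                       raw_file = unique(grid$raw_file),
                       stringsAsFactors = FALSE)
  have <- paste(grid$precursor_tol, grid$fragment_tol, grid$offset,
                grid$raw_file)
  want <- paste(cells$precursor_tol, cells$fragment_tol, cells$offset,
                cells$raw_file)
  if (!all(want %in% have)) {
    miss <- cells[!(want %in% have), , drop = FALSE]
    stop("ragged grid; missing cells:\n",
         paste(utils::capture.output(print(miss, row.names = FALSE)),
               collapse = "\n"))
  }

  pairKey <- paste(grid$precursor_tol, grid$fragment_tol, sep = "\r")
  perFileBest <- tapply(grid$n_peptides,
                        list(pairKey, grid$raw_file), max)
  totals <- rowSums(perFileBest)
  pairs <- do.call(rbind, strsplit(names(totals), "\r"))
  o <- order(-totals, as.numeric(pairs[, 1]), as.numeric(pairs[, 2]))[1]
  prec <- as.numeric(pairs[o, 1]); frag <- as.numeric(pairs[o, 2])

  sub <- grid[grid$precursor_tol == prec & grid$fragment_tol == frag, ,
              drop = FALSE]
  offsets <- vapply(split(sub, sub$raw_file), function(d) {
    d$offset[order(-d$n_peptides, abs(d$offset), d$offset)][1]
  }, numeric(1))
  list(precursor_tol = prec, fragment_tol = frag, offsets = offsets,
       total_peptides = unname(totals[o]))
}
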