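## Two-traversal target-decoy q-values on an already-ranked list
## (best first): raw q = cumulative decoys / cumulative targets, then a
## bottom-up pass replaces each value by the minimum seen so far, then cap
## at 1. With zero targets accumulated the raw value is Inf; it is
## resolved by the later traversals or capped.
tdQvalues <- function(isDecoy) {
  n <- length(isDecoy)
  if (n == 0) return(numeric(0))
  cumD <- cumsum(isDecoy)
  cumT <- cumsum(!isDecoy)
  raw <- ifelse(cumT == 0, Inf, cumD / cumT)
  q <- rev(cummin(rev(raw)))
  pmin(q, 1)
}

#' Collapse sanitized PSMs to peptide evidence
#'
#' One record per peptide sequence: the best (lowest) combined PEP over
#' all its PSMs, the PSM count, and the union of datasets it was seen in.
#' Modifications are ignored at this level (peptidoforms collapse onto the
#' sequence); they remain available in the PSM table. A sequence occurring
#' in both the target and the decoy database is labeled target and its
#' decoy occurrences are discarded.
#'
#' @param psms Sanitized PSM data.frame with `combined_pep` set.
#' @return data.frame: `peptide`, `length`, `is_decoy`, `best_pep`,
#'   `psm_count`, `dataset_ids` (semicolon-joined), `accessions`
#'   (semicolon-joined union), `q_value` (`NA` until
#'   [computePeptideQvalues()]).
#' @export
collapseToPeptides <- function(psms) {
  validatePsmTable(psms)
  if (anyNA(psms$combined_pep)) stop("combined_pep must be set")
  ## target/decoy sequence collision: keep the target interpretation
  tgtSeqs <- unique(psms$peptide[!psms$is_decoy])
  drop <- psms$is_decoy & psms$peptide %in% tgtSeqs
  psms <- psms[!drop, , drop = FALSE]
  if (nrow(psms) == 0) {
    return(data.frame(peptide = character(0), length = integer(0),
                      is_decoy = logical(0), best_pep = numeric(0),
                      psm_count = integer(0), dataset_ids = character(0),
                      accessions = character(0), q_value = numeric(0)))
  }
  idx <- split(seq_len(nrow(psms)), psms$peptide)
  out <- data.frame(
    peptide = names(idx),
    length = nchar(names(idx)),
    is_decoy = vapply(idx, function(i) psms$is_decoy[i[1]], logical(1)),
    best_pep = vapply(idx, function(i) min(psms$combined_pep[i]), numeric(1)),
    psm_count = lengths(idx),
    dataset_ids = vapply(idx, function(i)
      paste(sort(unique(psms$dataset_id[i])), collapse = ";"), character(1)),
    accessions = vapply(idx, function(i)
      paste(sort(unique(unlist(strsplit(psms$accessions[i], ";")))),
            collapse = ";"), character(1)),
    q_value = NA_real_,
    stringsAsFactors = FALSE, row.names = NULL
  )
  out
}

## merge sparse length bins (< minGroup peptides) into the nearest length
## bin until every bin is large enough (or one bin remains)
mergeLengthBins <- function(lengths, minGroup) {
  bins <- lapply(sort(unique(lengths)), function(l) l)
  counts <- vapply(bins, function(b) sum(lengths %in% b), integer(1))
  while (length(bins) > 1 && any(counts < minGroup)) {
    i <- which(counts < minGroup)[1]
    ## nearest neighbor in length space
    if (i == 1) {
      j <- 2
    } else if (i == length(bins)) {
      j <- i - 1
    } else {
      dPrev <- min(bins[[i]]) - max(bins[[i - 1]])
      dNext <- min(bins[[i + 1]]) - max(bins[[i]])
      j <- if (dPrev <= dNext) i - 1 else i + 1
    }
    bins[[j]] <- sort(c(bins[[j]], bins[[i]]))
    counts[j] <- counts[j] + counts[i]
    bins[[i]] <- NULL
    counts <- counts[-i]
  }
  grp <- integer(length(lengths))
  for (k in seq_along(bins)) grp[lengths %in% bins[[k]]] <- k
  grp
}

#' Length-grouped peptide q-values
#'
#' Ranks peptides by ascending best PEP (decoys before targets on ties)
#' and computes empirical target-decoy q-values by the two-traversal
#' scheme: a top-down pass dividing cumulative decoys by cumulative
#' targets, then a bottom-up pass taking the minimum seen so far to
#' enforce monotonicity. With `groupByLength = TRUE` the computation runs
#' separately per peptide-length group, counteracting the FDR bias of very
#' short and very long peptides; length bins holding fewer than
#' `minGroup` peptides are merged with the nearest length bin first.
#'
#' @param peptides Peptide data.frame from [collapseToPeptides()].
#' @param groupByLength Compute q-values per length group?
#' @param minGroup Minimum peptides per length bin before merging.
#' @return The peptide table with `q_value` set (targets and decoys).
#' @export
computePeptideQvalues <- function(peptides, groupByLength = TRUE,
                                  minGroup = 100L) {
  if (nrow(peptides) == 0) return(peptides)
  grp <- if (groupByLength) {
    mergeLengthBins(peptides$length, minGroup)
  } else {
    rep(1L, nrow(peptides))
  }
  peptides$q_value <- NA_real_
  for (idx in split(seq_len(nrow(peptides)), grp)) {
    if (!any(!peptides$is_decoy[idx])) {
      warning("length group without target peptides; q-values cap at 1")
    }
    o <- idx[order(peptides$best_pep[idx], !peptides$is_decoy[idx],
                   peptides$peptide[idx])]
    peptides$q_value[o] <- tdQvalues(peptides$is_decoy[o])
  }
  peptides
}

#' Simplistic protein inference
#'
#' Assigns confident peptides to proteins. Proteotypic peptides (mapping
#' to a single database entry) assign directly. A non-proteotypic peptide
#' is assigned to one protein if, among the proteins containing it,
#' exactly one is evidenced by other peptides in the same scope; if
#' several are, the identification is discarded as ambiguous
#' (`discarded_ambiguous`) and not counted; if none is, the accession set
#' is kept as a protein group and counted as a single protein. Target and
#' decoy strata are inferred independently, so decoy groups can be scored
#' identically for the picked protein FDR.
#'
#' @param peptides Peptide data.frame (confident set) with `accessions`.
#' @param db [ProteinDb-class]; accessions are mapped onto the merged
#'   representatives.
#' @return data.frame of protein groups: `representative`, `members`
#'   (comma-joined), `peptides` (semicolon-joined), `n_peptides`,
#'   `psm_count`, `is_decoy`, `status`
#'   (`single`/`group`/`discarded_ambiguous`), `score`, `q_value`.
#' @export
inferProteins <- function(peptides, db) {
  e <- db@entries
  ## member accession -> representative accession
  memMap <- do.call(rbind, lapply(seq_len(nrow(e)), function(i) {
    data.frame(member = strsplit(e$duplicate_members[i], ",")[[1]],
               rep = e$accession[i], stringsAsFactors = FALSE)
  }))
  rows <- list()
  for (stratum in unique(peptides$is_decoy)) {
    pep <- peptides[peptides$is_decoy == stratum, , drop = FALSE]
    if (nrow(pep) == 0) next
    accs <- lapply(strsplit(pep$accessions, ";"), function(a) {
      m <- memMap$rep[match(a, memMap$member)]
      if (anyNA(m)) {
        stop("peptide accession not in database: ",
             paste(a[is.na(m)], collapse = ", "))
      }
      sort(unique(m))
    })
    ## protein -> indices of peptides containing it
    protPep <- split(rep(seq_len(nrow(pep)), lengths(accs)), unlist(accs))

    assigned <- vector("list", length(protPep))
    names(assigned) <- names(protPep)
    groupRows <- list()
    for (i in seq_len(nrow(pep))) {
      cand <- accs[[i]]
      if (length(cand) == 1L) {
        assigned[[cand]] <- c(assigned[[cand]], i)
        next
      }
      evid <- cand[vapply(cand, function(a)
        length(setdiff(protPep[[a]], i)) > 0, logical(1))]
      if (length(evid) == 1L) {
        assigned[[evid]] <- c(assigned[[evid]], i)
      } else if (length(evid) >= 2L) {
        groupRows[[length(groupRows) + 1L]] <-
          list(members = cand, idx = i, status = "discarded_ambiguous")
      } else {
        groupRows[[length(groupRows) + 1L]] <-
          list(members = cand, idx = i, status = "group")
      }
    }
    mkRow <- function(repAcc, members, idx, status) {
      data.frame(representative = repAcc,
                 members = paste(members, collapse = ","),
                 peptides = paste(sort(pep$peptide[idx]), collapse = ";"),
                 n_peptides = length(idx),
                 psm_count = sum(pep$psm_count[idx]),
                 is_decoy = stratum, status = status,
                 score = NA_real_, q_value = NA_real_,
                 stringsAsFactors = FALSE)
    }
    for (a in names(assigned)) {
      if (length(assigned[[a]]) > 0) {
        rows[[length(rows) + 1L]] <- mkRow(a, a, assigned[[a]], "single")
      }
    }
    ## merge identical accession-set groups
    if (length(groupRows) > 0) {
      keys <- vapply(groupRows, function(g)
        paste(g$status, paste(g$members, collapse = ","), sep = "\r"),
        character(1))
      for (k in unique(keys)) {
        gs <- groupRows[keys == k]
        rows[[length(rows) + 1L]] <- mkRow(
          gs[[1]]$members[1], gs[[1]]$members,
          vapply(gs, function(g) g$idx, integer(1)), gs[[1]]$status)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Score protein groups
#'
#' A protein's score is the sum of \eqn{-\log_{10}}-transformed minimal
#' combined PEPs over its assigned peptide sequences, counting only
#' peptides at or below the peptide q-value threshold. Groups with no
#' qualifying peptide are dropped.
#'
#' @param groups Protein groups from [inferProteins()].
#' @param peptides Peptide table with `q_value` set.
#' @param peptideQThreshold Peptide q-value cutoff (default 1%).
#' @return Groups with `score` set; non-qualifying groups removed.
#' @export
scoreProteins <- function(groups, peptides, peptideQThreshold = 0.01) {
  qual <- peptides[!is.na(peptides$q_value) &
                     peptides$q_value <= peptideQThreshold, , drop = FALSE]
  pepScore <- setNames(-log10(pmax(qual$best_pep, PEP_EPS)), qual$peptide)
  groups$score <- vapply(strsplit(groups$peptides, ";"), function(p) {
    sum(pepScore[p[p %in% names(pepScore)]])
  }, numeric(1))
  nQual <- vapply(strsplit(groups$peptides, ";"), function(p)
    sum(p %in% names(pepScore)), integer(1))
  out <- groups[nQual > 0, , drop = FALSE]
  rownames(out) <- NULL
  out
}

## rank groups (best score first, decoys before targets on ties) and apply
## the two-traversal q-value scheme
rankedProteinQvalues <- function(groups) {
  o <- order(-groups$score, !groups$is_decoy, groups$representative)
  groups$q_value[o] <- tdQvalues(groups$is_decoy[o])
  groups
}

#' Picked protein q-values
#'
#' Implements the picked protein FDR: each target protein competes only
#' against its own decoy (paired by the `"decoy_"` accession prefix); the
#' lower-scoring member of each pair is discarded before ranking (ties
#' keep the target). Survivors are ranked by descending score and
#' q-values are computed with the same two-traversal scheme as for
#' peptides. Proteins whose partner has no scored group survive
#' automatically.
#'
#' @param groups Scored target and decoy protein groups.
#' @return The surviving groups with `q_value` set.
#' @export
computePickedProteinQvalues <- function(groups) {
  if (any(groups$is_decoy & !isDecoyAccession(groups$representative))) {
    stop("decoy group whose representative lacks the decoy prefix")
  }
  base <- ifelse(groups$is_decoy, stripDecoyPrefix(groups$representative),
                 groups$representative)
  keep <- rep(TRUE, nrow(groups))
  for (idx in split(seq_len(nrow(groups)), base)) {
    if (length(idx) < 2) next
    t <- idx[!groups$is_decoy[idx]]
    d <- idx[groups$is_decoy[idx]]
    if (length(t) != 1 || length(d) != 1) next
    if (groups$score[d] > groups$score[t]) keep[t] <- FALSE else keep[d] <- FALSE
  }
  surv <- groups[keep, , drop = FALSE]
  surv <- rankedProteinQvalues(surv)
  rownames(surv) <- NULL
  surv
}

#' Classical protein q-values
#'
#' Ranks every target and decoy group together by descending score,
#' without target/decoy pair competition, and applies the two-traversal
#' q-value scheme. Provided for comparison with the picked approach.
#'
#' @param groups Scored protein groups.
#' @return Groups with `q_value` set.
#' @export
computeClassicalProteinQvalues <- function(groups) {
  rankedProteinQvalues(groups)
}

#' Apply the final confidence filters
#'
#' A peptide identification is confident at peptide q-value at or below
#' `peptideQ` with at least `minPsms` spectra; a protein at protein
#' q-value at or below `proteinQ` (half the common 1%, affordable thanks
#' to the picked approach) with at least `minPsms` spectra and an
#' unambiguous inference status.
#'
#' @param peptides Peptide table with q-values.
#' @param groups Protein groups with q-values.
#' @param peptideQ,proteinQ,minPsms Thresholds.
#' @param countedSize Counted database size for the identified fraction.
#' @return list with `peptides` (confident target peptides), `proteins`
#'   (confident target groups), and `summary` (`n_peptides`, `n_proteins`,
#'   `identified_fraction_percent` when `countedSize` is given).
#' @export
applyConfidenceFilters <- function(peptides, groups, peptideQ = 0.01,
                                   proteinQ = 0.005, minPsms = 2L,
                                   countedSize = NULL) {
  pep <- peptides[!peptides$is_decoy & !is.na(peptides$q_value) &
                    peptides$q_value <= peptideQ &
                    peptides$psm_count >= minPsms, , drop = FALSE]
  prot <- groups[!groups$is_decoy & !is.na(groups$q_value) &
                   groups$q_value <= proteinQ &
                   groups$psm_count >= minPsms &
                   groups$status != "discarded_ambiguous", , drop = FALSE]
  summary <- list(n_peptides = nrow(pep), n_proteins = nrow(prot))
  if (!is.null(countedSize)) {
    summary$identified_fraction_percent <-
      roundHalfUp(100 * nrow(prot) / countedSize, 0)
  }
  list(peptides = pep, proteins = prot, summary = summary)
}
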