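#' @importFrom jsonlite write_json read_json
NULL

ALPHABET_NO_KRP <- setdiff(AA_ALPHABET20, c("K", "R", "P"))

randomSequence <- function(len) {
  paste(sample(AA_ALPHABET20, len, replace = TRUE), collapse = "")
}

## Engineered protein carrying a planted signal-peptide cleavage site.
## The background alphabet excludes K/R/P so cleavage sites sit exactly
## where the K residues are placed: one in the signal region, regularly
## spaced ones in the mature region, and (for incorrect-case proteins
## only) one at cs-4 so a fully tryptic peptide can start at cs-3.
plantedCsSequence <- function(cs, length, incorrectCase) {
  stopifnot(cs >= 15, length >= cs + 35)
  chars <- sample(ALPHABET_NO_KRP, length, replace = TRUE)
  chars[10] <- "K"
  if (incorrectCase) chars[cs - 4] <- "K"
  kpos <- seq(cs + 9, length - 6, by = 10)
  chars[kpos] <- "K"
  paste(chars, collapse = "")
}

#' Simulate a ground-truthed proteome study
#'
#' Generates a protein database laid out in gene order on one or more
#' circular replicons, with exact-count allocation of spurious entries,
#' redundant duplicate entries and per-dataset protein presence, plus a
#' localization-prediction table and the [SyntheticTruth-class] record.
#' Optionally plants signal-peptide cleavage sites (with engineered
#' sequences so the planted evidence is enzymatically realizable), absent
#' gene runs (low-identification islands), and an arCOG class enriched in
#' the present fraction. All allocation is exact-count rather than
#' Bernoulli so results are deterministic given the seed; the same seed
#' reproduces the study byte for byte.
#'
#' @param nProteins Total database entries (before merging); at least 51
#'   per replicon.
#' @param nDatasets Number of datasets.
#' @param presentFraction Fraction of counted proteins present per
#'   dataset (must give an integer count).
#' @param duplicateFraction Fraction of entries that are redundant copies
#'   of another entry's sequence.
#' @param spuriousFraction Fraction of entries flagged spurious.
#' @param seed Integer seed.
#' @param nReplicons Number of circular replicons.
#' @param lengthRange Protein length range (residues).
#' @param csCases Named integer vector over
#'   `c(correct, refined, incorrect, sparse)`: how many proteins receive
#'   a planted cleavage site of each validation case.
#' @param refinedDeltas Offsets (within ±3, nonzero) cycled over the
#'   refined cases.
#' @param plantIslands data.frame (`replicon_id`, `start`, `length`;
#'   0-based start) of gene runs forced absent in every dataset.
#' @param tmFraction Fraction of unplanted proteins given 1–3 TM
#'   segments in the prediction table.
#' @param arcogClasses Letters sampled (uniformly) as arCOG classes;
#'   a trailing `NA` share of 10% of proteins carries no class.
#' @return list with `db` ([ProteinDb-class], targets only), `truth`
#'   ([SyntheticTruth-class]), `predictions` (data.frame).
#' @export
simulateStudy <- function(nProteins, nDatasets = 7L, presentFraction = 0.72,
                          duplicateFraction = 0, spuriousFraction = 0,
                          seed = 1L, nReplicons = 1L,
                          lengthRange = c(80L, 300L),
                          csCases = c(correct = 0L, refined = 0L,
                                      incorrect = 0L, sparse = 0L),
                          refinedDeltas = c(1L, -1L, 2L, -2L, 3L, -3L),
                          plantIslands = NULL, tmFraction = 0.15,
                          arcogClasses = LETTERS[1:10]) {
  stopifnot(presentFraction >= 0, presentFraction <= 1,
            duplicateFraction >= 0, duplicateFraction <= 1,
            spuriousFraction >= 0, spuriousFraction <= 1)
  if (nProteins < 51L * nReplicons) {
    stop("need at least 51 proteins per replicon for well-defined windows")
  }
  nSpur <- exactCount(spuriousFraction, nProteins, "spurious_fraction")
  nDup <- exactCount(duplicateFraction, nProteins, "duplicate_fraction")
  nCs <- sum(csCases)
  nBase <- nProteins - nDup
  if (nBase - nSpur - nCs < 0) stop("infeasible allocation of entry roles")

  withSeed(seed, {
    ## base (distinct-sequence) proteins; planted-CS proteins first
    caseVec <- rep(names(csCases), csCases)
    csPos <- integer(nCs)
    seqs <- character(nBase)
    deltas <- rep(NA_integer_, nCs)
    ri <- 1L
    for (i in seq_len(nBase)) {
      if (i <= nCs) {
        cs <- sample(20:32, 1)
        csPos[i] <- cs
        if (caseVec[i] == "refined") {
          deltas[i] <- refinedDeltas[(ri - 1L) %% length(refinedDeltas) + 1L]
          ri <- ri + 1L
        }
        seqs[i] <- plantedCsSequence(cs, cs + 40L + sample(0:60, 1),
                                     caseVec[i] == "incorrect")
      } else {
        seqs[i] <- randomSequence(sample(lengthRange[1]:lengthRange[2], 1))
      }
    }
    acc <- sprintf("SYN%04d", seq_len(nBase))
    ## redundant duplicates: copies of non-planted, non-spurious entries
    spurIdx <- if (nSpur > 0) {
      sample((nCs + 1L):nBase, nSpur)
    } else {
      integer(0)
    }
    dupSource <- setdiff((nCs + 1L):nBase, spurIdx)
    if (nDup > length(dupSource)) stop("too many duplicates requested")
    dupOf <- if (nDup > 0) sample(dupSource, nDup) else integer(0)

    allAcc <- c(acc, sprintf("SYN%04d", nBase + seq_len(nDup)))
    allSeq <- c(seqs, seqs[dupOf])
    spurious <- c(seq_len(nBase) %in% spurIdx, rep(FALSE, nDup))

    ## gene layout: shuffle entries over replicons and order positions
    repliconIds <- sprintf("rep%d", seq_len(nReplicons))
    repAssign <- sort(rep_len(seq_len(nReplicons), nProteins))
    perm <- sample.int(nProteins)
    geneIndex <- integer(nProteins)
    replicon <- character(nProteins)
    for (r in seq_len(nReplicons)) {
      slots <- which(repAssign == r)
      members <- perm[slots]
      replicon[members] <- repliconIds[r]
      geneIndex[members] <- seq_along(members) - 1L
    }
    arcog <- sample(c(arcogClasses, NA), nProteins, replace = TRUE,
                    prob = c(rep(0.9 / length(arcogClasses),
                                 length(arcogClasses)), 0.1))
    strand <- sample(c("+", "-"), nProteins, replace = TRUE)

    ann <- data.frame(accession = allAcc, spurious = spurious,
                      replicon = replicon, gene_index = geneIndex,
                      strand = strand, arcog = arcog,
                      stringsAsFactors = FALSE)
    fasta <- tempfile(fileext = ".fasta")
    Biostrings::writeXStringSet(
      Biostrings::AAStringSet(setNames(allSeq, allAcc)), fasta)
    db <- loadProteome(fasta, ann, seed = seed)
    unlink(fasta)

    counted <- countedAccessions(db)
    ## planted islands: those genes absent in every dataset
    islandAcc <- character(0)
    islands <- data.frame(replicon_id = character(0), start = integer(0),
                          length = integer(0))
    if (!is.null(plantIslands)) {
      e <- dbEntries(db, targetsOnly = TRUE)
      for (i in seq_len(nrow(plantIslands))) {
        r <- plantIslands$replicon_id[i]
        nGenes <- sum(e$replicon_id == r & !e$is_spurious)
        idx <- (plantIslands$start[i] + seq_len(plantIslands$length[i]) - 1L) %%
          nGenes
        onRep <- e[e$replicon_id == r & !e$is_spurious, , drop = FALSE]
        onRep <- onRep[order(onRep$gene_index), , drop = FALSE]
        islandAcc <- c(islandAcc, onRep$accession[idx + 1L])
      }
      islands <- plantIslands
    }

    nPresent <- exactCount(presentFraction, length(counted),
                           "present_fraction")
    eligible <- setdiff(counted, islandAcc)
    csAcc <- acc[seq_len(nCs)]
    if (nPresent > length(eligible)) {
      stop("present count exceeds proteins eligible after island planting")
    }
    datasets <- sprintf("DS%02d", seq_len(nDatasets))
    presence <- do.call(rbind, lapply(datasets, function(d) {
      ## planted-CS proteins always present so their evidence is coherent
      pres <- union(intersect(csAcc, eligible),
                    sample(eligible, nPresent))[seq_len(max(nPresent, nCs))]
      pres <- pres[!is.na(pres)]
      data.frame(dataset_id = d, accession = counted,
                 present = counted %in% pres, stringsAsFactors = FALSE)
    }))

    plantedCs <- if (nCs > 0) {
      data.frame(accession = csAcc, pathway = "Sec(SPI)", cs = csPos,
                 case = caseVec, delta = deltas, stringsAsFactors = FALSE)
    } else {
      data.frame(accession = character(0), pathway = character(0),
                 cs = integer(0), case = character(0), delta = integer(0))
    }

    ## prediction table over counted proteins
    e <- dbEntries(db, targetsOnly = TRUE)
    e <- e[!e$is_spurious, , drop = FALSE]
    pred <- data.frame(accession = e$accession, tm_segments = "",
                       tatlipo_pos = FALSE, tatlipo_cs = NA_integer_,
                       lipop_pos = FALSE, lipop_cs = NA_integer_,
                       tatfind_pos = FALSE, tatfind_cs = NA_integer_,
                       flafind_pos = FALSE, flafind_cs = NA_integer_,
                       signalp_pos = FALSE, signalp_cs = NA_integer_,
                       stringsAsFactors = FALSE)
    hit <- match(plantedCs$accession, pred$accession)
    pred$signalp_pos[hit] <- TRUE
    pred$signalp_cs[hit] <- plantedCs$cs
    rest <- setdiff(seq_len(nrow(pred)), hit)
    nTm <- floor(tmFraction * length(rest))
    tmIdx <- sample(rest, nTm)
    lens <- nchar(e$sequence)
    pred$tm_segments[tmIdx] <- vapply(tmIdx, function(i) {
      k <- sample(1:3, 1)
      starts <- sort(sample(seq_len(max(lens[i] - 25L, 1L)), k))
      paste(sprintf("%d-%d", starts, pmin(starts + 20L, lens[i])),
            collapse = ";")
    }, character(1))

    truth <- new("SyntheticTruth",
                 psmLabels = data.frame(spectrum_id = character(0),
                                        label = character(0)),
                 proteinPresence = presence, plantedCs = plantedCs,
                 plantedIslands = islands,
                 params = list(seed = seed, n_proteins = nProteins,
                               n_datasets = nDatasets,
                               present_fraction = presentFraction,
                               duplicate_fraction = duplicateFraction,
                               spurious_fraction = spuriousFraction))
    list(db = db, truth = truth, predictions = pred)
  })
}

## peptide pool for PSM sampling: fully enzymatic peptides of the given
## entries, length-bounded
peptidePool <- function(db, accessions, enzyme = "trypsin", maxMissed = 2L,
                        lengthBounds = c(6L, 50L)) {
  e <- db@entries
  rows <- lapply(accessions, function(a) {
    s <- e$sequence[match(a, e$accession)]
    d <- digest(s, enzyme, maxMissed = maxMissed,
                lengthBounds = lengthBounds)
    if (nrow(d) == 0) return(NULL)
    data.frame(accession = a, peptide = d$peptide, start = d$start,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

drawEnginePeps <- function(basePep, engines, pSelect) {
  n <- length(engines)
  pick <- runif(n) < pSelect
  if (!any(pick)) pick[sample.int(n, 1)] <- TRUE
  sel <- engines[pick]
  peps <- pmin(pmax(basePep * 10^runif(length(sel), -0.3, 0.3),
                    PEP_EPS), 1)
  setNames(peps, sel)
}

## vectorized engine-set and PEP-string assembly for n matches
drawEngineColumns <- function(basePeps, engines, pSelect) {
  n <- length(basePeps)
  m <- length(engines)
  pick <- matrix(runif(n * m) < pSelect, nrow = n)
  none <- which(rowSums(pick) == 0)
  if (length(none) > 0) {
    pick[cbind(none, sample.int(m, length(none), replace = TRUE))] <- TRUE
  }
  ids <- character(n)
  pepStr <- character(n)
  jitter <- matrix(10^runif(n * m, -0.3, 0.3), nrow = n)
  for (i in seq_len(n)) {
    sel <- which(pick[i, ])
    p <- pmin(pmax(basePeps[i] * jitter[i, sel], PEP_EPS), 1)
    ids[i] <- paste(engines[sel], collapse = ";")
    pepStr[i] <- paste(sprintf("%s=%.6g", engines[sel], p), collapse = ";")
  }
  list(engine_ids = ids, engine_peps = pepStr)
}

#' Simulate multi-engine PSM tables
#'
#' Draws true and false peptide-spectrum matches for each dataset of a
#' simulated study. True matches sample distinct fully enzymatic peptides
#' of the proteins present in that dataset, with low PEPs
#' (`Beta(pepModel$true)`); false matches hit target and decoy peptides
#' with equal probability and exchangeable PEPs
#' (`Beta(pepModel$false)`) — the symmetry that makes decoy counts an
#' estimate of the false-target rate. True matches are seen by more
#' engines on average (`overlapBias`). Per-engine rows are merged into
#' engine-set PSMs and all labels are recorded in the truth object.
#'
#' @param db [ProteinDb-class] including decoys.
#' @param truth [SyntheticTruth-class] from [simulateStudy()].
#' @param nTrue,nFalse Matches per dataset. An error is raised when
#'   `nTrue` exceeds the peptides available from present proteins.
#' @param engines Engine names.
#' @param overlapBias Added per-engine selection probability for true
#'   matches (false matches use 0.4, true `0.4 + overlapBias`).
#' @param pepModel list of Beta parameters `true` and `false`.
#' @param psmsPerTrue Spectra per sampled true peptide.
#' @param enzyme Protease.
#' @param seed Integer seed.
#' @param datasets Dataset ids to simulate (default: all in the truth).
#' @return list with `psms` (merged PSM table) and `truth` (updated with
#'   PSM labels).
#' @export
simulatePsmTables <- function(db, truth, nTrue, nFalse,
                              engines = c("msfragger", "msgf", "xtandem"),
                              overlapBias = 0.35,
                              pepModel = list(true = c(0.7, 300),
                                              false = c(1, 1)),
                              psmsPerTrue = 1L, enzyme = "trypsin",
                              seed = 1L, datasets = NULL) {
  if (!any(db@entries$is_decoy)) stop("database contains no decoys")
  datasets <- datasets %||% unique(truth@proteinPresence$dataset_id)
  e <- db@entries
  counted <- countedAccessions(db)
  decoyAcc <- e$accession[e$is_decoy]

  withSeed(seed, {
    targetPool <- peptidePool(db, counted, enzyme)
    decoyPool <- peptidePool(db, decoyAcc, enzyme)
    perDataset <- list()
    for (d in datasets) {
      pres <- truth@proteinPresence
      presAcc <- pres$accession[pres$dataset_id == d & pres$present]
      pool <- targetPool[targetPool$accession %in% presAcc, , drop = FALSE]
      if (nTrue > nrow(pool)) {
        stop(sprintf("nTrue = %d exceeds the %d peptides available in %s",
                     nTrue, nrow(pool), d))
      }
      truePick <- pool[sample.int(nrow(pool), nTrue), , drop = FALSE]
      falseDecoy <- runif(nFalse) < 0.5
      fT <- targetPool[sample.int(nrow(targetPool), sum(!falseDecoy),
                                  replace = TRUE), , drop = FALSE]
      fD <- decoyPool[sample.int(nrow(decoyPool), sum(falseDecoy),
                                 replace = TRUE), , drop = FALSE]

      trueIdx <- rep(seq_len(nrow(truePick)), each = psmsPerTrue)
      trueEng <- drawEngineColumns(rbeta(nrow(truePick), pepModel$true[1],
                                         pepModel$true[2]),
                                   engines, 0.4 + overlapBias)
      falseBase <- rbeta(nrow(fT) + nrow(fD), pepModel$false[1],
                         pepModel$false[2])
      falseEng <- drawEngineColumns(falseBase, engines, 0.4)
      nFT <- nrow(fT)

      peptide <- c(truePick$peptide[trueIdx], fT$peptide, fD$peptide)
      accession <- c(truePick$accession[trueIdx], fT$accession,
                     fD$accession)
      isDecoy <- c(rep(FALSE, length(trueIdx) + nFT), rep(TRUE, nrow(fD)))
      engIds <- c(trueEng$engine_ids[trueIdx], falseEng$engine_ids)
      engPeps <- c(trueEng$engine_peps[trueIdx], falseEng$engine_peps)
      label <- c(rep("true_match", length(trueIdx)),
                 rep("false_match", nFT + nrow(fD)))
      n <- length(peptide)
      psms <- data.frame(
        spectrum_id = sprintf("%s:scan%07d", d, seq_len(n)),
        dataset_id = d, raw_file = paste0(d, "_f1"),
        engine_ids = engIds, peptide = peptide, modifications = "",
        charge = 2L, is_decoy = isDecoy, accessions = accession,
        enzyme = enzyme, specificity = "full", engine_peps = engPeps,
        combined_pep = NA_real_, stringsAsFactors = FALSE)
      perDataset[[d]] <- list(psms = psms,
                              labels = data.frame(
                                spectrum_id = psms$spectrum_id,
                                label = label, stringsAsFactors = FALSE))
    }
    psms <- do.call(rbind, lapply(perDataset, `[[`, "psms"))
    rownames(psms) <- NULL
    truth@psmLabels <- rbind(truth@psmLabels,
                             do.call(rbind, lapply(perDataset, `[[`,
                                                   "labels")))
    rownames(truth@psmLabels) <- NULL
    list(psms = psms, truth = truth)
  })
}

#' Plant semi-enzymatic evidence for predicted cleavage sites
#'
#' Emits the peptide-spectrum matches that realize each planted
#' cleavage-site case of a simulated study: correct-case proteins get six
#' semi-enzymatic PSMs starting exactly at the cleavage site, refined
#' cases six starting at the planted offset (within ±3), incorrect cases
#' six fully enzymatic PSMs starting three residues N-terminal of the
#' site, and sparse cases only four semi-enzymatic PSMs (below the
#' five-PSM evidence requirement). Every planted protein additionally
#' receives two fully enzymatic mature-region peptides (two PSMs each) so
#' it is not skipped for having more semi- than fully enzymatic peptides.
#'
#' @param db [ProteinDb-class].
#' @param truth [SyntheticTruth-class] with planted cleavage sites.
#' @param seed Integer seed.
#' @param datasetId Dataset the evidence is attributed to.
#' @param engines Engine names to draw from.
#' @return list with `psms` (semi + full PSM table) and `truth` (labels
#'   appended).
#' @export
plantSignalPeptideEvidence <- function(db, truth, seed = 1L,
                                       datasetId = "DS01",
                                       engines = c("msfragger", "msgf",
                                                   "xtandem")) {
  cs <- truth@plantedCs
  if (nrow(cs) == 0) stop("no planted cleavage sites in the truth")
  e <- db@entries
  counter <- 0L
  rows <- list()

  withSeed(seed, {
    for (i in seq_len(nrow(cs))) {
      acc <- cs$accession[i]
      s <- e$sequence[match(acc, e$accession)]
      if (cs$cs[i] >= nchar(s)) stop("cleavage site beyond protein length")
      sites <- cleavagePositions(s, "trypsin")
      emit <- function(peptide, specificity, n) {
        basePep <- rbeta(1, 0.7, 300)
        for (k in seq_len(n)) {
          counter <<- counter + 1L
          peps <- drawEnginePeps(basePep, engines, 0.8)
          rows[[length(rows) + 1L]] <<- data.frame(
            spectrum_id = sprintf("%s:sp%05d", datasetId, counter),
            dataset_id = datasetId, raw_file = paste0(datasetId, "_sp"),
            engine_ids = paste(names(peps), collapse = ";"),
            peptide = peptide, modifications = "", charge = 2L,
            is_decoy = FALSE, accessions = acc, enzyme = "trypsin",
            specificity = specificity,
            engine_peps = formatEnginePeps(list(peps)),
            combined_pep = NA_real_, stringsAsFactors = FALSE)
        }
      }
      semiPeptideAt <- function(start) {
        end <- sites[sites >= start + 4L][1]
        if (is.na(end)) stop("no enzymatic C-terminus for planted peptide")
        substring(s, start, end)
      }
      case <- cs$case[i]
      if (case == "correct") {
        emit(semiPeptideAt(cs$cs[i]), "semi_n", 6L)
      } else if (case == "refined") {
        emit(semiPeptideAt(cs$cs[i] + cs$delta[i]), "semi_n", 6L)
      } else if (case == "incorrect") {
        emit(semiPeptideAt(cs$cs[i] - 3L), "full", 6L)
      } else if (case == "sparse") {
        emit(semiPeptideAt(cs$cs[i]), "semi_n", 4L)
      }
      ## mature-region fully tryptic peptides keep full >= semi
      mature <- sites[sites > cs$cs[i] + 9L]
      mature <- mature[!is.na(vapply(mature, function(m)
        sites[sites > m + 4L][1], numeric(1)))]
      for (m in head(mature, 2)) {
        emit(substring(s, m + 1L, sites[sites > m + 4L][1]), "full", 2L)
      }
    }
    psms <- do.call(rbind, rows)
    truth@psmLabels <- rbind(truth@psmLabels,
                             data.frame(spectrum_id = psms$spectrum_id,
                                        label = "true_match",
                                        stringsAsFactors = FALSE))
    rownames(truth@psmLabels) <- NULL
    list(psms = mergeEngineRows(psms), truth = truth)
  })
}

setMethod("show", "SyntheticTruth", function(object) {
  cat(sprintf("SyntheticTruth: %d PSM labels, %d presence rows, %d planted CS, %d planted islands\n",
              nrow(object@psmLabels), nrow(object@proteinPresence),
              nrow(object@plantedCs), nrow(object@plantedIslands)))
  cat(sprintf("  seed: %s\n", object@params$seed %||% "unset"))
})

#' Serialize or restore a synthetic truth record
#'
#' Lossless JSON round-trip of a [SyntheticTruth-class], so empirical
#' error rates remain recomputable from serialized artifacts alone.
#'
#' @param truth A [SyntheticTruth-class].
#' @param path JSON file path.
#' @return `readTruth` returns the truth object; `writeTruth` invisibly
#'   returns `path`.
#' @export
writeTruth <- function(truth, path) {
  write_json(list(psm_labels = truth@psmLabels,
                  protein_presence = truth@proteinPresence,
                  planted_cs = truth@plantedCs,
                  planted_islands = truth@plantedIslands,
                  params = truth@params),
             path, digits = NA, na = "null")
  invisible(path)
}

#' @rdname writeTruth
#' @export
readTruth <- function(path) {
  x <- read_json(path, simplifyVector = TRUE)
  asDf <- function(d, template) {
    if (length(d) == 0 || nrow(as.data.frame(d)) == 0) return(template)
    as.data.frame(d, stringsAsFactors = FALSE)
  }
  new("SyntheticTruth",
      psmLabels = asDf(x$psm_labels,
                       data.frame(spectrum_id = character(0),
                                  label = character(0))),
      proteinPresence = asDf(x$protein_presence,
                             data.frame(dataset_id = character(0),
                                        accession = character(0),
                                        present = logical(0))),
      plantedCs = asDf(x$planted_cs,
                       data.frame(accession = character(0),
                                  pathway = character(0), cs = integer(0),
                                  case = character(0), delta = integer(0))),
      plantedIslands = asDf(x$planted_islands,
                            data.frame(replicon_id = character(0),
                                       start = integer(0),
                                       length = integer(0))),
      params = as.list(x$params))
}
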