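LOCALIZATION_CATEGORIES <- c("Tat(lipobox)", "Sec(lipobox)", "Tat(SPI)",
                             "Pil(SPIII)", "Sec(SPI)", "integral_membrane",
                             "TM_N_term", "TM_C_term", "Cyt")

PREDICTION_COLUMNS <- c("accession", "tm_segments",
                        "tatlipo_pos", "tatlipo_cs", "lipop_pos", "lipop_cs",
                        "tatfind_pos", "tatfind_cs", "flafind_pos",
                        "flafind_cs", "signalp_pos", "signalp_cs")

#' Read or write a localization-prediction table
#'
#' Tab-separated summary of six prediction engines, one row per protein:
#' `tm_segments` (semicolon-joined `start-end` pairs, may be empty) and,
#' for each signal-peptide predictor (TatLipo, LipoP, TatFind, FlaFind,
#' SignalP), a positive/negative flag and an optional cleavage position
#' (1-based first mature residue). The predictors are consumed as data,
#' never executed.
#'
#' @param path File path.
#' @param predictions Prediction data.frame.
#' @return The prediction data.frame (`readPredictionTable`) or,
#'   invisibly, `path`.
#' @export
readPredictionTable <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE)
  missing <- setdiff(PREDICTION_COLUMNS, names(d))
  if (length(missing) > 0) {
    stop("prediction table missing columns: ", paste(missing, collapse = ", "))
  }
  d$tm_segments[is.na(d$tm_segments)] <- ""
  d
}

#' @rdname readPredictionTable
#' @export
writePredictionTable <- function(predictions, path) {
  write.table(predictions, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

parseTmSegments <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE), function(s) {
    s <- s[nzchar(s)]
    if (length(s) == 0) {
      return(matrix(integer(0), ncol = 2))
    }
    parts <- strsplit(s, "-", fixed = TRUE)
    cbind(as.integer(vapply(parts, `[`, "", 1)),
          as.integer(vapply(parts, `[`, "", 2)))
  })
}

#' Localization category from stacked predictions
#'
#' Assigns each protein to exactly one localization category by a fixed
#' sequential decision tree over the prediction engines: TatLipo
#' (Tat(lipobox)), then LipoP (Sec(lipobox)), TatFind (Tat(SPI)), FlaFind
#' (Pil(SPIII)), SignalP (Sec(SPI)); the first positive predictor decides.
#' If none is positive, proteins with two or more predicted TM domains are
#' integral membrane proteins; a single TM domain within the first or
#' last 50 residues gives `TM_N_term` or `TM_C_term`; a single TM domain
#' elsewhere goes to `singleTmBucket`; everything else is cytoplasmic.
#' The categories are mutually exclusive and exhaustive.
#'
#' @param predictions Prediction data.frame (see [readPredictionTable()]);
#'   proteins without a row are categorized `Cyt` with a warning.
#' @param proteinLengths Named vector of protein lengths (names =
#'   accessions) covering all proteins to classify.
#' @param singleTmBucket Category for one internal TM domain.
#' @return Named character vector of categories, one per protein length
#'   entry.
#' @export
classifyLocalization <- function(predictions, proteinLengths,
                                 singleTmBucket = "integral_membrane") {
  acc <- names(proteinLengths)
  row <- match(acc, predictions$accession)
  if (anyNA(row)) {
    warning(sprintf("%d proteins without prediction row; categorized Cyt",
                    sum(is.na(row))))
  }
  out <- setNames(rep("Cyt", length(acc)), acc)
  has <- which(!is.na(row))
  p <- predictions[row[has], , drop = FALSE]
  tm <- parseTmSegments(p$tm_segments)
  nTm <- vapply(tm, nrow, integer(1))
  len <- proteinLengths[has]

  cat <- ifelse(p$tatlipo_pos, "Tat(lipobox)",
         ifelse(p$lipop_pos, "Sec(lipobox)",
         ifelse(p$tatfind_pos, "Tat(SPI)",
         ifelse(p$flafind_pos, "Pil(SPIII)",
         ifelse(p$signalp_pos, "Sec(SPI)", NA_character_)))))
  tmCat <- vapply(seq_along(has), function(i) {
    if (nTm[i] >= 2) return("integral_membrane")
    if (nTm[i] == 0) return("Cyt")
    seg <- tm[[i]]
    if (seg[1, 2] <= 50) "TM_N_term"
    else if (seg[1, 1] >= len[i] - 49) "TM_C_term"
    else singleTmBucket
  }, character(1))
  out[has] <- ifelse(is.na(cat), tmCat, cat)
  out
}

#' Classify a protein terminus from a peptide
#'
#' An N-terminal peptide starting at position 1 on an initiator
#' methionine gives `met_retained`; one starting at position 2 (the
#' initiator removed, exposing one residue downstream) gives `cleaved`.
#' An N-terminal acetyl modification (position 0 of the peptide or
#' residue 1) sets the acetylated flag. A peptide ending at the final
#' residue identifies the C-terminus. Non-terminal peptides yield no
#' call. One protein can legitimately produce several peptidoform calls.
#'
#' @param peptide Peptide sequence.
#' @param start 1-based start position in the protein.
#' @param proteinSequence Full protein sequence.
#' @param modifications Modification string (`"name@pos;..."`).
#' @return list with `n_term_class` (`"met_retained"`, `"cleaved"` or
#'   `NA`), `acetylated`, `c_term_identified`.
#' @export
classifyTerminus <- function(peptide, start, proteinSequence,
                             modifications = "") {
  mods <- parseModifications(modifications)[[1]]
  acetyl <- any(grepl("acetyl", mods$name, ignore.case = TRUE) &
                  mods$position <= 1)
  nClass <- NA_character_
  if (start == 1 && substring(proteinSequence, 1, 1) == "M" &&
      substring(peptide, 1, 1) == "M") {
    nClass <- "met_retained"
  } else if (start == 2) {
    nClass <- "cleaved"
  }
  cTerm <- (start + nchar(peptide) - 1L) == nchar(proteinSequence)
  list(n_term_class = nClass, acetylated = acetyl && !is.na(nClass),
       c_term_identified = cTerm)
}
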