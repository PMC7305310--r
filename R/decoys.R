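## Shuffle one fully cleaved peptide, keeping the enzymatic C-terminal
## residue in place so the decoy digests into peptides of the same lengths.
shufflePeptide <- function(peptide, fixLast) {
  n <- nchar(peptide)
  if (n <= 1) return(peptide)
  chars <- strsplit(peptide, "")[[1]]
  if (fixLast) {
    if (n == 2) return(peptide)
    head <- chars[seq_len(n - 1)]
    paste(c(head[sample.int(n - 1)], chars[n]), collapse = "")
  } else {
    paste(chars[sample.int(n)], collapse = "")
  }
}

#' Generate a shuffled-decoy database
#'
#' For every counted (non-spurious) target protein, builds a decoy protein
#' by shuffling residues within each fully enzymatic peptide of the
#' protease digest, keeping the enzymatic terminal residue fixed, so the
#' decoy preserves residue composition and the digest's peptide length
#' spectrum. Decoy accessions carry the `"decoy_"` prefix, which the picked
#' protein FDR relies on for target/decoy pairing.
#'
#' @param db Target [ProteinDb-class].
#' @param enzyme `"trypsin"` or `"gluc"`.
#' @param seed Integer seed; the result is deterministic given the seed.
#' @param glucResidues Residues GluC cleaves after.
#' @return The database with decoy entries appended.
#' @export
generateDecoys <- function(db, enzyme, seed = 1L, glucResidues = "E") {
  e <- db@entries
  if (any(e$is_decoy)) stop("database already contains decoys")
  tgt <- e[!e$is_spurious, , drop = FALSE]
  if (nrow(tgt) == 0) stop("no target entries to build decoys from")
  siteResidues <- if (enzyme == "trypsin") c("K", "R")
                  else strsplit(glucResidues, "")[[1]]

  decoySeqs <- withSeed(seed, vapply(tgt$sequence, function(s) {
    cut <- cleavagePositions(s, enzyme, glucResidues)
    bounds <- c(0L, cut, nchar(s))
    parts <- substring(s, head(bounds, -1) + 1L, tail(bounds, -1))
    shuffled <- vapply(parts, function(p) {
      shufflePeptide(p, fixLast = substring(p, nchar(p)) %in% siteResidues)
    }, character(1), USE.NAMES = FALSE)
    paste(shuffled, collapse = "")
  }, character(1), USE.NAMES = FALSE))

  dec <- tgt
  dec$accession <- paste0(DECOY_PREFIX, tgt$accession)
  dec$sequence <- decoySeqs
  dec$is_decoy <- TRUE
  dec$partner_accession <- tgt$accession
  dec$duplicate_members <- dec$accession
  newProteinDb(rbind(e, dec), db@circular)
}
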