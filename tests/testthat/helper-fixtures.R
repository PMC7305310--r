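# Small programmatic fixtures shared across test files.

# Minimal PSM table: one row per (spectrum, peptide), single engine unless
# engine strings are supplied.
fixturePsms <- function(peptides, peps, isDecoy = FALSE,
                        spectra = NULL, datasets = "DS01",
                        engines = "msgf", accessions = "P1",
                        specificity = "full", modifications = "") {
  n <- length(peptides)
  psmTable(
    spectrum_id = spectra %||% sprintf("scan%04d", seq_len(n)),
    dataset_id = rep_len(datasets, n),
    raw_file = "f1",
    engine_ids = rep_len(engines, n),
    peptide = peptides,
    modifications = rep_len(modifications, n),
    charge = 2L,
    is_decoy = rep_len(isDecoy, n),
    accessions = rep_len(accessions, n),
    specificity = rep_len(specificity, n),
    engine_peps = sprintf("%s=%.8g", rep_len(engines, n), peps),
    combined_pep = NA_real_)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Write a tiny FASTA + annotation pair and load it.
fixtureDb <- function(sequences, spurious = NULL, seed = 1L) {
  acc <- names(sequences)
  fasta <- tempfile(fileext = ".fasta")
  writeLines(paste0(">", acc, "\n", unname(sequences)), fasta)
  ann <- data.frame(accession = acc,
                    spurious = spurious %||% rep(FALSE, length(acc)),
                    replicon = "chr", gene_index = seq_along(acc) - 1L,
                    strand = "+", arcog = NA_character_,
                    stringsAsFactors = FALSE)
  db <- loadProteome(fasta, ann, seed = seed)
  unlink(fasta)
  db
}

# Peptide-evidence rows for direct FDR-stage tests.
fixturePeptides <- function(bestPep, isDecoy, psmCount = 2L,
                            length = 10L, accessions = "P1") {
  n <- base::length(bestPep)
  data.frame(peptide = sprintf("PEP%04d", seq_len(n)),
             length = rep_len(length, n),
             is_decoy = isDecoy,
             best_pep = bestPep,
             psm_count = rep_len(psmCount, n),
             dataset_ids = "DS01",
             accessions = rep_len(accessions, n),
             q_value = NA_real_, stringsAsFactors = FALSE)
}

# Scored protein groups for picked/classical FDR tests.
fixtureGroups <- function(representative, score, isDecoy,
                          status = "single") {
  data.frame(representative = representative,
             members = representative,
             peptides = "PEP0001", n_peptides = 1L, psm_count = 2L,
             is_decoy = isDecoy, status = rep_len(status,
                                                  base::length(score)),
             score = score, q_value = NA_real_, stringsAsFactors = FALSE)
}
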