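#' FDR calibration on ground-truthed synthetic data
#'
#' Runs the peptide-level error-control chain (combined PEP, spectrum
#' sanitization, peptide collapse, length-grouped q-values) on simulated
#' PSM tables with known per-spectrum truth, and compares the empirical
#' false discovery proportion of the peptide set accepted at the nominal
#' q-value threshold against the exact binomial band around that
#' threshold. The study (database, presence pattern) is fixed; each seed
#' redraws the PSM tables.
#'
#' @param nTrue,nFalse True and false PSMs per seed; false matches split
#'   evenly between target and decoy peptides.
#' @param seeds Integer vector of PSM-level seeds.
#' @param nominalQ Peptide q-value threshold under test.
#' @param nProteins,presentFraction Study dimensions. The defaults keep
#'   the target peptide space large relative to the identified set, as in
#'   real searches, so false target matches rarely collide with true
#'   peptides.
#' @param studySeed Seed for the fixed study.
#' @param band Two-sided coverage of the binomial band.
#' @return data.frame per seed: `n_accepted`, `n_false`, `band_lo`,
#'   `band_hi`, `empirical_fdr`, `in_band`.
#' @export
fdrCalibration <- function(nTrue = 9000L, nFalse = 1000L, seeds = 1:20,
                           nominalQ = 0.01, nProteins = 1200L,
                           presentFraction = 0.25, studySeed = 1L,
                           band = 0.95) {
  st <- simulateStudy(nProteins, nDatasets = 1L,
                      presentFraction = presentFraction, seed = studySeed)
  db <- generateDecoys(st$db, "trypsin", seed = studySeed)
  alpha <- (1 - band) / 2
  rows <- lapply(seeds, function(s) {
    sim <- simulatePsmTables(db, st$truth, nTrue = nTrue, nFalse = nFalse,
                             seed = s)
    psms <- sanitizePsms(combinePep(sim$psms))
    pep <- computePeptideQvalues(collapseToPeptides(psms))
    lbl <- sim$truth@psmLabels
    trueIds <- lbl$spectrum_id[lbl$label == "true_match"]
    truePep <- unique(sim$psms$peptide[sim$psms$spectrum_id %in% trueIds])
    acc <- pep[!pep$is_decoy & !is.na(pep$q_value) &
                 pep$q_value <= nominalQ, , drop = FALSE]
    n <- nrow(acc)
    x <- sum(!(acc$peptide %in% truePep))
    lo <- qbinom(alpha, n, nominalQ)
    hi <- qbinom(1 - alpha, n, nominalQ)
    data.frame(seed = s, n_accepted = n, n_false = x, band_lo = lo,
               band_hi = hi, empirical_fdr = x / n,
               in_band = x >= lo & x <= hi)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
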