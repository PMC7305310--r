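#' @importFrom IRanges IRanges reduce width
NULL

## Monoisotopic residue masses (Da); a peptide's mass adds one water.
MONO_RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)

MASS_WATER <- 18.0105646863

## Kyte-Doolittle hydropathy index
KD_HYDROPATHY <- c(
  A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5, E = -3.5,
  G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9, M = 1.9, F = 2.8,
  P = -1.6, S = -0.8, T = -0.7, V = 4.2, W = -0.9, Y = -1.3)

## pK values (EMBOSS set): terminal groups plus ionizable side chains.
## Swappable via the pkSet argument of computePhysicochemical().
PK_EMBOSS <- list(
  nterm = 8.6, cterm = 3.6,
  positive = c(K = 10.8, R = 12.5, H = 6.5),
  negative = c(D = 3.9, E = 4.1, C = 8.5, Y = 10.1))

## net charge of a protein at a given pH; strictly decreasing in pH
proteinNetCharge <- function(counts, pH, pkSet) {
  pos <- 1 / (1 + 10^(pH - pkSet$nterm)) +
    sum(counts[names(pkSet$positive)] / (1 + 10^(pH - pkSet$positive)))
  neg <- 1 / (1 + 10^(pkSet$cterm - pH)) +
    sum(counts[names(pkSet$negative)] / (1 + 10^(pkSet$negative - pH)))
  pos - neg
}

#' Physicochemical protein properties
#'
#' Monoisotopic molecular weight (sum of residue masses plus one water),
#' isoelectric point (the pH where the net charge crosses zero, found by
#' bisection to `|charge| < 1e-4`, using pK values distinguishing
#' N-terminal, C-terminal and side-chain groups), and the GRAVY index
#' (mean Kyte-Doolittle hydropathy per residue; positive means
#' hydrophobic).
#'
#' @param sequence Amino-acid string over the 20-letter alphabet.
#' @param pkSet pK table: list with `nterm`, `cterm`, and named `positive`
#'   and `negative` side-chain vectors.
#' @return list with `mw` (Da), `pi` (pH units), `gravy`.
#' @export
#' @examples
#' computePhysicochemical("MKTAYIAK")
computePhysicochemical <- function(sequence, pkSet = PK_EMBOSS) {
  chars <- strsplit(sequence, "")[[1]]
  bad <- which(!(chars %in% names(MONO_RESIDUE_MASS)))
  if (length(bad) > 0) {
    stop(sprintf("non-standard residue '%s' at position %d",
                 chars[bad[1]], bad[1]))
  }
  counts <- table(factor(chars, levels = names(MONO_RESIDUE_MASS)))
  counts <- setNames(as.numeric(counts), names(MONO_RESIDUE_MASS))
  mw <- sum(counts * MONO_RESIDUE_MASS) + MASS_WATER

  lo <- 0; hi <- 14
  repeat {
    mid <- (lo + hi) / 2
    ch <- proteinNetCharge(counts, mid, pkSet)
    if (abs(ch) < 1e-4 || hi - lo < 1e-12) break
    if (ch > 0) lo <- mid else hi <- mid
  }
  gravy <- mean(KD_HYDROPATHY[chars])
  list(mw = mw, pi = mid, gravy = unname(gravy))
}

#' Protein sequence coverage
#'
#' Fraction of a protein's residues covered by the union of its
#' identified peptides' intervals.
#'
#' @param proteinLength Protein length in residues.
#' @param starts 1-based peptide start positions.
#' @param lengths Peptide lengths.
#' @return Coverage fraction in `[0, 1]`.
#' @export
computeSequenceCoverage <- function(proteinLength, starts, lengths) {
  if (length(starts) == 0) return(0)
  ends <- starts + lengths - 1L
  if (any(starts < 1) || any(ends > proteinLength)) {
    stop("peptide interval outside the protein")
  }
  covered <- sum(width(reduce(IRanges(start = starts, end = ends))))
  covered / proteinLength
}
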