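## Positions after which the protease cleaves (1-based residue index).
## Trypsin: C-terminal to K/R, suppressed before P. GluC: after E (or E/D).
cleavagePositions <- function(sequence, enzyme, glucResidues = "E") {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  if (enzyme == "trypsin") {
    cut <- which(chars %in% c("K", "R"))
    cut <- cut[cut < n & chars[pmin(cut + 1, n)] != "P" | cut == n]
    cut <- cut[cut < n]  # cutting after the last residue is a no-op
  } else if (enzyme == "gluc") {
    res <- strsplit(glucResidues, "")[[1]]
    cut <- which(chars %in% res)
    cut <- cut[cut < n]
  } else {
    stop(sprintf("unknown enzyme: %s", enzyme))
  }
  cut
}

#' In-silico protein digestion
#'
#' Enumerates the peptides a protease produces from a protein sequence.
#' Trypsin cleaves C-terminal to K/R but not before proline; GluC cleaves
#' after E (after E or D with `glucResidues = "ED"`). In `"full"` mode both
#' peptide termini sit at cleavage sites (or the protein termini), with up
#' to `maxMissed` internal missed cleavage sites. In `"semi"` mode,
#' peptides with exactly one non-enzymatic terminus are returned in
#' addition.
#'
#' @param sequence Amino-acid string.
#' @param enzyme `"trypsin"` or `"gluc"`.
#' @param maxMissed Maximum number of internal missed cleavage sites.
#' @param mode `"full"` or `"semi"`.
#' @param lengthBounds Length 2 integer vector `(min, max)`; peptides
#'   outside the bounds are dropped.
#' @param glucResidues Residues GluC cleaves after (`"E"` or `"ED"`).
#' @return data.frame with columns `peptide`, `start` (1-based position of
#'   the first residue in the protein), `specificity` (`"full"`,
#'   `"semi_n"`: non-enzymatic N-terminus, or `"semi_c"`).
#' @export
#' @examples
#' digest("MAKRGLE", "trypsin", maxMissed = 0)
digest <- function(sequence, enzyme, maxMissed = 2L, mode = "full",
                   lengthBounds = c(1L, .Machine$integer.max),
                   glucResidues = "E") {
  stopifnot(maxMissed >= 0, lengthBounds[1] <= lengthBounds[2])
  n <- nchar(sequence)
  cut <- cleavagePositions(sequence, enzyme, glucResidues)
  bounds <- c(0L, cut, n)  # peptide i..j spans bounds[i]+1 .. bounds[j]

  out <- list()
  k <- length(bounds)
  for (i in seq_len(k - 1)) {
    maxj <- min(i + 1 + maxMissed, k)
    for (j in (i + 1):maxj) {
      s <- bounds[i] + 1L
      e <- bounds[j]
      out[[length(out) + 1L]] <- c(s, e, 0L)  # 0 = full
      if (mode == "semi" && e > s) {
        ## non-enzymatic C-terminus, N-terminus at the cleavage site
        inner <- setdiff(s:(e - 1L), bounds)
        for (e2 in inner) out[[length(out) + 1L]] <- c(s, e2, 2L)
        ## non-enzymatic N-terminus, C-terminus at the cleavage site
        inner <- setdiff((s + 1L):e, bounds + 1L)
        for (s2 in inner) out[[length(out) + 1L]] <- c(s2, e, 1L)
      }
    }
  }
  m <- do.call(rbind, out)
  len <- m[, 2] - m[, 1] + 1L
  keep <- len >= lengthBounds[1] & len <= lengthBounds[2]
  m <- m[keep, , drop = FALSE]
  spec <- c("full", "semi_n", "semi_c")[m[, 3] + 1L]
  res <- data.frame(peptide = substring(sequence, m[, 1], m[, 2]),
                    start = as.integer(m[, 1]), specificity = spec,
                    stringsAsFactors = FALSE)
  ## semi enumeration can regenerate a peptide reachable as fully enzymatic
  ## with more missed cleavages or duplicate a span across windows
  res <- res[!duplicated(res[, c("peptide", "start", "specificity")]), ,
             drop = FALSE]
  full <- res$specificity == "full"
  key <- paste(res$peptide, res$start)
  res <- res[full | !(key %in% key[full]), , drop = FALSE]
  rownames(res) <- NULL
  res
}
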