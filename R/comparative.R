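#' Cross-dataset identification overlap
#'
#' For every counted protein, the number k of whole-proteome datasets in
#' which it was confidently identified, binned over 0..n. Bin 0 holds the
#' counted proteins never identified, so the bins partition the counted
#' proteome.
#'
#' @param confidentSets Named list of character vectors: confident
#'   protein accessions per whole-proteome dataset.
#' @param db [ProteinDb-class].
#' @return list with `k` (named integer vector per counted protein) and
#'   `bins` (table over 0..n).
#' @export
datasetOverlap <- function(confidentSets, db) {
  acc <- countedAccessions(db)
  n <- length(confidentSets)
  k <- setNames(integer(length(acc)), acc)
  for (s in confidentSets) {
    hit <- intersect(s, acc)
    k[hit] <- k[hit] + 1L
  }
  bins <- table(factor(k, levels = 0:n))
  list(k = k, bins = bins)
}

#' arCOG class enrichment
#'
#' Tests, for every arCOG class, whether a protein group is enriched or
#' depleted relative to the background proteome using a two-sided
#' Fisher's exact test on the 2x2 table (in group / in class against the
#' complements), with Bonferroni adjustment over the number of classes
#' tested. Proteins without a class count outside every class.
#'
#' @param group Character vector of protein accessions.
#' @param db [ProteinDb-class]; the background is its counted proteome.
#' @return data.frame per class: `arcog_class`, `n_group`, `n_background`,
#'   `odds_ratio` (sample cross-product ratio), `p_value`, `p_adjusted`.
#' @export
arcogEnrichment <- function(group, db) {
  if (length(group) == 0) stop("empty protein group")
  e <- dbEntries(db, targetsOnly = TRUE)
  e <- e[!e$is_spurious, , drop = FALSE]
  inGroup <- e$accession %in% group
  classes <- sort(unique(e$arcog_class[!is.na(e$arcog_class)]))
  rows <- lapply(classes, function(cl) {
    inClass <- !is.na(e$arcog_class) & e$arcog_class == cl
    a <- sum(inGroup & inClass)
    b <- sum(inGroup & !inClass)
    c <- sum(!inGroup & inClass)
    d <- sum(!inGroup & !inClass)
    p <- fisher.test(matrix(c(a, b, c, d), nrow = 2),
                     alternative = "two.sided")$p.value
    orr <- if (b == 0 || c == 0) Inf else (a * d) / (b * c)
    data.frame(arcog_class = cl, n_group = a, n_background = a + c,
               odds_ratio = orr, p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- p.adjust(out$p_value, method = "bonferroni")
  rownames(out) <- NULL
  out
}

#' Identification rate of a gene window as a printed percentage
#'
#' @param count Identified genes in the window.
#' @param windowSize Window width in genes.
#' @return Percentage rounded half-up to one decimal.
#' @export
#' @examples
#' windowRatePercent(c(14, 20, 48))
windowRatePercent <- function(count, windowSize = 51L) {
  roundHalfUp(100 * count / windowSize, 1)
}

#' Genomic regions with low protein identification rates
#'
#' Slides a window of `2 * halfWindow + 1` genes along a replicon's gene
#' order (start of the coding region, regardless of strand) and counts
#' identified proteins among the covered genes; on circular replicons the
#' indices wrap around the origin. Genes whose window holds at most
#' `lowThreshold` identifications are low; maximal consecutive runs of
#' low genes (joined across the origin on circular replicons) are
#' reported as low-identification islands.
#'
#' @param identified Logical vector in gene order along the replicon.
#' @param circular Is the replicon circular?
#' @param halfWindow Genes considered on each side of the focal gene.
#' @param lowThreshold Maximum identified count for a low window.
#' @return list with `window_size`, `counts` (per-gene window counts),
#'   `rate_percent` (printed percentages), and `islands` (data.frame
#'   `start`, `end`, `length`, `min_rate_percent`; 0-based gene indices,
#'   `end` inclusive, possibly wrapping past the origin so `end` can be
#'   numerically smaller than `start`).
#' @export
scanLowIdentificationIslands <- function(identified, circular = TRUE,
                                         halfWindow = 25L,
                                         lowThreshold = 20L) {
  n <- length(identified)
  w <- 2L * halfWindow + 1L
  if (n < w) {
    if (!circular) stop("replicon shorter than the window and not circular")
    stop("replicon must hold at least one full window of genes")
  }
  x <- as.numeric(identified)
  if (circular) {
    ext <- c(tail(x, halfWindow), x, head(x, halfWindow))
    cum <- c(0, cumsum(ext))
    counts <- cum[(1:n) + w] - cum[1:n]
  } else {
    cum <- c(0, cumsum(x))
    lo <- pmax(seq_len(n) - halfWindow, 1L)
    hi <- pmin(seq_len(n) + halfWindow, n)
    counts <- cum[hi + 1L] - cum[lo]
  }
  low <- counts <= lowThreshold

  islands <- list()
  r <- rle(low)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (i in which(r$values)) {
    islands[[length(islands) + 1L]] <- c(starts[i], ends[i])
  }
  if (circular && length(islands) >= 2) {
    first <- islands[[1]]; last <- islands[[length(islands)]]
    if (first[1] == 1L && last[2] == n) {  # join across the origin
      islands[[length(islands)]] <- c(last[1], first[2])
      islands[[1]] <- NULL
    }
  }
  isl <- if (length(islands) == 0) {
    data.frame(start = integer(0), end = integer(0), length = integer(0),
               min_rate_percent = numeric(0))
  } else {
    do.call(rbind, lapply(islands, function(se) {
      idx <- if (se[2] >= se[1]) se[1]:se[2] else c(se[1]:n, 1:se[2])
      data.frame(start = se[1] - 1L, end = se[2] - 1L,
                 length = length(idx),
                 min_rate_percent = min(windowRatePercent(counts[idx], w)))
    }))
  }
  list(window_size = w, counts = counts,
       rate_percent = windowRatePercent(counts, w), islands = isl)
}
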