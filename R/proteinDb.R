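#' @importFrom Biostrings readAAStringSet AAStringSet writeXStringSet
NULL

newProteinDb <- function(entries, circular) {
  rownames(entries) <- NULL
  new("ProteinDb", entries = entries, circular = circular)
}

#' @rdname countedSize
#' @export
setMethod("countedSize", "ProteinDb", function(x) {
  sum(!x@entries$is_decoy & !x@entries$is_spurious)
})

#' @rdname dbEntries
#' @export
setMethod("dbEntries", "ProteinDb", function(x, targetsOnly = FALSE) {
  e <- x@entries
  if (targetsOnly) e <- e[!e$is_decoy, , drop = FALSE]
  rownames(e) <- NULL
  e
})

#' @rdname countedAccessions
#' @export
setMethod("countedAccessions", "ProteinDb", function(x) {
  e <- x@entries[!x@entries$is_decoy & !x@entries$is_spurious, , drop = FALSE]
  e <- e[order(e$replicon_id, e$gene_index), , drop = FALSE]
  e$accession
})

#' Replicon circularity flags
#' @param db A [ProteinDb-class].
#' @return Named logical vector.
#' @export
repliconCircularity <- function(db) db@circular

setMethod("show", "ProteinDb", function(object) {
  e <- object@entries
  cat(sprintf("ProteinDb: %d entries (%d targets, %d decoys)\n",
              nrow(e), sum(!e$is_decoy), sum(e$is_decoy)))
  cat(sprintf("  spurious: %d; counted size: %d\n",
              sum(e$is_spurious & !e$is_decoy), countedSize(object)))
  cat(sprintf("  replicons: %s\n",
              paste(sprintf("%s(%s)", names(object@circular),
                            ifelse(object@circular, "circular", "linear")),
                    collapse = ", ")))
})

defaultAnnotationRow <- function(accession) {
  data.frame(accession = accession, spurious = FALSE, replicon = "chr",
             gene_index = NA_integer_, strand = "+",
             arcog = NA_character_, stringsAsFactors = FALSE)
}

#' Load a protein database from FASTA plus annotations
#'
#' Reads a target proteome and its per-entry annotation table, merges
#' entries with identical sequences into one representative (chosen by a
#' seeded draw, with all member accessions recorded), and flags spurious
#' annotations. Spurious and redundant duplicate entries are excluded from
#' the counted database size.
#'
#' @param fastaPath Path to the target FASTA file.
#' @param annotations data.frame with columns `accession`, `spurious`
#'   (logical), `replicon`, `gene_index` (0-based), `strand`, `arcog`;
#'   or a path to a tab-separated file with those columns.
#' @param circular Named logical vector of per-replicon circularity flags;
#'   defaults to circular for every replicon seen (the organism's replicons
#'   are all circular).
#' @param seed Seed for the duplicate-representative draw.
#' @return A [ProteinDb-class] object.
#' @details Identical duplicate accessions (same accession, same sequence)
#'   are collapsed silently; the same accession with two different
#'   sequences is an error. Entries without an annotation row are kept with
#'   default annotations and a warning.
#' @export
loadProteome <- function(fastaPath, annotations, circular = NULL, seed = 1L) {
  seqs <- readAAStringSet(fastaPath)
  acc <- sub("\\s.*$", "", names(seqs))
  seqChar <- as.character(seqs)
  if (anyDuplicated(acc)) {
    dup <- unique(acc[duplicated(acc)])
    for (a in dup) {
      if (length(unique(seqChar[acc == a])) > 1) {
        stop(sprintf("accession %s occurs with different sequences", a))
      }
    }
    keep <- !duplicated(acc)
    acc <- acc[keep]; seqChar <- seqChar[keep]
  }
  if (is.character(annotations) && length(annotations) == 1) {
    annotations <- read.delim(annotations, stringsAsFactors = FALSE)
  }
  ann <- annotations[match(acc, annotations$accession), , drop = FALSE]
  missing <- is.na(ann$accession)
  if (any(missing)) {
    warning(sprintf("%d entries without annotation row; defaults used (e.g. %s)",
                    sum(missing), acc[which(missing)[1]]))
    for (i in which(missing)) ann[i, ] <- defaultAnnotationRow(acc[i])
  }

  ## merge identical sequences: one seeded-random representative per group
  grp <- match(seqChar, unique(seqChar))
  reps <- withSeed(seed, vapply(split(seq_along(acc), grp), function(idx) {
    idx[sample.int(length(idx), 1)]
  }, integer(1)))
  members <- vapply(split(acc, grp), function(a)
    paste(sort(a), collapse = ","), character(1))

  e <- data.frame(
    accession = acc[reps],
    sequence = seqChar[reps],
    is_spurious = as.logical(ann$spurious[reps]),
    duplicate_members = members,
    replicon_id = as.character(ann$replicon[reps]),
    gene_index = as.integer(ann$gene_index[reps]),
    strand = as.character(ann$strand[reps]),
    arcog_class = as.character(ann$arcog[reps]),
    is_decoy = FALSE,
    partner_accession = NA_character_,
    stringsAsFactors = FALSE
  )
  e <- e[order(e$replicon_id, e$gene_index, e$accession), , drop = FALSE]
  if (is.null(circular)) {
    circular <- setNames(rep(TRUE, length(unique(e$replicon_id))),
                         sort(unique(e$replicon_id)))
  }
  newProteinDb(e, circular)
}

#' Write a protein database to FASTA and annotation files
#'
#' Serializes a [ProteinDb-class] as a FASTA file (targets first, then
#' decoys, in replicon/gene order) plus a tab-separated annotation table,
#' the same formats [loadProteome()] consumes. Output is byte-deterministic
#' for a given database.
#'
#' @param db A [ProteinDb-class].
#' @param fastaPath Output FASTA path.
#' @param annotationPath Output annotation TSV path (optional).
#' @return Invisibly, `fastaPath`.
#' @export
writeProteinDb <- function(db, fastaPath, annotationPath = NULL) {
  e <- db@entries
  e <- e[order(e$is_decoy, e$replicon_id, e$gene_index, e$accession), ,
         drop = FALSE]
  set <- AAStringSet(setNames(e$sequence, e$accession))
  writeXStringSet(set, fastaPath)
  if (!is.null(annotationPath)) {
    ann <- data.frame(accession = e$accession, spurious = e$is_spurious,
                      replicon = e$replicon_id, gene_index = e$gene_index,
                      strand = e$strand, arcog = e$arcog_class,
                      duplicate_members = e$duplicate_members,
                      is_decoy = e$is_decoy,
                      partner_accession = e$partner_accession,
                      stringsAsFactors = FALSE)
    write.table(ann, annotationPath, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  invisible(fastaPath)
}
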