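PSM_COLUMNS <- c("spectrum_id", "dataset_id", "raw_file", "engine_ids",
                 "peptide", "modifications", "charge", "is_decoy",
                 "accessions", "enzyme", "specificity", "engine_peps",
                 "combined_pep")

#' Assemble a PSM table
#'
#' Builds the flat peptide-spectrum-match table the pipeline operates on.
#' Multi-valued fields are semicolon-joined strings: `engine_ids`
#' (`"msgf;xtandem"`), `accessions`, `modifications`
#' (`"name@pos;..."`, position 0 = peptide N-terminus) and `engine_peps`
#' (`"engine=pep;..."`).
#'
#' @param spectrum_id,dataset_id,raw_file,peptide Character vectors.
#' @param engine_ids,accessions,modifications,engine_peps Semicolon-joined
#'   character vectors as described above.
#' @param charge Integer vector.
#' @param is_decoy Logical vector.
#' @param enzyme `"trypsin"` or `"gluc"`, recycled.
#' @param specificity `"full"`, `"semi_n"` or `"semi_c"`, recycled.
#' @param combined_pep Numeric, `NA` until [combinePep()] has run.
#' @return data.frame with the PSM columns.
#' @export
psmTable <- function(spectrum_id, dataset_id, raw_file, engine_ids, peptide,
                     modifications = "", charge = 2L, is_decoy = FALSE,
                     accessions = "", enzyme = "trypsin",
                     specificity = "full", engine_peps,
                     combined_pep = NA_real_) {
  d <- data.frame(spectrum_id = spectrum_id, dataset_id = dataset_id,
                  raw_file = raw_file, engine_ids = engine_ids,
                  peptide = peptide, modifications = modifications,
                  charge = as.integer(charge), is_decoy = is_decoy,
                  accessions = accessions, enzyme = enzyme,
                  specificity = specificity, engine_peps = engine_peps,
                  combined_pep = combined_pep, stringsAsFactors = FALSE)
  validatePsmTable(d)
  d
}

validatePsmTable <- function(psms) {
  missing <- setdiff(PSM_COLUMNS, names(psms))
  if (length(missing) > 0) {
    stop("PSM table missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(psms) > 0) {
    if (any(nchar(psms$peptide) < 1)) stop("empty peptide in PSM table")
    if (any(psms$engine_peps == "")) stop("PSM without engine PEPs")
  }
  invisible(psms)
}

## engine_peps "a=0.1;b=0.2" -> named numeric list-column access
parseEnginePeps <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE), function(kv) {
    parts <- strsplit(kv, "=", fixed = TRUE)
    setNames(as.numeric(vapply(parts, `[`, "", 2)),
             vapply(parts, `[`, "", 1))
  })
}

formatEnginePeps <- function(peps) {
  vapply(peps, function(p)
    paste(sprintf("%s=%.6g", names(p), p), collapse = ";"), character(1))
}

## canonical engine-set key, order-independent
engineSetKey <- function(engine_ids) {
  vapply(strsplit(engine_ids, ";", fixed = TRUE), function(e)
    paste(sort(e), collapse = ";"), character(1))
}

## modifications "name@pos;..." -> data.frame(name, position)
parseModifications <- function(x) {
  lapply(strsplit(x, ";", fixed = TRUE), function(m) {
    m <- m[nzchar(m)]
    if (length(m) == 0) {
      return(data.frame(name = character(0), position = integer(0)))
    }
    parts <- strsplit(m, "@", fixed = TRUE)
    data.frame(name = vapply(parts, `[`, "", 1),
               position = as.integer(vapply(parts, `[`, "", 2)),
               stringsAsFactors = FALSE)
  })
}

#' Read or write a PSM table
#'
#' PSM tables are tab-separated text with the columns of [psmTable()].
#'
#' @param path File path.
#' @param psms PSM data.frame.
#' @return `readPsmTable` returns the PSM data.frame; `writePsmTable`
#'   invisibly returns `path`.
#' @export
readPsmTable <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE,
                  colClasses = c(combined_pep = "numeric"))
  d$modifications[is.na(d$modifications)] <- ""
  validatePsmTable(d)
  d
}

#' @rdname readPsmTable
#' @export
writePsmTable <- function(psms, path) {
  validatePsmTable(psms)
  write.table(psms, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
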