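#' Read a protein database from FASTA
#'
#' Accessions are parsed from the header up to the first whitespace;
#' sequences are upper-cased and molecular weights computed from sequence.
#' Decoy entries are recognized by the `DECOY_` accession prefix.
#'
#' @param path FASTA file path.
#' @return Protein data.frame: `id`, `symbol` (the header description, or
#'   the accession when absent), `sequence`, `mw`, `category` (`NA`),
#'   `is_decoy`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  aas <- Biostrings::readAAStringSet(path)
  if (length(aas) == 0L) stop("empty FASTA file: ", path)
  hdr <- names(aas)
  id <- sub("\\s.*$", "", hdr)
  desc <- trimws(sub("^\\S+", "", hdr))
  seqs <- toupper(as.character(aas))
  data.frame(
    id = id,
    symbol = ifelse(nzchar(desc), desc, id),
    sequence = unname(seqs),
    mw = protein_mw(seqs),
    category = NA_character_,
    is_decoy = startsWith(id, "DECOY_"),
    stringsAsFactors = FALSE
  )
}

#' Write a protein table to FASTA
#'
#' Sequences are wrapped at 60 columns; headers are the accession alone.
#'
#' @param proteins Protein data.frame (`id`, `sequence`).
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  aas <- Biostrings::AAStringSet(setNames(proteins$sequence, proteins$id))
  Biostrings::writeXStringSet(aas, path, width = 60L)
  invisible(path)
}

.write_tsv <- function(df, path) {
  # atomic write: temp file in the same directory, then rename
  tmp <- paste0(path, ".tmp")
  write.table(df, tmp, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  file.rename(tmp, path)
  invisible(path)
}

#' Write a PSM table in the pipeline's TSV dialect
#'
#' Columns: peptide, proteins (semicolon-separated accessions), charge,
#' score, spi, fraction, replicate, slice, is_decoy. Extra columns (such
#' as the simulator's ground-truth `is_noise` flag) are appended after the
#' dialect columns when `extra = TRUE`.
#'
#' @param psms PSM data.frame.
#' @param path Output path.
#' @param extra Keep non-dialect columns.
#' @return The path, invisibly.
#' @export
write_psms <- function(psms, path, extra = FALSE) {
  core <- c("peptide", "proteins", "charge", "score", "spi",
            "fraction", "replicate", "slice", "is_decoy")
  stopifnot(all(core %in% names(psms)))
  cols <- if (extra) c(core, setdiff(names(psms), core)) else core
  .write_tsv(psms[, cols, drop = FALSE], path)
}

#' Read a PSM table written by [write_psms()]
#'
#' @param path TSV path.
#' @return PSM data.frame.
#' @export
read_psms <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE)
  need <- c("peptide", "proteins", "charge", "score", "spi",
            "fraction", "replicate", "slice", "is_decoy")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L)
    stop("PSM table missing column(s): ", paste(miss, collapse = ", "))
  df$is_decoy <- as.logical(df$is_decoy)
  if ("is_noise" %in% names(df)) df$is_noise <- as.logical(df$is_noise)
  df
}

#' Write the ground-truth table of a simulation
#'
#' @param truth Truth data.frame from [generate_proteome()].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_truth <- function(truth, path) .write_tsv(truth, path)

#' Read a ground-truth table
#' @param path TSV path.
#' @return Truth data.frame.
#' @export
read_truth <- function(path) read.delim(path, stringsAsFactors = FALSE)
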