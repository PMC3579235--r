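#' Read a FASTA file into a tibble
#'
#' @param path Path to a FASTA file (optionally gzip-compressed).
#' @return A tibble with columns `name` and `sequence`.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  tibble(name = names(x), sequence = unname(as.character(x)))
}

#' Write sequences to FASTA
#'
#' @param seqs A data frame with columns `name` (or `transcript_id`/`read_id`)
#'   and `sequence`.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  nm <- intersect(c("name", "transcript_id", "read_id"), names(seqs))[1]
  if (is.na(nm)) abort("`seqs` needs a `name`, `transcript_id` or `read_id` column")
  x <- Biostrings::DNAStringSet(setNames(seqs$sequence, seqs[[nm]]))
  Biostrings::writeXStringSet(x, path, format = "fasta",
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file into a tibble
#'
#' Qualities are not retained: tag extraction operates on base calls only.
#'
#' @param path Path to a FASTQ file (optionally gzip-compressed).
#' @return A tibble with columns `read_id` and `sequence`.
#' @export
read_fastq <- function(path) {
  x <- tryCatch(
    Biostrings::readDNAStringSet(path, format = "fastq"),
    error = function(e) abort(paste0("malformed FASTQ in '", path, "': ",
                                     conditionMessage(e)))
  )
  tibble(read_id = names(x), sequence = unname(as.character(x)))
}

#' Write reads to FASTQ with constant Q40 qualities
#'
#' Simulated reads carry no base-call uncertainty, so every base is written
#' with Sanger-scale quality 40 (`"I"`).
#'
#' @param reads A data frame with columns `read_id` and `sequence`.
#' @param path Output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  q <- Biostrings::PhredQuality(
    vapply(nchar(reads$sequence), function(n) strrep("I", n), character(1))
  )
  Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

as_reads_tibble <- function(reads, format = c("fastq", "fasta")) {
  format <- match.arg(format)
  if (is.character(reads) && length(reads) == 1 && file.exists(reads)) {
    return(if (format == "fastq") read_fastq(reads) else read_fasta(reads))
  }
  if (is.data.frame(reads)) {
    if (!"sequence" %in% names(reads)) abort("`reads` must have a `sequence` column")
    return(as_tibble(reads))
  }
  abort("`reads` must be a data frame or a path to an existing file")
}
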