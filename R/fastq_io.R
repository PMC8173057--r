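# FASTQ I/O thin wrappers over Biostrings (handles .gz transparently).

#' Read a FASTQ(.gz) file
#'
#' @param path FASTQ or FASTQ.gz file.
#' @return List with character vectors `id`, `seq`, `qual`.
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  list(id = names(x),
       seq = as.character(x, use.names = FALSE),
       qual = as.character(S4Vectors::mcols(x)$qualities, use.names = FALSE))
}

#' Write a FASTQ file (gzip-compressed if the path ends in .gz)
#'
#' @param ids Read identifiers.
#' @param seqs Sequences.
#' @param quals Quality strings (same lengths as `seqs`).
#' @param path Output path.
#' @export
write_fastq <- function(ids, seqs, quals, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(
    x, filepath = path, format = "fastq",
    qualities = Biostrings::BStringSet(quals),
    compress = grepl("\\.gz$", path))
  invisible(path)
}
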