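# Thin FASTQ wrappers around Biostrings (gzip-transparent).

#' Read and write FASTQ files
#'
#' `read_fastq()` returns sequences as a named character vector (names =
#' read ids); `write_fastq()` writes sequences with a constant quality
#' string (synthetic reads carry no meaningful qualities).
#'
#' @param path FASTQ path; `.gz` handled transparently.
#' @param seqs Named character vector of sequences (names become read ids).
#' @param quality_char Single character used for every base quality
#'   (default `"I"`, Phred 40).
#' @param compress Gzip the output (default from the file extension).
#' @return `read_fastq()`: named character vector. `write_fastq()`: `path`,
#'   invisibly.
#' @export
read_fastq <- function(path) {
  set <- Biostrings::readDNAStringSet(path, format = "fastq")
  setNames(as.character(set), names(set))
}

#' @rdname read_fastq
#' @export
write_fastq <- function(seqs, path, quality_char = "I",
                        compress = grepl("\\.gz$", path)) {
  set <- Biostrings::DNAStringSet(seqs)
  quals <- Biostrings::BStringSet(vapply(nchar(seqs), function(w) {
    strrep(quality_char, w)
  }, ""))
  Biostrings::writeXStringSet(set, filepath = path, format = "fastq",
                              qualities = quals, compress = compress)
  invisible(path)
}
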