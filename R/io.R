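#' Read sequences from FASTA or FASTQ (optionally gzipped)
#'
#' Format is detected from the file extension (`.fq`/`.fastq` vs
#' everything else), with `.gz` handled transparently.
#' @param file path
#' @return named character vector of sequences
#' @export
read_sequences <- function(file) {
  base <- sub("\\.gz$", "", file)
  fmt <- if (grepl("\\.(fq|fastq)$", base, ignore.case = TRUE)) "fastq"
         else "fasta"
  x <- Biostrings::readDNAStringSet(file, format = fmt)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' Write a named character vector as FASTA
#' @param seqs named character vector
#' @param file output path
#' @export
write_fasta <- function(seqs, file) {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- names(seqs)
  Biostrings::writeXStringSet(x, file, width = 80L)
  invisible(file)
}

#' Write a named character vector as FASTQ (constant quality)
#' @param seqs named character vector
#' @param file output path
#' @param qual quality character applied to every base (default "I", Q40)
#' @export
write_fastq <- function(seqs, file, qual = "I") {
  x <- Biostrings::DNAStringSet(unlist(seqs))
  names(x) <- names(seqs)
  q <- Biostrings::BStringSet(vapply(nchar(seqs), function(n) {
    paste(rep(qual, n), collapse = "")
  }, character(1)))
  Biostrings::writeXStringSet(x, file, format = "fastq", qualities = q)
  invisible(file)
}

#' Write contigs as FASTA with descriptive headers
#'
#' Headers follow `<id> length=<n> circular=<yes|no> coverage=<x>`.
#' @param contigs list of `contig` objects
#' @param file output path
#' @export
write_contigs <- function(contigs, file) {
  if (length(contigs) == 0L) {
    con <- file(file, "w"); close(con)
    return(invisible(file))
  }
  seqs <- vapply(contigs, function(x) x$seq, character(1))
  names(seqs) <- vapply(contigs, function(x) {
    sprintf("%s length=%d circular=%s coverage=%g", x$id, x$length,
            if (x$is_circular) "yes" else "no", x$coverage)
  }, character(1))
  write_fasta(seqs, file)
}
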