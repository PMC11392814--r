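#' k'-min-mer abundance table
#'
#' Counts canonical k'-min-mers (windows of k' consecutive minimizers) by
#' sliding a window over each input minimizer sequence, exactly as in
#' classical k-mer counting. Sequences flagged circular (mContigs emitted
#' from circular unitigs) are scanned cyclically, so the windows wrap around
#' the origin. Sequences with fewer than k' minimizers contribute nothing.
#'
#' @param x an `mread_set`, a list of `mread`/`mcontig` objects, or a list
#'   of integer minimizer vectors (optionally with a `circular` attribute)
#' @param kprime window size k' (>= 2)
#' @return an object of class `abundance_table` with fields `kprime`,
#'   `keys` (canonical tuples as comma-joined strings, sorted), `abundance`,
#'   `tuples` (canonical integer tuples) and `refined`
#' @export
count_kminmers <- function(x, kprime) {
  stopifnot(kprime >= 2)
  ms <- .minimizer_seqs(x)
  tab <- cpp_count_kminmers(ms$seqs, ms$circular, as.integer(kprime))
  structure(list(kprime = as.integer(kprime),
                 keys = tab$keys,
                 abundance = tab$abundance,
                 tuples = tab$tuples,
                 refined = FALSE),
            class = "abundance_table")
}

#' @export
print.abundance_table <- function(x, ...) {
  cat(sprintf("abundance_table: k'=%d, %d k'-min-mers, %s\n", x$kprime,
              length(x$keys), if (x$refined) "refined" else "raw"))
  invisible(x)
}

#' Read-local initial abundance filter
#'
#' For every read, the read coverage R_cov is estimated as the median
#' abundance of its constituent k'-min-mers and a cutoff R_min = R_cov *
#' beta_err is derived. A k'-min-mer is discarded iff its abundance equals 1
#' and 1 < R_min, i.e. only within reads whose estimated coverage exceeds
#' 1/beta_err. This removes the bulk of erroneous k'-min-mers on deeply
#' covered genomes while leaving rare species untouched; remaining errors
#' are handled later by the progressive abundance filter. All R_cov values
#' are computed before any removal, so the outcome does not depend on read
#' order.
#'
#' @param x the reads (same types as [count_kminmers()])
#' @param table an unrefined `abundance_table` over `x`
#' @param beta_err read-local abundance factor (default 0.1)
#' @return the filtered `abundance_table`
#' @export
initial_filter <- function(x, table, beta_err = 0.1) {
  stopifnot(inherits(table, "abundance_table"), !isTRUE(table$refined))
  ms <- .minimizer_seqs(x)
  res <- cpp_initial_filter(ms$seqs, ms$circular, table$kprime, table$keys,
                            table$abundance, beta_err)
  keep <- res$keep
  table$keys <- table$keys[keep]
  table$abundance <- table$abundance[keep]
  table$tuples <- table$tuples[keep]
  table
}

#' Abundance smoothing and long-contig rescue
#'
#' For each mContig, the refined abundance C_cov is the median abundance of
#' its constituent k'-min-mers, and every constituent k'-min-mer's abundance
#' is set to C_cov. In mContigs longer than 2k' k'-min-mers (too long to be
#' error artefacts), any k'-min-mer left at abundance 1 is rescued by
#' incrementing it to 2, so that it survives the next iteration's filter.
#'
#' @param mcontigs list of `mcontig` objects from the current iteration
#' @param table the current `abundance_table`
#' @return the refined `abundance_table`
#' @export
smooth_and_rescue <- function(mcontigs, table) {
  stopifnot(inherits(table, "abundance_table"))
  if (length(mcontigs) == 0L) {
    table$refined <- TRUE
    return(table)
  }
  ms <- .minimizer_seqs(mcontigs)
  table$abundance <- cpp_smooth_rescue(ms$seqs, ms$circular, table$kprime,
                                       table$keys, table$abundance)
  table$refined <- TRUE
  table
}

#' Propagate refined abundances to the next k'
#'
#' Every distinct k'-min-mer present in the inputs (mReads plus the previous
#' iteration's mContigs) contains two overlapping (k'-1)-min-mers whose
#' refined abundances are known from the previous iteration. Its abundance
#' is the minimum of the two (the minimum, not the mean, so an erroneous
#' parent is never inflated by a correct one). k'-min-mers with a missing
#' parent (filtered upstream) or with propagated abundance 1 are discarded.
#'
#' @param x mReads and mContigs feeding the new iteration
#' @param prev_table refined `abundance_table` at k'-1
#' @param kprime the new window size (default `prev_table$kprime + 1`)
#' @return an `abundance_table` at `kprime`
#' @export
propagate_abundance <- function(x, prev_table, kprime = prev_table$kprime + 1L) {
  stopifnot(inherits(prev_table, "abundance_table"),
            kprime == prev_table$kprime + 1L)
  ms <- .minimizer_seqs(x)
  tab <- cpp_propagate(ms$seqs, ms$circular, as.integer(kprime),
                       prev_table$keys, prev_table$abundance)
  structure(list(kprime = as.integer(kprime),
                 keys = tab$keys,
                 abundance = tab$abundance,
                 tuples = tab$tuples,
                 refined = FALSE,
                 n_dropped = tab$n_dropped),
            class = "abundance_table")
}

#' Dump an abundance table as TSV
#' @param table an `abundance_table`
#' @param file output path
#' @export
write_abundance_tsv <- function(table, file) {
  utils::write.table(
    data.frame(kminmer = table$keys, abundance = table$abundance),
    file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
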