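#' Universal minimizer selection scheme
#'
#' A universal minimizer is a k-mer m whose hash value falls below d*H for a
#' fixed 64-bit hash f with range \[0, H) (H = 2^64). Selection is
#' position-independent: no window is involved, so an expected fraction d of
#' all k-mers is selected, wherever they occur. The hash is applied to the
#' 2-bit encoding of the canonical form of the k-mer (the lexicographic
#' minimum of the k-mer and its reverse complement), which makes selection
#' strand-symmetric.
#'
#' @param k minimizer length in bases (default 13; must be <= 15 so the
#'   2-bit encoding fits an R integer)
#' @param d selection density in (0, 1) (default 0.005)
#' @param seed seed of the deterministic 64-bit hash (splitmix64)
#' @return an object of class `minimizer_scheme`
#' @export
minimizer_scheme <- function(k = 13L, d = 0.005, seed = 42) {
  stopifnot(k >= 3, k <= 15, d > 0, d < 1)
  structure(list(k = as.integer(k), d = as.numeric(d), seed = as.numeric(seed),
                 hash = "splitmix64"),
            class = "minimizer_scheme")
}

#' @export
print.minimizer_scheme <- function(x, ...) {
  cat(sprintf("minimizer scheme: k=%d, d=%g, hash=%s(seed=%g)\n",
              x$k, x$d, x$hash, x$seed))
  invisible(x)
}

#' Homopolymer compression
#'
#' Collapses every run of identical bases to a single base. The second
#' element maps each compressed position back to the half-open run
#' `[start, end)` (0-based) in the original sequence, so that base-space
#' spans can later be cut from the original read with full runs intact.
#'
#' @param seq a DNA string over A,C,G,T,N
#' @return list with `hpc` (compressed string) and `runs` (two-column
#'   integer matrix of 0-based half-open run coordinates, one row per
#'   compressed position)
#' @export
homopolymer_compress <- function(seq) {
  r <- cpp_hpc_compress(seq)
  runs <- cbind(start = r$run_start, end = r$run_end)
  list(hpc = r$hpc, runs = runs)
}

#' Invert homopolymer compression
#'
#' Reconstructs the original sequence from a compressed sequence and its run
#' map (each compressed base is repeated over its original run).
#' @param hpc compressed sequence
#' @param runs run matrix as returned by [homopolymer_compress()]
#' @export
homopolymer_decompress <- function(hpc, runs) {
  if (nchar(hpc) == 0L) return("")
  chars <- strsplit(hpc, "", fixed = TRUE)[[1]]
  paste(rep(chars, times = runs[, "end"] - runs[, "start"]), collapse = "")
}

#' Canonical form of a k-mer
#'
#' The lexicographic minimum of a k-mer and its reverse complement.
#' Vectorised; k-mers containing non-ACGT characters yield `NA`.
#' @param kmer character vector of k-mers
#' @export
canonical_kmer <- function(kmer) {
  cpp_canonical_kmer(kmer)
}

#' Universal-minimizer membership test
#'
#' TRUE iff f(canonical(kmer)) < d*H under the scheme's hash. k-mers with
#' non-ACGT characters yield `NA` (windows containing them are skipped
#' during scanning).
#' @param kmer character vector of k-mers (each of length `scheme$k`)
#' @param scheme a [minimizer_scheme()]
#' @export
is_universal_minimizer <- function(kmer, scheme) {
  cpp_is_minimizer(kmer, scheme$k, scheme$d, scheme$seed)
}

#' Convert a read to minimizer space
#'
#' Homopolymer-compresses the read, slides a k-window over the compressed
#' sequence and records every window passing the universal-minimizer test,
#' in order. Each minimizer is stored as the integer 2-bit encoding of its
#' canonical k-mer together with its 0-based position in the compressed
#' sequence and its half-open span in the original read (spans cover whole
#' homopolymer runs).
#'
#' @param read_id identifier
#' @param seq read sequence
#' @param scheme a [minimizer_scheme()]
#' @return an object of class `mread`
#' @export
extract_mread <- function(read_id, seq, scheme) {
  hp <- cpp_hpc_compress(seq)
  sc <- cpp_scan_minimizers(hp$hpc, scheme$k, scheme$d, scheme$seed)
  # a window touching the first or last compressed position may sit on a
  # homopolymer run truncated by the read boundary; its original-coordinate
  # span would not cover the full run, so such windows are not used
  hpc_len <- nchar(hp$hpc)
  keep <- sc$pos >= 1L & sc$pos + scheme$k <= hpc_len - 1L
  sc$values <- sc$values[keep]
  sc$pos <- sc$pos[keep]
  n <- length(sc$values)
  if (n > 0L) {
    orig_start <- hp$run_start[sc$pos + 1L]
    orig_end <- hp$run_end[sc$pos + scheme$k]
  } else {
    orig_start <- integer(0)
    orig_end <- integer(0)
  }
  structure(list(read_id = read_id,
                 minimizers = sc$values,
                 hpc_pos = sc$pos,
                 orig_start = orig_start,
                 orig_end = orig_end,
                 source_len = nchar(seq),
                 hpc_len = nchar(hp$hpc)),
            class = "mread")
}

#' Convert a set of reads to minimizer space
#'
#' @param seqs named character vector or `Biostrings::DNAStringSet`
#' @param scheme a [minimizer_scheme()]
#' @return list of `mread` objects (class `mread_set`)
#' @export
extract_mreads <- function(seqs, scheme) {
  if (inherits(seqs, "XStringSet")) {
    nm <- names(seqs)
    seqs <- as.character(seqs)
    names(seqs) <- nm
  }
  if (is.null(names(seqs))) names(seqs) <- paste0("read", seq_along(seqs))
  out <- vector("list", length(seqs))
  for (i in seq_along(seqs)) {
    out[[i]] <- extract_mread(names(seqs)[i], seqs[[i]], scheme)
  }
  names(out) <- names(seqs)
  class(out) <- "mread_set"
  out
}

#' @export
print.mread <- function(x, ...) {
  cat(sprintf("mRead %s: %d minimizers over %d bp (hpc %d bp)\n",
              x$read_id, length(x$minimizers), x$source_len, x$hpc_len))
  invisible(x)
}

#' @export
print.mread_set <- function(x, ...) {
  nm <- vapply(x, function(r) length(r$minimizers), integer(1))
  cat(sprintf("mread_set: %d reads, %d minimizers total (median %d/read)\n",
              length(x), sum(nm), as.integer(stats::median(nm))))
  invisible(x)
}

#' Canonicalize a k'-min-mer window
#'
#' Compares a window of minimizer values against its reversal element by
#' element; the variant whose first differing element is smaller is the
#' canonical representative. A palindromic window (equal to its reversal)
#' canonicalizes to itself with `is_reversed = FALSE`.
#'
#' @param window integer vector of k' minimizer values
#' @return list with `mins` (canonical tuple) and `is_reversed`
#' @export
canonicalize_kminmer <- function(window) {
  cpp_canonicalize_kminmer(as.integer(window))
}

#' Reverse complement of a DNA string
#' @param seq DNA string
#' @export
revcomp <- function(seq) cpp_revcomp(seq)

# internal: minimizer sequences + circularity flags from mixed input
.minimizer_seqs <- function(x) {
  if (inherits(x, "mread")) x <- list(x)
  if (inherits(x, "mread_set")) x <- unclass(x)
  seqs <- vector("list", length(x))
  circ <- logical(length(x))
  for (i in seq_along(x)) {
    xi <- x[[i]]
    if (inherits(xi, "mread")) {
      seqs[[i]] <- as.integer(xi$minimizers)
    } else if (inherits(xi, "mcontig")) {
      seqs[[i]] <- as.integer(xi$minimizers)
      circ[i] <- isTRUE(xi$is_circular)
    } else {
      seqs[[i]] <- as.integer(xi)
      circ[i] <- isTRUE(attr(xi, "circular"))
    }
  }
  list(seqs = seqs, circular = circ)
}
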