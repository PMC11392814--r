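#' Assembly configuration
#'
#' The four critical parameters are the minimizer size `k` (13), the
#' minimizer density `d` (0.005), and the starting and ending k'-min-mer
#' sizes `kprime_min` (4) and `kprime_max` (derived from the median read
#' length unless overridden). With the defaults, the assembler initially
#' considers read overlaps of (4-1)/0.005 = 600 bases on average and grows
#' them in increments of 1/0.005 = 200 bases per iteration.
#'
#' @param k minimizer length (default 13)
#' @param d minimizer density (default 0.005)
#' @param kprime_min starting k' (default 4)
#' @param kprime_max ending k'; `NULL` derives it from the reads as
#'   `round(median_hpc_read_length * d * 2)`
#' @param beta_err read-local initial filter factor (default 0.1)
#' @param beta_contig local abundance factor of the contig generator
#'   (default 0.5): a unitig of abundance a in snapshot S_t is emitted only
#'   if a >= t / beta_contig
#' @param strict_contig_threshold if TRUE use a > t / beta_contig instead
#' @param tip_max_len_bp,bubble_max_len_bp simplification caps (default 50 kb)
#' @param hash_seed minimizer hash seed
#' @param polish_window,polish_max_frags polishing window size (500) and
#'   fragment cap (20)
#' @param template_min_len minimum contig length to act as a purge template
#'   (default 1 Mb)
#' @param min_identity identity threshold for purging and evaluation (0.99)
#' @export
assembly_config <- function(k = 13L, d = 0.005, kprime_min = 4L,
                            kprime_max = NULL, beta_err = 0.1,
                            beta_contig = 0.5,
                            strict_contig_threshold = FALSE,
                            tip_max_len_bp = 50000,
                            bubble_max_len_bp = 50000,
                            hash_seed = 42,
                            polish_window = 500L, polish_max_frags = 20L,
                            template_min_len = 1e6, min_identity = 0.99) {
  stopifnot(kprime_min >= 2L, beta_contig > 0, beta_contig <= 1)
  structure(list(k = as.integer(k), d = d, kprime_min = as.integer(kprime_min),
                 kprime_max = if (is.null(kprime_max)) NULL
                              else as.integer(kprime_max),
                 beta_err = beta_err, beta_contig = beta_contig,
                 strict_contig_threshold = strict_contig_threshold,
                 tip_max_len_bp = tip_max_len_bp,
                 bubble_max_len_bp = bubble_max_len_bp,
                 hash_seed = hash_seed,
                 polish_window = as.integer(polish_window),
                 polish_max_frags = as.integer(polish_max_frags),
                 template_min_len = template_min_len,
                 min_identity = min_identity),
            class = "assembly_config")
}

#' @export
print.assembly_config <- function(x, ...) {
  cat(sprintf(paste0("assembly_config: k=%d d=%g k'=%d..%s beta_err=%g ",
                     "beta_contig=%g\n"),
              x$k, x$d, x$kprime_min,
              if (is.null(x$kprime_max)) "auto" else x$kprime_max,
              x$beta_err, x$beta_contig))
  invisible(x)
}

#' Final k'-min-mer size from the read length distribution
#'
#' `kprime_max = round(median_read_len_hpc * d * 2)`, floored at
#' `kprime_min + 1`: the last iteration processes overlaps of about twice
#' the median (homopolymer-compressed) read length.
#'
#' @param median_read_len_hpc median compressed read length in bases
#' @param d minimizer density
#' @param kprime_min starting k'
#' @export
compute_kprime_max <- function(median_read_len_hpc, d = 0.005,
                               kprime_min = 4L) {
  stopifnot(median_read_len_hpc > 0)
  max(as.integer(round(median_read_len_hpc * d * 2)), kprime_min + 1L)
}

#' Mean initial overlap span in bases
#'
#' At the first iteration the assembler connects reads sharing k'_min
#' consecutive minimizers, i.e. overlaps of (kprime_min - 1)/d bases on
#' average (600 with the defaults).
#' @param config an [assembly_config()]
#' @export
initial_overlap_bp <- function(config = assembly_config()) {
  (config$kprime_min - 1) / config$d
}

#' Overlap growth per iteration in bases
#'
#' Each k' increment lengthens the processed overlaps by 1/d bases on
#' average (200 with the defaults).
#' @param config an [assembly_config()]
#' @export
overlap_increment_bp <- function(config = assembly_config()) {
  1 / config$d
}

#' Local progressive abundance filter
#'
#' Iterates an abundance threshold t from 1 to t_max (the abundance of the
#' most abundant unitig of the initial compacted graph). At each step the
#' graph is simplified (tips clipped, superbubbles popped) and compacted,
#' the surviving unitigs are recorded as the snapshot S_t, and unitigs with
#' abundance <= t are then removed before the next step. Fragmented unitigs
#' of abundant genomes get merged into longer ones as complexity below their
#' own depth is stripped away, so each genome converges to its longest form
#' in the snapshots taken just below half its coverage depth.
#'
#' @param graph an `mdbg` with abundances set
#' @param tip_max_len_bp,bubble_max_len_bp simplification caps
#' @return list of snapshots (class `unitig_snapshots`); each snapshot is a
#'   `unitig_set` whose paths reference the nodes of `graph`
#' @export
progressive_filter <- function(graph, tip_max_len_bp = 50000,
                               bubble_max_len_bp = 50000) {
  stopifnot(inherits(graph, "mdbg"))
  snaps <- cpp_progressive_filter(unclass(graph), tip_max_len_bp,
                                  bubble_max_len_bp, 0L)
  snaps <- lapply(snaps, function(s) {
    structure(c(s, list(kprime = graph$kprime, d = graph$d)),
              class = "unitig_set")
  })
  structure(snaps, class = "unitig_snapshots", kprime = graph$kprime)
}

#' Generate mContigs from progressive-filter snapshots
#'
#' Iterates the snapshots from the highest threshold down to t = 1 (so that
#' every unitig is seen in its longest, maximally merged form first). Within
#' each snapshot, unitigs are scanned in a deterministic order (decreasing
#' abundance, then decreasing node count, then lexicographically smallest
#' spelled minimizer sequence) and a unitig with abundance a is emitted iff
#' it shares no k'-min-mer with any previously emitted mContig and
#' a >= t / beta_contig. Emitted node sets are recorded so the output is
#' non-redundant by construction; this invariant is re-verified on every
#' call and violation is an error.
#'
#' @param snapshots a `unitig_snapshots` from [progressive_filter()]
#' @param graph the `mdbg` the snapshots refer to
#' @param beta_contig local abundance factor (default 0.5)
#' @param strict if TRUE require a > t / beta_contig (default FALSE: >=)
#' @return list of `mcontig` objects
#' @export
generate_mcontigs <- function(snapshots, graph, beta_contig = 0.5,
                              strict = FALSE) {
  stopifnot(inherits(graph, "mdbg"))
  n_nodes <- length(graph$keys)
  emitted <- logical(n_nodes)
  out <- list()
  for (t in rev(seq_along(snapshots))) {
    s <- snapshots[[t]]
    n_u <- length(s$path)
    if (n_u == 0L) next
    spells <- lapply(seq_len(n_u), function(i) {
      .spell_path(s$path[[i]], graph$tuples, s$is_circular[i])
    })
    spell_keys <- vapply(spells, paste, character(1), collapse = ",")
    ord <- order(-s$abundance, -lengths(s$path),
                 xtfrm(spell_keys), method = "radix")
    thr <- t / beta_contig
    for (i in ord) {
      a <- s$abundance[i]
      pass <- if (strict) a > thr else a >= thr
      if (!pass) next
      nodes <- abs(s$path[[i]])
      if (any(emitted[nodes])) next
      emitted[nodes] <- TRUE
      out[[length(out) + 1L]] <- structure(
        list(minimizers = spells[[i]],
             abundance = a,
             is_circular = s$is_circular[i],
             tip_derived = s$tip_derived[i],
             born_at_kprime = graph$kprime),
        class = "mcontig")
    }
  }
  assert_nonredundant(out, graph$kprime)
  out
}

#' Verify the non-redundancy invariant of a set of mContigs
#'
#' No canonical k'-min-mer may occur in two emitted mContigs. Always
#' enforced after emission; an invariant violation is a defect, hence an
#' error rather than a warning.
#' @param mcontigs list of `mcontig`
#' @param kprime window size used for the check
#' @export
assert_nonredundant <- function(mcontigs, kprime) {
  if (length(mcontigs) < 2L) return(invisible(TRUE))
  keys <- unlist(lapply(mcontigs, function(mc) {
    if (length(mc$minimizers) < kprime) return(character(0))
    cpp_window_keys(as.integer(mc$minimizers), isTRUE(mc$is_circular),
                    as.integer(kprime))
  }))
  if (anyDuplicated(keys)) {
    stop("non-redundancy invariant violated: a k'-min-mer occurs in two ",
         "emitted mContigs")
  }
  invisible(TRUE)
}

#' @export
print.mcontig <- function(x, ...) {
  cat(sprintf("mcontig: %d minimizers, abundance %g, %s (k'=%d)\n",
              length(x$minimizers), x$abundance,
              if (x$is_circular) "circular" else "linear", x$born_at_kprime))
  invisible(x)
}

#' Multi-k' minimizer-space assembly
#'
#' Extracts mReads once, then iterates k' from `kprime_min` to `kprime_max`
#' in increments of 1. Each iteration counts k'-min-mers over the mReads
#' plus the previous iteration's mContigs (raw counting with the read-local
#' initial filter at k'_min; refined-abundance propagation afterwards),
#' builds the graph, runs the progressive abundance filter, emits mContigs,
#' and refines abundances (smoothing + rescue) for the next iteration.
#' mContigs too short to produce any window at the current k' bypass the
#' iteration and are carried forward unchanged.
#'
#' @param reads an `mread_set` (or a named character vector / DNAStringSet
#'   of read sequences, converted using the scheme implied by `config`)
#' @param config an [assembly_config()]
#' @param verbose print one line per iteration
#' @return object of class `msassembly`: final `mcontigs`, per-iteration
#'   `stats`, the final `graph`, the `scheme` and `config` used
#' @export
assemble <- function(reads, config = assembly_config(), verbose = FALSE) {
  scheme <- minimizer_scheme(config$k, config$d, config$hash_seed)
  if (!inherits(reads, "mread_set")) reads <- extract_mreads(reads, scheme)
  nmins <- vapply(reads, function(r) length(r$minimizers), integer(1))
  kmin <- config$kprime_min
  if (!any(nmins >= kmin)) {
    warning("no read has >= kprime_min minimizers; empty assembly")
    return(structure(list(mcontigs = list(), stats = NULL, graph = NULL,
                          scheme = scheme, config = config),
                     class = "msassembly"))
  }
  kmax <- config$kprime_max
  if (is.null(kmax)) {
    med_hpc <- stats::median(vapply(reads, function(r) r$hpc_len, integer(1)))
    kmax <- compute_kprime_max(med_hpc, config$d, kmin)
  }
  read_seqs <- lapply(reads, function(r) as.integer(r$minimizers))

  mcontigs <- list()
  prev_table <- NULL
  stats <- vector("list", kmax - kmin + 1L)
  graph <- NULL
  for (kp in kmin:kmax) {
    long_enough <- vapply(mcontigs, function(mc) {
      length(mc$minimizers) >= kp
    }, logical(1))
    # circular mContigs too short for the current k' are finished replicons:
    # carry them forward unchanged. Short linear leftovers stop producing
    # windows and drop out, as in any multi-k iteration scheme.
    carried <- Filter(function(mc) isTRUE(mc$is_circular),
                      mcontigs[!long_enough])
    active <- mcontigs[long_enough]
    inputs <- c(lapply(read_seqs, identity), lapply(active, identity))
    if (kp == kmin) {
      tab <- count_kminmers(inputs, kp)
      n_raw <- length(tab$keys)
      tab <- initial_filter(reads, tab, config$beta_err)
    } else {
      tab <- propagate_abundance(inputs, prev_table, kp)
      n_raw <- length(tab$keys) + tab$n_dropped
    }
    graph <- build_mdbg(tab, config$d)
    snaps <- progressive_filter(graph, config$tip_max_len_bp,
                                config$bubble_max_len_bp)
    mc <- generate_mcontigs(snaps, graph, config$beta_contig,
                            config$strict_contig_threshold)
    tab <- smooth_and_rescue(mc, tab)
    prev_table <- tab
    mcontigs <- c(mc, carried)
    nm <- vapply(mc, function(x) length(x$minimizers), integer(1))
    stats[[kp - kmin + 1L]] <- data.frame(
      kprime = kp, n_kminmers_raw = n_raw, n_kminmers = length(tab$keys),
      n_edges = nrow(graph$edges), n_snapshots = length(snaps),
      n_emitted = length(mc), n_carried = length(carried),
      n50_minimizers = .n50(nm))
    if (verbose) {
      message(sprintf(
        "k'=%d: %d k'-min-mers, %d edges, %d mContigs (+%d carried)",
        kp, length(tab$keys), nrow(graph$edges), length(mc),
        length(carried)))
    }
  }
  # deterministic final order: large contigs first
  ord <- order(-vapply(mcontigs, function(x) length(x$minimizers), integer(1)),
               xtfrm(vapply(mcontigs, function(x) {
                 paste(x$minimizers[seq_len(min(8, length(x$minimizers)))],
                       collapse = ",")
               }, character(1))), method = "radix")
  structure(list(mcontigs = mcontigs[ord],
                 stats = do.call(rbind, stats),
                 graph = graph,
                 kprime_final = kmax,
                 scheme = scheme,
                 config = config,
                 mreads = reads),
            class = "msassembly")
}

#' @export
print.msassembly <- function(x, ...) {
  nm <- vapply(x$mcontigs, function(m) length(m$minimizers), integer(1))
  cat(sprintf(
    "msassembly: %d mContigs (%d circular), ~%.0f bp total (1/d estimate)\n",
    length(x$mcontigs),
    sum(vapply(x$mcontigs, function(m) isTRUE(m$is_circular), logical(1))),
    sum(nm) / x$config$d))
  invisible(x)
}

.n50 <- function(lens) {
  if (length(lens) == 0L) return(0L)
  lens <- sort(lens, decreasing = TRUE)
  as.integer(lens[which(cumsum(lens) >= sum(lens) / 2)[1]])
}
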