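#' Map mReads onto mContigs in minimizer space
#'
#' mContigs are indexed by their k'-min-mers at k' = kprime_min (so that
#' every contig k'-min-mer is guaranteed to occur in some read). Each mRead
#' is processed twice, forward and reversed, to handle reverse complements;
#' matches are extended maximally while consecutive read windows equal
#' consecutive contig windows, and for every contig window position the
#' match with the longest run is retained (ties: longer read, then smaller
#' read index, then forward orientation).
#'
#' @param mreads an `mread_set`
#' @param mcontigs list of `mcontig`
#' @param kprime_min k' used for seeding (default 4)
#' @return a `best_match_table`: per-contig best matches plus the table of
#'   maximal match runs
#' @export
map_mreads_to_mcontigs <- function(mreads, mcontigs, kprime_min = 4L) {
  stopifnot(length(mcontigs) > 0L)
  seqs <- lapply(mreads, function(r) as.integer(r$minimizers))
  rlen <- vapply(mreads, function(r) r$source_len, numeric(1))
  cseqs <- lapply(mcontigs, function(m) as.integer(m$minimizers))
  circ <- vapply(mcontigs, function(m) isTRUE(m$is_circular), logical(1))
  res <- cpp_map_to_contigs(seqs, as.integer(rlen), cseqs, circ,
                            as.integer(kprime_min))
  structure(list(best = res$best, runs = res$runs,
                 kprime = as.integer(kprime_min),
                 contig_circular = circ),
            class = "best_match_table")
}

# oriented minimizer spans (0-based half-open, coordinates of the oriented
# read string) for an mread
.oriented_spans <- function(mr, ori) {
  n <- length(mr$minimizers)
  if (ori == 0L) {
    list(s = mr$orig_start, e = mr$orig_end)
  } else {
    L <- mr$source_len
    list(s = rev(L - mr$orig_end), e = rev(L - mr$orig_start))
  }
}

# cache of oriented read strings
.oriented_string <- function(cache, read_strings, r, ori) {
  key <- paste0(r, "_", ori)
  val <- cache[[key]]
  if (is.null(val)) {
    val <- if (ori == 0L) read_strings[[r]] else cpp_revcomp(read_strings[[r]])
    cache[[key]] <- val
  }
  val
}

#' Reconstruct nucleotide contigs from mContigs
#'
#' The base span of the first k'-min-mer is taken in full from its
#' best-matching read; every subsequent window appends only the bases
#' between the end of its second-to-last minimizer and the end of its last
#' minimizer (the k'-1 minimizer overlap contributes no new sequence). For
#' circular mContigs every window is treated as "subsequent" cyclically, so
#' the pieces partition the full circle with no duplicated overlap. Spans
#' are cut from the original, uncompressed reads through the
#' homopolymer-run map, and reverse-orientation matches are
#' reverse-complemented before appending.
#'
#' @param mcontigs list of `mcontig`
#' @param bm a `best_match_table` from [map_mreads_to_mcontigs()]
#' @param mreads the `mread_set` used to build `bm`
#' @param read_strings character vector of the original read sequences, in
#'   the same order as `mreads`
#' @return list of `contig` objects
#' @export
reconstruct_sequences <- function(mcontigs, bm, mreads, read_strings) {
  kp <- bm$kprime
  cache <- new.env(parent = emptyenv())
  span_cache <- new.env(parent = emptyenv())
  get_spans <- function(r, ori) {
    key <- paste0(r, "_", ori)
    val <- span_cache[[key]]
    if (is.null(val)) {
      val <- .oriented_spans(mreads[[r]], ori)
      span_cache[[key]] <- val
    }
    val
  }
  out <- vector("list", length(mcontigs))
  for (ci in seq_along(mcontigs)) {
    mc <- mcontigs[[ci]]
    M <- mc$minimizers
    n <- length(M)
    best <- bm$best[[ci]]
    np <- length(best$read)
    if (np == 0L) {
      stop("mContig ", ci, " has fewer than k' minimizers; cannot reconstruct")
    }
    if (anyNA(best$read)) {
      stop("reconstruction impossible: contig ", ci, " position ",
           which(is.na(best$read))[1] - 1L, " has no matching read")
    }
    circ <- isTRUE(mc$is_circular)
    from <- integer(np); to <- integer(np); end_idx <- integer(np)
    for (p in seq_len(np)) {
      r <- best$read[p]; ori <- best$orient[p]; rp <- best$rpos[p]
      sp <- get_spans(r, ori)
      if (!circ && p == 1L) {
        from[p] <- sp$s[rp + 1L] + 1L
        to[p] <- sp$e[rp + kp]
        end_idx[p] <- kp
      } else {
        from[p] <- sp$e[rp + kp - 1L] + 1L
        to[p] <- sp$e[rp + kp]
        end_idx[p] <- if (circ) ((p - 1L + kp - 1L) %% n) + 1L else p + kp - 1L
      }
      if (to[p] < from[p]) {
        stop("inconsistent junction in contig ", ci, " at position ", p - 1L)
      }
    }
    keys <- paste0(best$read, "_", best$orient)
    ukeys <- unique(keys)
    ustr <- vapply(ukeys, function(k) {
      parts <- strsplit(k, "_", fixed = TRUE)[[1]]
      .oriented_string(cache, read_strings, as.integer(parts[1]),
                       as.integer(parts[2]))
    }, character(1))
    pieces <- substring(ustr[match(keys, ukeys)], from, to)
    seq <- paste(pieces, collapse = "")
    cum <- cumsum(nchar(pieces))
    min_end_off <- rep(NA_integer_, n)
    min_end_off[end_idx] <- cum
    out[[ci]] <- structure(
      list(id = sprintf("contig_%d", ci),
           seq = seq,
           length = nchar(seq),
           is_circular = circ,
           coverage = mc$abundance,
           tip_derived = isTRUE(mc$tip_derived),
           min_end_off = min_end_off,
           kprime = kp),
      class = "contig")
  }
  out
}

#' @export
print.contig <- function(x, ...) {
  cat(sprintf("contig %s: %d bp, %s, coverage %g%s\n", x$id, x$length,
              if (x$is_circular) "circular" else "linear", x$coverage,
              if (x$tip_derived) " (tip-derived)" else ""))
  invisible(x)
}

# anchor table of a match run: contig base offsets of minimizer ends paired
# with oriented-read base offsets; circular contig offsets may wrap, in which
# case the run is split into monotone segments
.run_anchors <- function(run, contig, mreads, get_spans, kp) {
  r <- run[["read"]]; ori <- run[["orient"]]
  cpos <- run[["cpos"]]; rpos <- run[["rpos"]]; len <- run[["len"]]
  n <- length(contig$min_end_off)
  sp <- get_spans(r, ori)
  j <- seq_len(min(len, n)) - 1L
  cidx <- if (contig$is_circular) ((cpos + j + kp - 1L) %% n) + 1L
          else cpos + j + kp
  ridx <- rpos + j + kp
  ok <- cidx >= 1L & cidx <= n & ridx <= length(sp$e)
  c_off <- contig$min_end_off[cidx[ok]]
  r_off <- sp$e[ridx[ok]]
  keep <- !is.na(c_off)
  data.frame(c_off = c_off[keep], r_off = r_off[keep], read = r, ori = ori)
}

# linear interpolation/extrapolation of window coordinates through anchors
.project <- function(c_off, r_off, x) {
  nidx <- length(c_off)
  i <- findInterval(x, c_off)
  res <- numeric(length(x))
  lowmask <- i == 0L
  highmask <- i >= nidx
  mid <- !lowmask & !highmask
  res[lowmask] <- r_off[1] + (x[lowmask] - c_off[1])
  res[highmask] <- r_off[nidx] + (x[highmask] - c_off[nidx])
  if (any(mid)) {
    im <- i[mid]
    frac <- (x[mid] - c_off[im]) / pmax(1, c_off[im + 1L] - c_off[im])
    res[mid] <- r_off[im] + frac * (r_off[im + 1L] - r_off[im])
  }
  round(res)
}

#' Polish contigs with a window consensus
#'
#' Reads are uniquely assigned to contigs by the matching score
#' MS = alignLength x alignIdentity (longer alignments are not always the
#' best ones; identity matters with close strains). Each contig is split
#' into non-overlapping windows of `window` nucleotides; up to `max_frags`
#' read fragments are projected onto each window through minimizer anchors,
#' and the window is replaced by the majority consensus of the fragments
#' (ties keep the draft base). Windows with no spanning fragment are left
#' unpolished and flagged in the report.
#'
#' @param contigs list of `contig` from [reconstruct_sequences()]
#' @param bm the `best_match_table` used for reconstruction
#' @param mreads the `mread_set`
#' @param read_strings original read sequences
#' @param window window size in nucleotides (default 500)
#' @param max_frags maximum fragments per window (default 20)
#' @return the polished contigs; a per-contig report is attached as
#'   attribute `report`
#' @export
polish_contigs <- function(contigs, bm, mreads, read_strings, window = 500L,
                           max_frags = 20L) {
  kp <- bm$kprime
  runs <- as.data.frame(bm$runs)
  cache <- new.env(parent = emptyenv())
  span_cache <- new.env(parent = emptyenv())
  get_spans <- function(r, ori) {
    key <- paste0(r, "_", ori)
    val <- span_cache[[key]]
    if (is.null(val)) {
      val <- .oriented_spans(mreads[[r]], ori)
      span_cache[[key]] <- val
    }
    val
  }
  # unique read -> contig assignment by MS
  assign_tab <- .assign_reads(runs, contigs, mreads, read_strings, cache,
                              get_spans, kp)
  report <- data.frame(contig = character(0), n_windows = integer(0),
                       n_unpolished = integer(0), mean_frags = numeric(0))
  for (ci in seq_along(contigs)) {
    ctg <- contigs[[ci]]
    L <- ctg$length
    asg <- assign_tab[runs$read]
    cruns <- runs[runs$contig == ci & !is.na(asg) & asg == ci, , drop = FALSE]
    nw <- ceiling(L / window)
    if (nrow(cruns) == 0L || L < 100L) {
      report <- rbind(report, data.frame(contig = ctg$id, n_windows = nw,
                                         n_unpolished = nw, mean_frags = 0))
      next
    }
    # anchor segments per run; runs crossing a circular origin are
    # unwrapped into one monotone segment and registered at both
    # coordinate representations so origin-spanning windows get fragments
    segs <- list()
    for (ri in seq_len(nrow(cruns))) {
      a <- .run_anchors(as.list(cruns[ri, ]), ctg, mreads, get_spans, kp)
      if (nrow(a) < 2L) next
      wraps <- which(diff(a$c_off) < 0)
      if (length(wraps) == 0L || !ctg$is_circular) {
        brk <- c(0L, wraps, nrow(a))
        for (b in seq_len(length(brk) - 1L)) {
          seg <- a[(brk[b] + 1L):brk[b + 1L], , drop = FALSE]
          if (nrow(seg) >= 2L) {
            seg$prio <- nrow(a)
            segs[[length(segs) + 1L]] <- seg
          }
        }
      } else {
        shift <- c(0, cumsum(diff(a$c_off) < 0)) * L
        a$c_off <- a$c_off + shift
        a$prio <- nrow(a)
        for (off in unique(c(0, -shift))) {
          seg <- a
          seg$c_off <- seg$c_off + off
          segs[[length(segs) + 1L]] <- seg
        }
      }
    }
    if (length(segs) == 0L) {
      report <- rbind(report, data.frame(contig = ctg$id, n_windows = nw,
                                         n_unpolished = nw, mean_frags = 0))
      next
    }
    seg_lo <- vapply(segs, function(s) s$c_off[1], numeric(1))
    seg_hi <- vapply(segs, function(s) s$c_off[nrow(s)], numeric(1))
    seg_prio <- vapply(segs, function(s) s$prio[1], numeric(1))
    seg_read <- vapply(segs, function(s) s$read[1], numeric(1))
    pieces <- character(nw)
    n_unpol <- 0L
    tot_frags <- 0L
    flank <- 10L
    for (w in seq_len(nw)) {
      w0 <- (w - 1L) * window
      w1 <- min(L, w0 + window)
      # short flanks keep junction-adjacent variants inside the alignment;
      # the consensus is trimmed back to [w0, w1)
      ext_lo <- min(flank, w0)
      ext_hi <- min(flank, L - w1)
      cand <- which(seg_lo <= w0 + 800 & seg_hi >= w1 - 800)
      cand <- cand[order(-seg_prio[cand], seg_read[cand])]
      frags <- character(0)
      for (si in cand) {
        if (length(frags) >= max_frags) break
        s <- segs[[si]]
        pr <- .project(s$c_off, s$r_off,
                       c(w0 - ext_lo - 10, w1 + ext_hi + 10))
        rlen <- mreads[[s$read[1]]]$source_len
        if (pr[1] < 0 || pr[2] > rlen ||
            pr[2] - pr[1] < (w1 - w0 + ext_lo + ext_hi)) next
        str <- .oriented_string(cache, read_strings, s$read[1], s$ori[1])
        frags <- c(frags, substr(str, pr[1] + 1L, pr[2]))
      }
      win_seq <- substr(ctg$seq, w0 - ext_lo + 1L, w1 + ext_hi)
      if (length(frags) == 0L) {
        pieces[w] <- substr(ctg$seq, w0 + 1L, w1)
        n_unpol <- n_unpol + 1L
      } else {
        pieces[w] <- cpp_window_consensus(win_seq, frags, 40L,
                                          ext_lo, ext_hi)
        tot_frags <- tot_frags + length(frags)
      }
    }
    newseq <- paste(pieces, collapse = "")
    contigs[[ci]]$seq <- newseq
    contigs[[ci]]$length <- nchar(newseq)
    contigs[[ci]]$min_end_off <- NULL # offsets invalidated by polishing
    report <- rbind(report, data.frame(contig = ctg$id, n_windows = nw,
                                       n_unpolished = n_unpol,
                                       mean_frags = tot_frags / max(1, nw)))
  }
  attr(contigs, "report") <- report
  contigs
}

# read -> contig assignment maximizing MS = alignLength * alignIdentity
.assign_reads <- function(runs, contigs, mreads, read_strings, cache,
                          get_spans, kp) {
  n_reads <- length(mreads)
  assign_tab <- rep(NA_integer_, n_reads)
  if (nrow(runs) == 0L) return(assign_tab)
  agg <- aggregate(len ~ read + contig, data = runs, FUN = sum)
  for (r in unique(agg$read)) {
    sub <- agg[agg$read == r, , drop = FALSE]
    sub <- sub[order(-sub$len, sub$contig), , drop = FALSE]
    if (nrow(sub) == 1L || sub$len[1] >= 2 * sub$len[2]) {
      # minimizer-space evidence is decisive; base-level MS would agree
      assign_tab[r] <- sub$contig[1]
      next
    }
    cand <- head(sub$contig[sub$len >= 0.3 * sub$len[1]], 4)
    best_ms <- -1
    best_c <- cand[1]
    for (ci in cand) {
      rr <- runs[runs$read == r & runs$contig == ci, , drop = FALSE]
      rr <- rr[which.max(rr$len), , drop = FALSE]
      ms <- .run_ms(as.list(rr[1, ]), contigs[[ci]], mreads, read_strings,
                    cache, get_spans, kp)
      if (ms > best_ms) { best_ms <- ms; best_c <- ci }
    }
    assign_tab[r] <- best_c
  }
  assign_tab
}

# matching score of a run: banded fit alignment of the read against the
# anchored contig region (with overhang margins). For efficiency the scored
# alignment window is capped at `cap` read bases centred on the match; the
# cap is identical across the candidate contigs of a read, so the
# comparison of MS = alignLength x alignIdentity is unaffected for matches
# longer than the cap.
.run_ms <- function(run, contig, mreads, read_strings, cache, get_spans, kp,
                    cap = 2400L) {
  a <- .run_anchors(run, contig, mreads, get_spans, kp)
  if (nrow(a) < 1L) return(0)
  r <- run[["read"]]; ori <- run[["orient"]]
  rlen <- mreads[[r]]$source_len
  left_over <- a$r_off[1]
  right_over <- rlen - a$r_off[nrow(a)]
  r_lo <- max(0L, a$r_off[1] - left_over)
  r_hi <- min(rlen, a$r_off[nrow(a)] + right_over)
  mid_i <- (nrow(a) + 1L) %/% 2L
  r_lo <- max(r_lo, a$r_off[mid_i] - cap %/% 2L)
  r_hi <- min(r_hi, a$r_off[mid_i] + cap %/% 2L)
  c_mid <- a$c_off[mid_i]
  lo <- max(0L, c_mid - (a$r_off[mid_i] - r_lo) - 150L)
  hi <- min(contig$length, c_mid + (r_hi - a$r_off[mid_i]) + 150L)
  if (hi - lo < 50L || r_hi - r_lo < 50L) return(0)
  str <- .oriented_string(cache, read_strings, r, ori)
  al <- cpp_banded_align(substr(str, r_lo + 1L, r_hi),
                         substr(contig$seq, lo + 1L, hi), 64L, TRUE)
  if (!isTRUE(al$ok)) return(0)
  al$align_len * al$identity
}

#' Purge strain duplications
#'
#' Contigs of at least `template_min_len` are immutable templates. Shorter
#' contigs are mapped onto the templates in minimizer space; regions whose
#' nucleotide alignment identity against a template exceeds `min_identity`
#' are removed. Tip-derived contigs (retained earlier as potential rare
#' species) are dropped entirely when more than half of their length
#' duplicates another contig at high identity. Remaining fragments shorter
#' than `min_keep` are discarded.
#'
#' @param contigs list of `contig`
#' @param scheme the [minimizer_scheme()] used by the assembly
#' @param template_min_len template length threshold (default 1 Mb)
#' @param min_identity identity threshold (default 0.99)
#' @param kprime_min k' for seeding (default 4)
#' @param min_keep minimum length of surviving fragments (default 1000)
#' @return the purged contigs, with a `report` attribute (one row per
#'   removed region)
#' @export
purge_duplicates <- function(contigs, scheme, template_min_len = 1e6,
                             min_identity = 0.99, kprime_min = 4L,
                             min_keep = 1000L) {
  report <- data.frame(contig = character(0), start = integer(0),
                       end = integer(0), template = character(0),
                       identity = numeric(0), action = character(0))
  lens <- vapply(contigs, function(x) x$length, numeric(1))
  tmpl <- which(lens >= template_min_len)
  qry <- which(lens < template_min_len)
  if (length(tmpl) == 0L || length(qry) == 0L) {
    attr(contigs, "purge_report") <- report
    return(contigs)
  }
  tm_seqs <- lapply(contigs[tmpl], function(x) x$seq)
  q_seqs <- lapply(contigs[qry], function(x) x$seq)
  tm_mr <- extract_mreads(setNames(unlist(tm_seqs),
                                   paste0("t", seq_along(tmpl))), scheme)
  q_mr <- extract_mreads(setNames(unlist(q_seqs),
                                  paste0("q", seq_along(qry))), scheme)
  tm_lists <- lapply(seq_along(tmpl), function(i) {
    structure(list(minimizers = tm_mr[[i]]$minimizers,
                   is_circular = contigs[[tmpl[i]]]$is_circular),
              class = "mcontig")
  })
  res <- cpp_map_to_contigs(lapply(q_mr, function(r) as.integer(r$minimizers)),
                            as.integer(vapply(q_mr, function(r) r$source_len,
                                              numeric(1))),
                            lapply(tm_lists, function(x)
                              as.integer(x$minimizers)),
                            vapply(tm_lists, function(x)
                              isTRUE(x$is_circular), logical(1)),
                            as.integer(kprime_min))
  runs <- as.data.frame(res$runs)
  keep_flags <- rep(TRUE, length(contigs))
  removal <- vector("list", length(contigs))
  for (qi in seq_along(qry)) {
    q_idx <- qry[qi]
    rr_all <- runs[runs$read == qi, , drop = FALSE]
    if (nrow(rr_all) == 0L) next
    for (ti in unique(rr_all$contig)) {
      rr <- rr_all[rr_all$contig == ti, , drop = FALSE]
      tm_ctg <- contigs[[tmpl[ti]]]
      blocks <- .contig_ref_blocks(qi, ti, rr, q_mr[[qi]], tm_mr[[ti]],
                                   contigs[[q_idx]]$seq, tm_ctg$seq,
                                   isTRUE(tm_ctg$is_circular), kprime_min)
      if (is.null(blocks) || nrow(blocks) == 0L) next
      for (bi in seq_len(nrow(blocks))) {
        b <- blocks[bi, ]
        if (b$q_hi - b$q_lo < 500) next
        if (b$identity > min_identity) {
          removal[[q_idx]] <- rbind(removal[[q_idx]], c(b$q_lo, b$q_hi))
          report <- rbind(report, data.frame(
            contig = contigs[[q_idx]]$id, start = b$q_lo, end = b$q_hi,
            template = tm_ctg$id, identity = b$identity,
            action = "remove"))
        }
      }
    }
  }
  out <- list()
  for (i in seq_along(contigs)) {
    if (!keep_flags[i]) next
    rem <- removal[[i]]
    if (is.null(rem)) {
      out[[length(out) + 1L]] <- contigs[[i]]
      next
    }
    rem <- .merge_intervals(rem, gap = 0)
    covered <- sum(rem[, 2] - rem[, 1])
    L <- contigs[[i]]$length
    if (contigs[[i]]$tip_derived && covered >= 0.5 * L) {
      report <- rbind(report, data.frame(
        contig = contigs[[i]]$id, start = 0L, end = L,
        template = NA_character_, identity = NA_real_,
        action = "drop_tip"))
      next
    }
    # splice out removed regions; keep fragments >= min_keep
    keep_iv <- .complement_intervals(rem, L)
    frag <- 0L
    for (k in seq_len(nrow(keep_iv))) {
      a <- keep_iv[k, 1]; b <- keep_iv[k, 2]
      if (b - a < min_keep) next
      frag <- frag + 1L
      ctg <- contigs[[i]]
      ctg$seq <- substr(ctg$seq, a + 1L, b)
      ctg$length <- b - a
      ctg$is_circular <- FALSE
      ctg$id <- if (nrow(keep_iv) > 1L) paste0(ctg$id, ".", frag) else ctg$id
      ctg$min_end_off <- NULL
      out[[length(out) + 1L]] <- ctg
    }
  }
  attr(out, "purge_report") <- report
  out
}

.merge_intervals <- function(iv, gap = 0) {
  if (is.null(iv) || nrow(iv) == 0L) return(matrix(numeric(0), ncol = 2))
  iv <- iv[order(iv[, 1]), , drop = FALSE]
  out <- iv[1, , drop = FALSE]
  for (i in seq_len(nrow(iv))[-1]) {
    if (iv[i, 1] <= out[nrow(out), 2] + gap) {
      out[nrow(out), 2] <- max(out[nrow(out), 2], iv[i, 2])
    } else {
      out <- rbind(out, iv[i, ])
    }
  }
  out
}

.complement_intervals <- function(iv, L) {
  if (nrow(iv) == 0L) return(matrix(c(0, L), ncol = 2))
  out <- matrix(numeric(0), ncol = 2)
  prev <- 0
  for (i in seq_len(nrow(iv))) {
    if (iv[i, 1] > prev) out <- rbind(out, c(prev, iv[i, 1]))
    prev <- max(prev, iv[i, 2])
  }
  if (prev < L) out <- rbind(out, c(prev, L))
  out
}
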