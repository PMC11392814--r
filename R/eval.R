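#' Greedy assignment of contig alignments to references
#'
#' Alignments (one row per aligned block: `contig`, `ref`, `ms`,
#' `identity`, `r_start`, `r_end`; `r_end` may exceed the reference length
#' for blocks wrapping a circular origin) are filtered at `min_identity`,
#' ordered by decreasing matching score MS = alignLength x alignIdentity,
#' and processed sequentially. A contig is assigned to at most one
#' reference; no contig is assigned to a reference that is already complete
#' (>= `complete_threshold` of its positions covered), and a block is
#' skipped when more than `max_overlap` of its positions are already
#' covered by previously assigned contigs. References ending below
#' `missed_threshold` completeness are reported as missed.
#'
#' @param blocks data.frame of alignment blocks (0-based half-open
#'   reference coordinates)
#' @param ref_lens named vector of reference lengths
#' @param min_identity alignment identity filter (default 0.99)
#' @param max_overlap maximum tolerated pre-covered fraction (default 0.30)
#' @param complete_threshold completeness to call a reference complete
#'   (default 0.99)
#' @param missed_threshold completeness below which a reference is missed
#'   (default 0.70)
#' @return list with `report` (per reference) and `assignments` (accepted
#'   blocks)
#' @export
assign_alignments <- function(blocks, ref_lens, min_identity = 0.99,
                              max_overlap = 0.30,
                              complete_threshold = 0.99,
                              missed_threshold = 0.70) {
  refs <- names(ref_lens)
  covered <- lapply(ref_lens, function(L) logical(L))
  complete <- setNames(rep(FALSE, length(refs)), refs)
  contig_ref <- character(0)
  accepted <- blocks[0, , drop = FALSE]
  if (nrow(blocks)) {
    blocks <- blocks[blocks$identity >= min_identity, , drop = FALSE]
    blocks <- blocks[order(-blocks$ms), , drop = FALSE]
    for (i in seq_len(nrow(blocks))) {
      b <- blocks[i, ]
      L <- ref_lens[[b$ref]]
      prev <- contig_ref[b$contig]
      if (!is.na(prev) && length(prev) && prev != b$ref) next
      if (complete[[b$ref]]) next
      pos <- (seq.int(b$r_start, b$r_end - 1L) %% L) + 1L
      pos <- unique(pos)
      if (mean(covered[[b$ref]][pos]) > max_overlap) next
      covered[[b$ref]][pos] <- TRUE
      contig_ref[b$contig] <- b$ref
      accepted <- rbind(accepted, b)
      if (mean(covered[[b$ref]]) >= complete_threshold) {
        complete[[b$ref]] <- TRUE
      }
    }
  }
  compl <- vapply(refs, function(r) mean(covered[[r]]), numeric(1))
  status <- ifelse(compl >= complete_threshold, "complete",
                   ifelse(compl < missed_threshold, "missed", "partial"))
  list(report = data.frame(ref = refs, length = as.numeric(ref_lens),
                           completeness = compl, status = status,
                           row.names = NULL),
       assignments = accepted)
}

# chain match-run segments between one contig and one reference into
# alignment blocks and compute banded identity for each. All chaining is
# done in oriented-query space (the orientation in which the minimizer-space
# match ran forward), so the reference coordinate always increases along a
# segment; reverse-orientation blocks are aligned as the reverse complement
# of the query.
.contig_ref_blocks <- function(qi, ti, rr, q_mr, t_mr, q_seq, t_seq,
                               t_circ, kp) {
  L <- nchar(t_seq)
  Lq <- q_mr$source_len
  n_t <- length(t_mr$minimizers)
  nmin <- length(q_mr$minimizers)
  segs <- NULL
  for (k in seq_len(nrow(rr))) {
    ori <- rr$orient[k]
    sp <- .oriented_spans(q_mr, ori)
    span <- min(rr$len[k], n_t)
    j <- seq_len(span) - 1L
    ridx <- rr$rpos[k] + j + kp        # oriented q minimizer index (1-based)
    keep <- ridx <= nmin
    j <- j[keep]; ridx <- ridx[keep]
    if (length(j) == 0L) next
    tw <- (rr$cpos[k] + j + kp - 1L) %% n_t + 1L # t-side anchor minimizer
    tw_first <- (rr$cpos[k] + j) %% n_t + 1L    # first minimizer of window
    q_off <- sp$e[ridx]
    t_off <- t_mr$orig_end[tw]
    # split at reference wrap points (anchor offset drops)
    brk <- c(0L, which(diff(t_off) < 0), length(t_off))
    for (b in seq_len(length(brk) - 1L)) {
      sel <- (brk[b] + 1L):brk[b + 1L]
      segs <- rbind(segs, data.frame(
        ori = ori,
        q_lo = if (b == 1L) sp$s[rr$rpos[k] + 1L] else q_off[sel[1]] - 1L,
        q_hi = q_off[sel[length(sel)]],
        t_lo = min(t_mr$orig_start[tw_first[sel[1]]], t_off[sel[1]]),
        t_hi = t_off[sel[length(sel)]]))
    }
  }
  if (is.null(segs)) return(NULL)
  out <- NULL
  for (ori in unique(segs$ori)) {
    ss <- segs[segs$ori == ori, , drop = FALSE]
    ss <- ss[order(ss$q_lo), , drop = FALSE]
    grp <- cumsum(c(TRUE, ss$q_lo[-1] > head(cummax(ss$q_hi), -1) + 6000))
    for (g in unique(grp)) {
      gg <- ss[grp == g, , drop = FALSE]
      q_lo <- min(gg$q_lo); q_hi <- max(gg$q_hi)
      if (q_hi - q_lo < 200) next
      # pull the unanchored contig margins (before the first / after the
      # last minimizer) into the alignment so coverage reflects full contigs
      q_lo <- q_lo - min(q_lo, 3000L)
      q_hi <- q_hi + min(Lq - q_hi, 3000L)
      # unwrap reference coordinates along the chain
      t_lo_u <- gg$t_lo[1]; t_hi_u <- gg$t_hi[1]
      if (nrow(gg) > 1L) {
        shift <- 0
        prev_hi <- gg$t_hi[1]
        for (i in 2:nrow(gg)) {
          lo_i <- gg$t_lo[i] + shift
          if (t_circ && lo_i < prev_hi - L / 2) {
            shift <- shift + L
            lo_i <- lo_i + L
          }
          hi_i <- gg$t_hi[i] + shift
          t_lo_u <- min(t_lo_u, lo_i)
          t_hi_u <- max(t_hi_u, hi_i)
          prev_hi <- max(prev_hi, hi_i)
        }
      }
      margin <- max(300, 300 + (q_hi - q_lo) - (t_hi_u - t_lo_u))
      tsrc <- if (t_circ) paste0(t_seq, t_seq) else t_seq
      t0 <- t_lo_u - margin
      t1 <- t_hi_u + margin
      if (t_circ && t0 < 0) {
        # the window reaches across the origin: shift into the doubled copy
        t0 <- t0 + L
        t1 <- t1 + L
      }
      t0 <- max(0, t0)
      t1 <- min(nchar(tsrc), t1)
      qs <- substr(q_seq, q_lo + 1L, q_hi)
      if (ori == 1L) {
        qs <- cpp_revcomp(substr(q_seq, Lq - q_hi + 1L, Lq - q_lo))
      }
      ts <- substr(tsrc, t0 + 1L, t1)
      al <- cpp_banded_align(qs, ts, 150L, TRUE)
      if (!isTRUE(al$ok)) next
      out <- rbind(out, data.frame(
        q_lo = if (ori == 0L) q_lo else Lq - q_hi,
        q_hi = if (ori == 0L) q_hi else Lq - q_lo, ori = ori,
        r_start = (t0 + al$b_start) %% L,
        r_end = (t0 + al$b_start) %% L + (al$b_end - al$b_start),
        identity = al$identity, matches = al$matches,
        align_len = al$align_len, ms = al$align_len * al$identity))
    }
  }
  out
}

#' Evaluate an assembly against reference genomes
#'
#' Contigs are aligned to the references with the package's minimizer-space
#' mapper plus banded base-level alignment, alignments below `min_identity`
#' are filtered out, and contigs are uniquely assigned to references
#' greedily by matching score (see [assign_alignments()]). A reference is
#' complete when at least `complete_threshold` of its positions are covered
#' by assigned contigs and missed when below `missed_threshold`.
#'
#' @param contigs list of `contig` objects or a named character vector
#' @param references named character vector (or DNAStringSet) of reference
#'   genomes
#' @param ref_circular logical, recycled over references
#' @param scheme the [minimizer_scheme()] (must match the assembly's)
#' @param kprime_min seeding k' (default 4)
#' @param min_identity,max_overlap,complete_threshold,missed_threshold
#'   thresholds, see [assign_alignments()]
#' @return list with `report`, `assignments`, and `identity` (overall
#'   identity over assigned blocks, total matches / total columns)
#' @export
evaluate_assembly <- function(contigs, references, ref_circular = TRUE,
                              scheme = minimizer_scheme(), kprime_min = 4L,
                              min_identity = 0.99, max_overlap = 0.30,
                              complete_threshold = 0.99,
                              missed_threshold = 0.70) {
  if (inherits(references, "XStringSet")) {
    nm <- names(references)
    references <- as.character(references)
    names(references) <- nm
  }
  if (is.list(contigs) && length(contigs) && inherits(contigs[[1]], "contig")) {
    cs <- vapply(contigs, function(x) x$seq, character(1))
    names(cs) <- vapply(contigs, function(x) x$id, character(1))
    contigs <- cs
  }
  ref_circular <- rep_len(ref_circular, length(references))
  ref_lens <- setNames(nchar(references), names(references))
  empty <- list(report = data.frame(ref = names(references),
                                    length = as.numeric(ref_lens),
                                    completeness = 0,
                                    status = "missed", row.names = NULL),
                assignments = NULL, identity = NA_real_)
  if (length(contigs) == 0L) return(empty)
  q_mr <- extract_mreads(contigs, scheme)
  t_mr <- extract_mreads(references, scheme)
  res <- cpp_map_to_contigs(
    lapply(q_mr, function(r) as.integer(r$minimizers)),
    as.integer(vapply(q_mr, function(r) r$source_len, numeric(1))),
    lapply(t_mr, function(r) as.integer(r$minimizers)),
    ref_circular, as.integer(kprime_min))
  runs <- as.data.frame(res$runs)
  if (nrow(runs) == 0L) return(empty)
  blocks <- NULL
  for (qi in unique(runs$read)) {
    for (ti in unique(runs$contig[runs$read == qi])) {
      rr <- runs[runs$read == qi & runs$contig == ti, , drop = FALSE]
      bl <- .contig_ref_blocks(qi, ti, rr, q_mr[[qi]], t_mr[[ti]],
                               contigs[[qi]], references[[ti]],
                               ref_circular[ti], kprime_min)
      if (!is.null(bl) && nrow(bl)) {
        bl$contig <- names(contigs)[qi]
        bl$ref <- names(references)[ti]
        blocks <- rbind(blocks, bl)
      }
    }
  }
  if (is.null(blocks) || nrow(blocks) == 0L) return(empty)
  res2 <- assign_alignments(blocks, ref_lens, min_identity, max_overlap,
                            complete_threshold, missed_threshold)
  acc <- res2$assignments
  overall <- if (!is.null(acc) && nrow(acc)) {
    sum(acc$matches) / sum(acc$align_len)
  } else NA_real_
  list(report = res2$report, assignments = acc, identity = overall)
}
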