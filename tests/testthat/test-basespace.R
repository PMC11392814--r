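# substitution-only mutation helper for purge fixtures
.mutate_for_test <- function(seq, rate) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  n_edit <- max(1L, rbinom(1, length(v), rate))
  pos <- sample.int(length(v), n_edit)
  for (p in pos) v[p] <- sample(setdiff(c("A", "C", "G", "T"), v[p]), 1)
  paste(v, collapse = "")
}

# build a tiny error-free community in base space for mapping tests
mini_world <- function(glen = 12000, read_len = 2500, step = 600, seed = 55) {
  g <- random_dna(glen, seed = seed)
  gg <- paste0(g, g)
  starts <- seq(1, glen, by = step)
  reads <- vapply(starts, function(s) substr(gg, s, s + read_len - 1),
                  character(1))
  names(reads) <- paste0("r", seq_along(reads))
  scheme <- minimizer_scheme()
  list(genome = g, reads = reads, scheme = scheme,
       mreads = extract_mreads(reads, scheme))
}

test_that("minimizer-space mapping finds exact and reverse matches", {
  w <- mini_world()
  # an mContig equal to one read's minimizer list maps at full length
  mr1 <- w$mreads[[3]]
  mc <- structure(list(minimizers = mr1$minimizers, abundance = 1,
                       is_circular = FALSE, tip_derived = FALSE),
                  class = "mcontig")
  bm <- map_mreads_to_mcontigs(w$mreads, list(mc), 4L)
  best <- bm$best[[1]]
  expect_false(anyNA(best$read))
  nw <- length(mr1$minimizers) - 3L
  expect_true(all(best$m >= nw - 1)) # full-length runs everywhere

  # reverse-complement reads are found on the reversed pass
  rc_reads <- vapply(w$reads, revcomp, character(1))
  names(rc_reads) <- names(w$reads)
  rc_mr <- extract_mreads(rc_reads, w$scheme)
  bm2 <- map_mreads_to_mcontigs(rc_mr, list(mc), 4L)
  expect_false(anyNA(bm2$best[[1]]$read))
  expect_true(all(bm2$best[[1]]$orient == 1L))

  # the longer of two overlapping matches wins
  short_mr <- extract_mread("s", substr(w$genome, 1200, 2600), w$scheme)
  sub <- c(w$mreads, list(short = short_mr))
  class(sub) <- "mread_set"
  mc_all <- structure(list(minimizers = extract_mread("g", w$genome,
                                                      w$scheme)$minimizers,
                           abundance = 1, is_circular = FALSE,
                           tip_derived = FALSE), class = "mcontig")
  bm3 <- map_mreads_to_mcontigs(sub, list(mc_all), 4L)
  covered <- which(!is.na(bm3$best[[1]]$read))
  m_short <- length(short_mr$minimizers) - 3L
  # wherever a long read covers, its m exceeds the short read's best
  expect_true(all(bm3$best[[1]]$m[covered] >= m_short | is.na(bm3$best[[1]]$m[covered])))
})

test_that("reconstruction reproduces the source sequence exactly", {
  w <- mini_world()
  run <- run_assembly(w$reads, polish = FALSE, purge = FALSE)
  expect_gte(length(run$contigs), 1)
  for (ctg in run$contigs) {
    expect_true(is_exact_copy(ctg$seq, w$genome, TRUE))
  }
  # circular contig recovers the full genome length
  circ <- Filter(function(c) c$is_circular, run$contigs)
  expect_length(circ, 1)
  expect_equal(circ[[1]]$length, nchar(w$genome))

  # the same genome sampled only on the reverse strand reconstructs too
  rc_reads <- vapply(w$reads, revcomp, character(1))
  names(rc_reads) <- names(w$reads)
  run2 <- run_assembly(rc_reads, polish = FALSE, purge = FALSE)
  circ2 <- Filter(function(c) c$is_circular, run2$contigs)
  expect_length(circ2, 1)
  expect_true(is_exact_copy(circ2[[1]]$seq, w$genome, TRUE))
})

test_that("reconstruction from a single spanning mRead equals its substring", {
  w <- mini_world()
  r5 <- w$reads[[5]]
  mr <- extract_mreads(setNames(r5, "r5"), w$scheme)
  mc <- structure(list(minimizers = mr[[1]]$minimizers, abundance = 1,
                       is_circular = FALSE, tip_derived = FALSE),
                  class = "mcontig")
  bm <- map_mreads_to_mcontigs(mr, list(mc), 4L)
  ctg <- reconstruct_sequences(list(mc), bm, mr, unname(r5))
  sp <- mr[[1]]
  expected <- substr(r5, sp$orig_start[1] + 1,
                     sp$orig_end[length(sp$orig_end)])
  expect_equal(ctg[[1]]$seq, expected)
})

test_that("polishing corrects induced errors and flags empty windows", {
  w <- mini_world(glen = 10000, read_len = 2500, step = 400, seed = 66)
  run <- run_assembly(w$reads, polish = FALSE, purge = FALSE)
  circ <- which(vapply(run$contigs, function(c) c$is_circular, logical(1)))
  expect_length(circ, 1)
  ctg <- run$contigs[[circ]]
  # inject substitutions mid-contig (away from the window boundaries)
  seq0 <- ctg$seq
  pos <- c(750, 1234, 2600)
  broken <- seq0
  for (p in pos) {
    old <- substr(broken, p, p)
    new <- setdiff(c("A", "C", "G", "T"), old)[1]
    substr(broken, p, p) <- new
  }
  ctg_broken <- ctg
  ctg_broken$seq <- broken
  usable <- Filter(function(m) length(m$minimizers) >= 4,
                   run$assembly$mcontigs)
  bm <- map_mreads_to_mcontigs(run$assembly$mreads, usable, 4L)
  polished <- polish_contigs(
    replace(run$contigs, circ, list(ctg_broken)), bm,
    run$assembly$mreads, unname(w$reads))
  expect_equal(polished[[circ]]$seq, seq0)
  rep <- attr(polished, "report")
  # nearly every window is consensus-corrected; a sparse minimizer desert
  # may leave the odd window without a spanning fragment (flagged, kept)
  expect_lte(rep$n_unpolished[rep$contig == ctg$id], 2)

  # a contig with no mapped reads is left unpolished and flagged
  alien <- structure(list(id = "alien", seq = random_dna(1200, seed = 9),
                          length = 1200L, is_circular = FALSE, coverage = 1,
                          tip_derived = FALSE,
                          min_end_off = rep(NA_integer_, 5), kprime = 4L),
                     class = "contig")
  polished2 <- polish_contigs(c(run$contigs, list(alien)), bm,
                              run$assembly$mreads, unname(w$reads))
  rep2 <- attr(polished2, "report")
  expect_equal(rep2$n_unpolished[rep2$contig == "alien"],
               rep2$n_windows[rep2$contig == "alien"])
})

test_that("purging removes high-identity duplicates and respects thresholds", {
  set.seed(123)
  tmpl_seq <- random_dna(60000)
  # near-identical duplicate (0.2% divergence) and a diverged one (5%)
  near <- .mutate_for_test(substr(tmpl_seq, 10001, 30000), 0.002)
  far <- .mutate_for_test(substr(tmpl_seq, 30001, 50000), 0.05)
  mk <- function(id, seq, tip = FALSE) {
    structure(list(id = id, seq = seq, length = nchar(seq),
                   is_circular = FALSE, coverage = 10, tip_derived = tip,
                   min_end_off = NULL, kprime = 4L), class = "contig")
  }
  tmpl <- mk("big", tmpl_seq)
  contigs <- list(tmpl, mk("near", near), mk("far", far))
  out <- purge_duplicates(contigs, minimizer_scheme(),
                          template_min_len = 50000, min_identity = 0.99)
  ids <- vapply(out, function(c) c$id, character(1))
  expect_true("big" %in% ids)
  expect_false(any(startsWith(ids, "near")))
  expect_true(any(startsWith(ids, "far")))

  # two templates are never touched ("longer than the floor are left alone")
  tmpl2 <- mk("big2", tmpl_seq)
  out2 <- purge_duplicates(list(tmpl, tmpl2), minimizer_scheme(),
                           template_min_len = 50000)
  expect_length(out2, 2)

  # tip-derived duplicates are dropped entirely
  out3 <- purge_duplicates(list(tmpl, mk("tipdup", near, tip = TRUE)),
                           minimizer_scheme(), template_min_len = 50000)
  expect_length(out3, 1)
  expect_equal(out3[[1]]$id, "big")
})
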