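test_that("counting slides windows and matches brute force", {
  # one mRead of 5 minimizers, k'=4 -> 2 windows
  tab <- count_kminmers(list(as.integer(c(1, 2, 3, 4, 5))), 4L)
  expect_length(tab$keys, 2)
  expect_equal(tab$abundance, c(1L, 1L))

  # same read twice -> every abundance doubled
  tab2 <- count_kminmers(list(as.integer(1:5), as.integer(1:5)), 4L)
  expect_equal(tab2$abundance, tab$abundance * 2L)

  # reads tiling a cyclic genome: counts equal brute-force enumeration
  set.seed(13)
  cyc <- sample.int(500, 60)
  reads <- tile_cycle(cyc, 12L, 3L)
  tab3 <- count_kminmers(reads, 4L)
  oracle <- o_count_kminmers(reads, rep(FALSE, length(reads)), 4L)
  expect_equal(setNames(tab3$abundance, tab3$keys), oracle)

  # circular sequences wrap
  tabc <- count_kminmers(list(structure(as.integer(1:6), circular = TRUE)), 4L)
  expect_length(tabc$keys, 6)
})

test_that("initial filter discards only abundance-1 k'-min-mers in deep reads", {
  # base read seen 15x; one read adds a unique window -> R_cov = 15,
  # R_min = 1.5 > 1, its abundance-1 windows are discarded
  base <- as.integer(1:10)
  deep <- c(rep(list(base), 15), list(as.integer(c(1:10, 99))))
  tab <- count_kminmers(deep, 4L)
  unique_key <- paste(minidbg:::cpp_canonicalize_kminmer(
    as.integer(c(8, 9, 10, 99)))$mins, collapse = ",")
  expect_true(unique_key %in% tab$keys)
  filt <- initial_filter(deep, tab, beta_err = 0.1)
  expect_false(unique_key %in% filt$keys)

  # same layout at 8x: R_cov = 8, R_min = 0.8 < 1 -> kept
  shallow <- c(rep(list(base), 8), list(as.integer(c(1:10, 99))))
  tab2 <- count_kminmers(shallow, 4L)
  filt2 <- initial_filter(shallow, tab2, beta_err = 0.1)
  expect_true(unique_key %in% filt2$keys)

  # abundance 2 is never removed, however deep the read
  two <- c(rep(list(base), 100),
           list(as.integer(c(1:10, 99))), list(as.integer(c(1:10, 99))))
  tab3 <- count_kminmers(two, 4L)
  filt3 <- initial_filter(two, tab3, beta_err = 0.1)
  expect_true(unique_key %in% filt3$keys)
  expect_true(all(filt3$abundance >= 1))
})

test_that("smoothing sets constituents to the median; rescue needs length", {
  # craft a table directly from one linear mContig's windows
  mc_seq <- as.integer(1:9) # 6 windows at k'=4
  tab <- count_kminmers(list(mc_seq), 4L)
  # impose abundances [4,4,1,4,4,4] in key order of appearance
  keys_in_order <- minidbg:::cpp_window_keys(mc_seq, FALSE, 4L)
  tab$abundance <- ifelse(tab$keys == keys_in_order[3], 1L, 4L)
  mc <- structure(list(minimizers = mc_seq, is_circular = FALSE,
                       abundance = 4),
                  class = "mcontig")
  sm <- smooth_and_rescue(list(mc), tab)
  expect_true(sm$refined)
  # short mContig (6 windows <= 2k' = 8): all smoothed to median 4, no rescue
  expect_equal(unique(sm$abundance), 4L)

  # all-abundance-1 long mContig: smoothing keeps 1, rescue bumps to 2
  long_seq <- as.integer(1:13) # 10 windows > 2k' = 8
  tab2 <- count_kminmers(list(long_seq), 4L)
  mc2 <- structure(list(minimizers = long_seq, is_circular = FALSE,
                        abundance = 1),
                   class = "mcontig")
  sm2 <- smooth_and_rescue(list(mc2), tab2)
  expect_equal(unique(sm2$abundance), 2L)

  # same but short: stays 1
  short_seq <- as.integer(1:8)
  tab3 <- count_kminmers(list(short_seq), 4L)
  mc3 <- structure(list(minimizers = short_seq, is_circular = FALSE,
                        abundance = 1),
                   class = "mcontig")
  sm3 <- smooth_and_rescue(list(mc3), tab3)
  expect_equal(unique(sm3$abundance), 1L)
})

test_that("propagation takes the parent minimum and discards singletons", {
  # seqs at k'=3 with controlled abundances, then propagate to k'=4
  s <- as.integer(1:6)
  prev <- count_kminmers(rep(list(s), 5), 3L) # all parents abundance 5
  # lower one parent to 3, another to 1
  k_lo <- minidbg:::cpp_window_keys(s, FALSE, 3L)
  prev$abundance[prev$keys == k_lo[2]] <- 3L
  prev$abundance[prev$keys == k_lo[4]] <- 1L
  prev$refined <- TRUE
  tab <- propagate_abundance(list(s), prev, 4L)
  w4 <- minidbg:::cpp_window_keys(s, FALSE, 4L)
  ab <- setNames(tab$abundance, tab$keys)
  # window 1 has parents (w3[1], w3[2]) with abundances 5, 3 -> 3
  expect_equal(unname(ab[w4[1]]), 3L)
  # window 3 contains parent abundance 1 -> dropped
  expect_false(w4[3] %in% names(ab))
  # windows with both parents at 5 -> 5, never above either parent
  expect_true(all(vapply(seq_along(w4), function(i) {
    if (!w4[i] %in% names(ab)) return(TRUE)
    p1 <- prev$abundance[prev$keys == k_lo[i]]
    p2 <- prev$abundance[prev$keys == k_lo[i + 1]]
    ab[[w4[i]]] <= min(p1, p2)
  }, logical(1))))
  # a k'-min-mer with a missing parent is dropped
  tab2 <- propagate_abundance(list(as.integer(c(50, 51, 52, 53))), prev, 4L)
  expect_length(tab2$keys, 0)
})

test_that("no genomic k'-min-mer is filtered on error-free single-genome reads", {
  set.seed(77)
  cyc <- sample.int(5000, 80)
  reads <- tile_cycle(cyc, 20L, 4L) # every window covered >= 2x
  tab <- count_kminmers(reads, 4L)
  expect_true(all(tab$abundance >= 2))
  filt <- initial_filter(reads, tab, 0.1)
  expect_equal(filt$keys, tab$keys)
  prev <- filt
  prev$refined <- TRUE
  tab5 <- propagate_abundance(reads, prev, 5L)
  oracle5 <- o_count_kminmers(reads, rep(FALSE, length(reads)), 5L)
  expect_setequal(tab5$keys, names(oracle5))
})
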