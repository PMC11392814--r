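test_that("parameter arithmetic matches the published configuration", {
  cfg <- assembly_config()
  expect_equal(initial_overlap_bp(cfg), 600)
  expect_equal(overlap_increment_bp(cfg), 200)
  expect_equal(compute_kprime_max(10000, 0.005), 100L)
  expect_equal(compute_kprime_max(400, 0.005), 5L) # floor at kprime_min + 1
})

test_that("progressive filter snapshots shrink as the threshold rises", {
  # uniform-abundance cycle: S_1..S_5 hold the same single unitig, the
  # graph empties at t = 5
  cyc <- cycle_seq(12)
  tups <- o_windows(cyc, TRUE, 3L)
  g <- graph_from_tuples(tups, abund = rep(5, 12))
  snaps <- progressive_filter(g)
  expect_length(snaps, 5)
  for (s in snaps) {
    expect_length(s$path, 1)
    expect_equal(s$abundance, 5)
    expect_true(s$is_circular)
  }

  expect_length(progressive_filter(build_mdbg(
    count_kminmers(list(integer(0)), 4L))), 0)
})

test_that("fragmented unitigs merge once low-abundance noise is removed", {
  # an abundance-4 backbone cycle interrupted by abundance-1 noise spurs:
  # at t = 1 the noise is removed, the backbone re-compacts, and the
  # abundance-2 style fragments are recovered in later snapshots instead of
  # being lost
  cyc <- cycle_seq(30)
  backbone <- o_windows(cyc, TRUE, 3L)
  # noise branches off three backbone positions
  noise <- list(c(5, 6, 90), c(6, 90, 91), c(15, 16, 95), c(16, 95, 96),
                c(25, 26, 98))
  tups <- c(backbone, noise)
  g <- graph_from_tuples(tups, abund = c(rep(4, 30), rep(1, 5)), d = 0.5)
  snaps <- progressive_filter(g, tip_max_len_bp = 1e9, bubble_max_len_bp = 1e9)
  # by t = 2 (after the t=1 removal) the backbone is one circular unitig
  s2 <- snaps[[2]]
  big <- which(lengths(s2$path) == 30)
  expect_length(big, 1)
  expect_true(s2$is_circular[big])
  expect_equal(s2$abundance[big], 4)
  mc <- generate_mcontigs(snaps, g)
  expect_true(any(vapply(mc, function(m) m$is_circular &&
                           length(m$minimizers) == 30, logical(1))))
})

test_that("mContig emission follows the local abundance threshold", {
  # hand-built snapshots over a graph of two disjoint chains
  chain_a <- lapply(1:4, function(i) c(i, i + 1, i + 2))
  chain_b <- lapply(1:4, function(i) c(i + 20, i + 21, i + 22))
  g <- graph_from_tuples(c(chain_a, chain_b), abund = c(rep(6, 4), rep(5, 4)))
  snaps <- progressive_filter(g)
  # abundance 6 >= 3/0.5 = 6 -> emitted from S_3; abundance 5 is not
  # emitted at t = 3 but qualifies at t <= 2
  mc <- generate_mcontigs(snaps[1:3], g, beta_contig = 0.5)
  expect_length(mc, 2)
  expect_setequal(vapply(mc, function(m) m$abundance, numeric(1)), c(6, 5))
  # restrict the snapshot list to S_3 alone (t = 1, 2 empty): the
  # abundance-6 unitig passes 6 >= 3/0.5, the abundance-5 one does not
  empty <- snaps[[1]]
  for (f in names(empty)) {
    if (f %in% c("kprime", "d")) next
    empty[[f]] <- empty[[f]][0]
  }
  only3 <- snaps[1:3]
  only3[[1]] <- only3[[2]] <- empty
  mc3 <- generate_mcontigs(only3, g, beta_contig = 0.5)
  expect_equal(vapply(mc3, function(m) m$abundance, numeric(1)), 6)
  # under the strict variant 6 > 6 fails and nothing is emitted from S_3
  mc_strict <- generate_mcontigs(only3, g, beta_contig = 0.5, strict = TRUE)
  expect_length(mc_strict, 0)
})

test_that("emitted mContigs never share a k'-min-mer", {
  # a repeat-rich random graph emitted over all snapshots
  set.seed(99)
  for (i in 1:5) {
    seqs <- lapply(1:3, function(j) sample.int(40, 25, replace = TRUE))
    tab <- count_kminmers(seqs, 3L)
    g <- build_mdbg(tab)
    snaps <- progressive_filter(g)
    mc <- generate_mcontigs(snaps, g)
    expect_true(assert_nonredundant(mc, 3L))
  }
})

test_that("multi-k' assembly handles degenerate inputs", {
  set.seed(7)
  reads <- vapply(1:3, function(i) random_dna(400), character(1))
  names(reads) <- paste0("r", 1:3)
  expect_warning(asm <- assemble(reads, assembly_config(kprime_max = 5L,
                                                        d = 0.001)),
                 "no read")
  expect_length(asm$mcontigs, 0)

  # k'max == k'min + 1 still assembles a small cyclic genome
  g <- random_dna(8000, seed = 8)
  reads2 <- vapply(seq(1, 7500, by = 400), function(s) {
    substr(paste0(g, g), s, s + 1500)
  }, character(1))
  names(reads2) <- paste0("t", seq_along(reads2))
  asm2 <- assemble(reads2, assembly_config(kprime_min = 4L, kprime_max = 5L))
  expect_gt(length(asm2$mcontigs), 0)
  expect_equal(asm2$stats$kprime, 4:5)
})

test_that("a small circular genome is assembled end to end in minimizer space", {
  g <- random_dna(20000, seed = 15)
  starts <- seq(1, 20000, by = 900)
  reads <- vapply(starts, function(s) substr(paste0(g, g), s, s + 3999),
                  character(1))
  names(reads) <- paste0("r", seq_along(reads))
  asm <- assemble(reads, assembly_config())
  circ <- Filter(function(m) m$is_circular, asm$mcontigs)
  expect_length(circ, 1)
  # the circular mContig spells the genome's full minimizer cycle
  ref_mr <- extract_mread("g", g, minimizer_scheme())
  expect_equal(length(circ[[1]]$minimizers), length(ref_mr$minimizers))
})
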