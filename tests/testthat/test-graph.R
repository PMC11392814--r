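test_that("edges follow the k'-1 overlap definition", {
  g <- graph_from_tuples(list(c(1, 2, 3), c(2, 3, 4)))
  expect_equal(nrow(g$edges), 1L)

  # two disjoint chains -> no cross edges; components check via igraph
  g2 <- graph_from_tuples(list(c(1, 2, 3), c(2, 3, 4), c(10, 11, 12),
                               c(11, 12, 13)))
  expect_equal(nrow(g2$edges), 2L)
  if (requireNamespace("igraph", quietly = TRUE)) {
    ig <- igraph::graph_from_edgelist(
      cbind(g2$edges[, 1], g2$edges[, 3]), directed = FALSE)
    comp <- igraph::components(ig)
    expect_equal(comp$no, 2L)
  }
})

test_that("edge set matches the brute-force oracle on random graphs", {
  for (seed in 1:25) {
    rg <- o_random_graph(seed)
    g <- graph_from_tuples(rg$tuples, rg$abund, rg$kp)
    oracle <- o_edge_matrix(g$tuples, rg$kp)
    got <- g$edges[order(g$edges[, 1], g$edges[, 2], g$edges[, 3],
                         g$edges[, 4]), , drop = FALSE]
    dimnames(got) <- NULL
    expect_identical(got, oracle, label = paste("seed", seed))
  }
})

test_that("every oriented edge has its mirror (edge symmetry)", {
  for (seed in 1:10) {
    rg <- o_random_graph(seed + 100)
    g <- graph_from_tuples(rg$tuples, rg$abund, rg$kp)
    adj <- o_adj(g$edges, length(g$keys))
    for (v in seq_along(adj) - 1L) {
      for (u in adj[[v + 1L]]) {
        expect_true(bitwXor(v, 1L) %in% adj[[bitwXor(u, 1L) + 1L]])
      }
    }
  }
})

test_that("compaction yields maximal non-branching paths", {
  # linear chain of 5 nodes -> one unitig of length 5
  chain <- lapply(1:5, function(i) c(i, i + 1, i + 2))
  u <- compact_mdbg(graph_from_tuples(chain, abund = rep(3, 5)))
  expect_length(u$path, 1)
  expect_length(u$path[[1]], 5)
  expect_false(u$is_circular[1])
  expect_equal(u$abundance[1], 3)
  expect_equal(u$n_minimizers[1], 3 + 5 - 1)

  # perfect cycle -> one circular unitig
  cyc <- cycle_seq(8)
  tups <- o_windows(cyc, TRUE, 3L)
  u2 <- compact_mdbg(graph_from_tuples(tups, abund = rep(7, 8)))
  expect_length(u2$path, 1)
  expect_true(u2$is_circular[1])
  expect_equal(u2$n_minimizers[1], 8L)

  # X repeat: two in-arms, two out-arms around a shared center
  paths <- list(c(1, 2, 3, 100, 101, 102, 20, 21, 22),
                c(5, 6, 7, 100, 101, 102, 30, 31, 32))
  tups3 <- unique(unlist(lapply(paths, function(p) o_windows(p, FALSE, 3L)),
                         recursive = FALSE))
  canon_keys <- vapply(tups3, function(w) paste(
    minidbg:::cpp_canonicalize_kminmer(as.integer(w))$mins, collapse = ","),
    character(1))
  tups3 <- tups3[!duplicated(canon_keys)]
  u3 <- compact_mdbg(graph_from_tuples(tups3, abund = rep(2, length(tups3))))
  expect_length(u3$path, 5) # 4 arms + 1 center
})

test_that("compaction matches the independent oracle on random graphs", {
  for (seed in 1:40) {
    rg <- o_random_graph(seed + 300)
    g <- graph_from_tuples(rg$tuples, rg$abund, rg$kp)
    u <- compact_mdbg(g)
    got <- o_unitig_set_keys(g$tuples, lapply(seq_along(u$path), function(i) {
      path <- ifelse(u$path[[i]] > 0, (abs(u$path[[i]]) - 1L) * 2L,
                     (abs(u$path[[i]]) - 1L) * 2L + 1L)
      list(path = path, circular = u$is_circular[i],
           abundance = u$abundance[i])
    }))
    units_o <- o_compact(g$tuples, g$abundance, g$edges)
    expect_identical(got, o_unitig_set_keys(g$tuples, units_o),
                     label = paste("seed", seed))
  }
})

test_that("short dead-end unitigs are disconnected but not deleted", {
  # long chain with a 2-node spur off the middle; with d = 0.5 the spur
  # spans 8 bp-equivalents and the two chain halves 14 and 16, so a cap of
  # 10 clips exactly the spur
  chain <- lapply(1:11, function(i) c(i, i + 1, i + 2))
  spur <- list(c(6, 7, 80), c(7, 80, 81))
  g <- graph_from_tuples(c(chain, spur), abund = c(rep(5, 11), 1, 1),
                         d = 0.5)
  n_before <- length(g$keys)
  g2 <- clip_tips(g, max_len_bp = 10)
  expect_length(g2$keys, n_before) # retained, not removed
  u <- compact_mdbg(g2)
  # after disconnection the chain re-compacts into one unitig, spur isolated
  expect_length(u$path, 2)
  expect_true(any(u$tip_derived))
  spur_idx <- which(u$tip_derived)
  spur_nodes <- abs(u$path[[spur_idx]])
  # no edge connects a spur node to a non-spur node any more
  em <- g2$edges
  cross <- (em[, 1] %in% spur_nodes) != (em[, 3] %in% spur_nodes)
  expect_false(any(cross))

  # with the cap below the spur's span the graph is untouched
  g3 <- clip_tips(g, max_len_bp = 4)
  expect_equal(nrow(g3$edges), nrow(g$edges))

  # an isolated unitig is not a tip
  iso <- graph_from_tuples(list(c(60, 61, 62), c(61, 62, 63)),
                           abund = c(1, 1), d = 0.5)
  iso2 <- clip_tips(iso, 10)
  expect_equal(nrow(iso2$edges), nrow(iso$edges))
  expect_false(any(iso2$tip))
})

test_that("superbubble popping keeps the max-abundance path", {
  # two-path bubble: source (1,2,3), branches 7x vs 2x, sink (8,9,10)
  top <- list(c(1, 2, 3), c(2, 3, 40), c(3, 40, 41), c(40, 41, 8),
              c(41, 8, 9), c(8, 9, 10))
  bot <- list(c(2, 3, 50), c(3, 50, 51), c(50, 51, 8), c(51, 8, 9))
  ab <- c(5, 7, 7, 7, 7, 5, 2, 2, 2, 2)
  g <- graph_from_tuples(c(top, bot), abund = ab)
  g2 <- pop_superbubbles(g, 50000)
  expect_gt(attr(g2, "n_popped"), 0)
  # the 2x branch interior is gone; the 7x branch survives
  keys2 <- g2$keys
  expect_false(paste(minidbg:::cpp_canonicalize_kminmer(c(3L, 50L, 51L))$mins,
                     collapse = ",") %in% keys2)
  expect_true(paste(minidbg:::cpp_canonicalize_kminmer(c(3L, 40L, 41L))$mins,
                    collapse = ",") %in% keys2)
  # idempotent at fixed threshold
  g3 <- pop_superbubbles(g2, 50000)
  expect_equal(g3$keys, g2$keys)

  # a bubble larger than the cap is untouched
  g4 <- pop_superbubbles(g, 200) # cap ~1 node at d = 0.005
  expect_equal(length(g4$keys), length(g$keys))
})

test_that("popping matches the definition-based oracle on random graphs", {
  for (seed in 1:40) {
    rg <- o_random_graph(seed + 500)
    g <- graph_from_tuples(rg$tuples, rg$abund, rg$kp)
    g2 <- pop_superbubbles(g, 1e9)
    alive_o <- o_pop_superbubbles(g$tuples, g$abundance, g$edges)
    expect_identical(sort(g2$keys), sort(g$keys[alive_o]),
                     label = paste("seed", seed))
  }
})

test_that("simplifications never alter surviving node abundances", {
  for (seed in 1:10) {
    rg <- o_random_graph(seed + 900)
    g <- graph_from_tuples(rg$tuples, rg$abund, rg$kp)
    g2 <- pop_superbubbles(clip_tips(g, 50000), 50000)
    expect_identical(g2$abundance,
                     g$abundance[match(g2$keys, g$keys)])
  }
})

test_that("GFA export writes header, segments and links", {
  chain <- lapply(1:5, function(i) c(i, i + 1, i + 2))
  spur <- list(c(3, 4, 50), c(4, 50, 51))
  g <- graph_from_tuples(c(chain, spur), abund = c(rep(5, 5), 1, 1))
  f <- tempfile(fileext = ".gfa")
  write_gfa(g, f)
  lines <- readLines(f)
  expect_match(lines[1], "^H\tVN:Z:1\\.0")
  expect_gt(sum(startsWith(lines, "S\t")), 1)
  expect_gt(sum(startsWith(lines, "L\t")), 0)
  expect_true(all(grepl("dp:f:", lines[startsWith(lines, "S\t")])))
})
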