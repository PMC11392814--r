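test_that("homopolymer compression collapses runs and maps coordinates", {
  r <- homopolymer_compress("AAACCG")
  expect_equal(r$hpc, "ACG")
  expect_equal(unname(r$runs[, "start"]), c(0L, 3L, 5L))
  expect_equal(unname(r$runs[, "end"]), c(3L, 5L, 6L))

  r2 <- homopolymer_compress("ACGT")
  expect_equal(r2$hpc, "ACGT")
  expect_equal(unname(r2$runs[, "end"] - r2$runs[, "start"]), rep(1L, 4))

  expect_equal(homopolymer_compress("")$hpc, "")
})

test_that("compression round-trips on random sequence", {
  set.seed(11)
  for (i in 1:5) {
    s <- random_dna(1000)
    r <- homopolymer_compress(s)
    expect_false(any(diff(utf8ToInt(r$hpc)) == 0)) # no equal adjacent bases
    expect_equal(homopolymer_decompress(r$hpc, r$runs), s)
  }
})

test_that("canonical_kmer returns the lexicographic minimum with revcomp", {
  expect_equal(canonical_kmer("AAT"), "AAT")
  expect_equal(canonical_kmer("TTT"), "AAA")
  expect_equal(canonical_kmer("ACGT"), "ACGT") # self-reverse-complement
  set.seed(3)
  kmers <- vapply(1:50, function(i) random_dna(13), character(1))
  expect_equal(canonical_kmer(kmers), canonical_kmer(vapply(kmers, revcomp,
                                                            character(1))))
})

test_that("minimizer test is deterministic, strand-symmetric and monotone in d", {
  set.seed(4)
  kmers <- vapply(1:2000, function(i) random_dna(13), character(1))
  s1 <- minimizer_scheme(d = 0.01)
  hit1 <- is_universal_minimizer(kmers, s1)
  expect_identical(hit1, is_universal_minimizer(kmers, s1))
  expect_identical(hit1, is_universal_minimizer(
    vapply(kmers, revcomp, character(1)), s1))
  hit2 <- is_universal_minimizer(kmers, minimizer_scheme(d = 0.1))
  expect_true(all(hit2[hit1])) # smaller-d selection is a subset
  expect_true(is.na(is_universal_minimizer("ACGTNACGTNACG",
                                           minimizer_scheme())))
})

test_that("empirical selection density matches d (binomial bound)", {
  # 1e5 independent canonical 13-mers cut from a random sequence
  set.seed(9)
  n <- 1e5
  seq <- random_dna(13 * n)
  r <- minidbg:::cpp_count_selected(seq, 13L, 0.005, 42, 13L)
  p_hat <- r[2] / r[1]
  tol <- 4 * sqrt(0.005 * 0.995 / r[1])
  expect_lt(abs(p_hat - 0.005), tol)
})

test_that("extract_mread scans the compressed sequence in order", {
  scheme <- minimizer_scheme()
  expect_length(extract_mread("x", "ACGTACG", scheme)$minimizers, 0)

  set.seed(21)
  s <- random_dna(10000)
  mr <- extract_mread("r1", s, scheme)
  expect_true(all(diff(mr$hpc_pos) > 0))
  expect_equal(length(mr$minimizers), length(mr$orig_start))
  # expected count ~ hpc_len * d
  expect_gt(length(mr$minimizers), mr$hpc_len * 0.005 - 4 * sqrt(mr$hpc_len * 0.005))
  expect_lt(length(mr$minimizers), mr$hpc_len * 0.005 + 4 * sqrt(mr$hpc_len * 0.005))
  # every recorded span decodes back to the recorded canonical k-mer
  for (i in seq_len(min(10, length(mr$minimizers)))) {
    sub <- substr(s, mr$orig_start[i] + 1, mr$orig_end[i])
    hpc_sub <- homopolymer_compress(sub)$hpc
    km <- substr(hpc_sub, 1, scheme$k)
    expect_equal(canonical_kmer(km),
                 minidbg:::cpp_decode_kmer(mr$minimizers[i], scheme$k))
  }
})

test_that("a read and its reverse complement give mirrored minimizer lists", {
  scheme <- minimizer_scheme()
  set.seed(31)
  for (i in 1:4) {
    s <- random_dna(2000)
    a <- extract_mread("f", s, scheme)
    b <- extract_mread("r", revcomp(s), scheme)
    expect_equal(a$minimizers, rev(b$minimizers))
    # spans mirror through the read length
    expect_equal(a$orig_start, rev(nchar(s) - b$orig_end))
  }
})

test_that("windows containing N emit no minimizer", {
  scheme <- minimizer_scheme(d = 0.5)
  set.seed(41)
  s <- random_dna(300)
  sN <- paste0(substr(s, 1, 150), "N", substr(s, 152, 300))
  a <- extract_mread("a", s, scheme)
  b <- extract_mread("b", sN, scheme)
  # no minimizer of b overlaps the N position (HPC pos of N)
  npos <- nchar(homopolymer_compress(substr(sN, 1, 151))$hpc) - 1L
  expect_false(any(b$hpc_pos <= npos & b$hpc_pos + scheme$k - 1L >= npos))
  expect_gt(length(b$minimizers), 0)
})

test_that("k'-min-mer canonicalization follows the first-difference rule", {
  r <- canonicalize_kminmer(c(5L, 9L, 2L))
  expect_equal(r$mins, c(2L, 9L, 5L))
  expect_true(r$is_reversed)

  r2 <- canonicalize_kminmer(c(1L, 7L, 4L))
  expect_equal(r2$mins, c(1L, 7L, 4L))
  expect_false(r2$is_reversed)

  r3 <- canonicalize_kminmer(c(3L, 8L, 3L)) # palindromic
  expect_equal(r3$mins, c(3L, 8L, 3L))
  expect_false(r3$is_reversed)

  set.seed(5)
  for (i in 1:20) {
    w <- sample.int(50, 5, replace = TRUE)
    a <- canonicalize_kminmer(w)
    b <- canonicalize_kminmer(rev(w))
    expect_equal(a$mins, b$mins)
    if (!identical(w, rev(w))) expect_true(xor(a$is_reversed, b$is_reversed))
  }
})
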