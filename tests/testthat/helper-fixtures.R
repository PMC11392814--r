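# Shared fixtures. Expensive end-to-end runs used by several acceptance
# checks are computed once per session and memoized here.

.fixture_env <- new.env(parent = emptyenv())

memo <- function(name, expr) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- force(expr)
  .fixture_env[[name]]
}

random_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a minimizer-space "genome": a cyclic sequence of distinct minimizer ids
cycle_seq <- function(n, offset = 0L) as.integer(seq_len(n) + offset)

# windows of a cyclic integer sequence as plain reads tiling it
tile_cycle <- function(cyc, read_len, step) {
  n <- length(cyc)
  starts <- seq(1L, n, by = step)
  lapply(starts, function(s) {
    idx <- ((s - 1L + seq_len(read_len) - 1L) %% n) + 1L
    as.integer(cyc[idx])
  })
}

# the standard desk-scale benchmark community used by the acceptance tests:
# error-free variant (exactness) and 0.1%-error variant (robustness)
# the paper's 1 Mb purge-template floor is scaled to the 30-100 kb desk
# genomes: templates are the contigs of at least 45 kb
bench_config <- function() assembly_config(template_min_len = 45000)

bench_errorfree <- function() {
  memo("bench_errorfree", {
    spec <- community_spec(strains = NULL, chimera_rate = 0,
                           sub_rate = 0, ins_rate = 0, del_rate = 0,
                           seed = 42)
    sim <- simulate_community(spec)
    run <- run_assembly(sim$reads, config = bench_config(),
                        polish = TRUE, purge = TRUE)
    list(sim = sim, run = run)
  })
}

bench_errors <- function() {
  memo("bench_errors", {
    spec <- community_spec(strains = NULL, chimera_rate = 0, seed = 42)
    sim <- simulate_community(spec)
    run <- run_assembly(sim$reads, config = bench_config(),
                        polish = TRUE, purge = TRUE)
    list(sim = sim, run = run)
  })
}

# exact rotation-normalized containment of a contig in a reference
is_exact_copy <- function(contig_seq, ref_seq, ref_circular = TRUE) {
  hay <- if (ref_circular) paste0(ref_seq, ref_seq) else ref_seq
  grepl(contig_seq, hay, fixed = TRUE) ||
    grepl(minidbg::revcomp(contig_seq), hay, fixed = TRUE)
}

# helper: build an mdbg from explicit k'-min-mer tuples
graph_from_tuples <- function(tuples, abund = NULL, kp = length(tuples[[1]]),
                              d = 0.005) {
  canon <- lapply(tuples, function(w) {
    as.integer(minidbg:::cpp_canonicalize_kminmer(as.integer(w))$mins)
  })
  keys <- vapply(canon, paste, character(1), collapse = ",")
  stopifnot(!anyDuplicated(keys))
  ord <- order(xtfrm(keys), method = "radix")
  tab <- structure(list(kprime = as.integer(kp), keys = keys[ord],
                        abundance = if (is.null(abund)) rep(1L, length(keys))[ord]
                                    else as.integer(abund)[ord],
                        tuples = canon[ord], refined = FALSE),
                   class = "abundance_table")
  build_mdbg(tab, d)
}

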