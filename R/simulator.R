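#' Specification of a synthetic community
#'
#' Defines a small community of circular genomes with a log-spread
#' abundance profile, an optional near-identical strain pair, HiFi-like
#' reads (log-normal lengths, ~0.1% errors) and an optional chimera rate.
#' The defaults describe the package's standard desk-scale benchmark: five
#' random genomes of 30-100 kb at 5-80x coverage (higher coverage paired
#' with shorter genomes so that complete recovery of the rarest genome is
#' probable under Lander-Waterman statistics), one strain variant of the
#' 20x genome at 99% average nucleotide identity and 4x coverage, and 1%
#' chimeric reads.
#'
#' @param genome_lengths genome lengths in bp
#' @param coverages per-genome coverage depths (same order)
#' @param circular logical, recycled over genomes
#' @param strains data.frame with columns `source` (genome index),
#'   `divergence` (per-base edit rate, < 1) and `coverage`; `NULL` for none
#' @param read_len_median median read length (default 10 kb)
#' @param read_len_sdlog log-normal sdlog of read lengths (default 0.35);
#'   lengths are truncated to `[read_len_min, 3 * read_len_median]`
#' @param read_len_min minimum read length (default 1 kb)
#' @param sub_rate,ins_rate,del_rate per-base error rates (defaults
#'   6e-4/2e-4/2e-4, i.e. 0.1% total)
#' @param chimera_rate fraction of reads joining two random fragments
#' @param seed seed fixing all randomness
#' @export
community_spec <- function(genome_lengths = c(30e3, 45e3, 60e3, 80e3, 100e3),
                           coverages = c(5, 10, 20, 40, 80),
                           circular = TRUE,
                           strains = data.frame(source = 3, divergence = 0.01,
                                                coverage = 4),
                           read_len_median = 10e3,
                           read_len_sdlog = 0.35,
                           read_len_min = 1e3,
                           sub_rate = 6e-4, ins_rate = 2e-4, del_rate = 2e-4,
                           chimera_rate = 0.01,
                           seed = 42L) {
  stopifnot(length(genome_lengths) == length(coverages), all(coverages > 0),
            all(c(sub_rate, ins_rate, del_rate, chimera_rate) >= 0),
            all(c(sub_rate, ins_rate, del_rate, chimera_rate) < 1))
  if (!is.null(strains) && nrow(strains) > 0 &&
      any(strains$divergence >= 1)) {
    stop("strain divergence must be < 1")
  }
  structure(list(genome_lengths = genome_lengths, coverages = coverages,
                 circular = rep_len(circular, length(genome_lengths)),
                 strains = strains,
                 read_len_median = read_len_median,
                 read_len_sdlog = read_len_sdlog,
                 read_len_min = read_len_min,
                 sub_rate = sub_rate, ins_rate = ins_rate,
                 del_rate = del_rate,
                 chimera_rate = chimera_rate, seed = as.integer(seed)),
            class = "community_spec")
}

#' @export
print.community_spec <- function(x, ...) {
  cat(sprintf(paste0("community_spec: %d genomes (%s bp) at %sx, %d ",
                     "strain(s), errors %g/%g/%g, chimeras %g, seed %d\n"),
              length(x$genome_lengths),
              paste(x$genome_lengths, collapse = "/"),
              paste(x$coverages, collapse = "/"),
              if (is.null(x$strains)) 0L else nrow(x$strains),
              x$sub_rate, x$ins_rate, x$del_rate, x$chimera_rate, x$seed))
  invisible(x)
}

.random_genome <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}

# derive a strain variant by Poisson-placed edits at the requested divergence
.mutate_genome <- function(seq, divergence) {
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(v)
  n_edit <- rbinom(1, n, divergence)
  if (n_edit == 0L) return(list(seq = seq, n_edits = 0L))
  pos <- sort(sample.int(n, n_edit))
  kind <- sample(c("sub", "ins", "del"), n_edit, replace = TRUE,
                 prob = c(0.9, 0.05, 0.05))
  bases <- c("A", "C", "G", "T")
  out <- v
  for (i in seq_len(n_edit)) {
    p <- pos[i]
    if (kind[i] == "sub") {
      out[p] <- sample(setdiff(bases, v[p]), 1)
    } else if (kind[i] == "ins") {
      out[p] <- paste0(out[p], sample(bases, 1))
    } else {
      out[p] <- ""
    }
  }
  list(seq = paste(out, collapse = ""), n_edits = n_edit)
}

#' Generate the reference genomes of a community
#'
#' Random genomes with uniform base composition; strain variants are
#' derived from their source genome by randomly placed substitutions (90%)
#' and 1-base indels (10%) at the requested divergence. Fully deterministic
#' under the spec seed.
#'
#' @param spec a [community_spec()]
#' @return list with `genomes` (named character vector), and `truth`
#'   (data.frame: name, length, coverage, circular, is_strain, source,
#'   divergence)
#' @export
generate_genomes <- function(spec) {
  set.seed(spec$seed)
  ng <- length(spec$genome_lengths)
  genomes <- character(0)
  truth <- NULL
  for (i in seq_len(ng)) {
    g <- .random_genome(spec$genome_lengths[i])
    nm <- sprintf("genome_%d", i)
    genomes[nm] <- g
    truth <- rbind(truth, data.frame(
      name = nm, length = nchar(g), coverage = spec$coverages[i],
      circular = spec$circular[i], is_strain = FALSE, source = NA_character_,
      divergence = 0))
  }
  if (!is.null(spec$strains) && nrow(spec$strains) > 0) {
    for (s in seq_len(nrow(spec$strains))) {
      src <- spec$strains$source[s]
      mut <- .mutate_genome(genomes[[src]], spec$strains$divergence[s])
      nm <- sprintf("strain_%d_of_genome_%d", s, src)
      genomes[nm] <- mut$seq
      truth <- rbind(truth, data.frame(
        name = nm, length = nchar(mut$seq),
        coverage = spec$strains$coverage[s],
        circular = spec$circular[src], is_strain = TRUE,
        source = sprintf("genome_%d", src),
        divergence = spec$strains$divergence[s]))
    }
  }
  list(genomes = genomes, truth = truth)
}

.inject_errors <- function(seq, sub_rate, ins_rate, del_rate) {
  if (sub_rate + ins_rate + del_rate == 0) return(seq)
  v <- strsplit(seq, "", fixed = TRUE)[[1]]
  n <- length(v)
  u <- runif(n)
  bases <- c("A", "C", "G", "T")
  subs <- which(u < sub_rate)
  if (length(subs)) {
    for (p in subs) v[p] <- sample(setdiff(bases, v[p]), 1)
  }
  ins <- which(u >= sub_rate & u < sub_rate + ins_rate)
  if (length(ins)) {
    v[ins] <- paste0(v[ins], sample(bases, length(ins), replace = TRUE))
  }
  del <- which(u >= sub_rate + ins_rate & u < sub_rate + ins_rate + del_rate)
  if (length(del)) v[del] <- ""
  paste(v, collapse = "")
}

#' Sample HiFi-like reads from a community
#'
#' The number of reads per genome is chosen so that the total sampled bases
#' equal coverage x length. Read lengths are log-normal (median
#' `read_len_median`), truncated to `[read_len_min, 3 x median]`; start
#' positions are uniform, wrapping the origin for circular genomes; strands
#' are random. Substitutions and 1-base indels are injected at the
#' configured rates, and a fraction `chimera_rate` of reads is formed by
#' joining the first half of the read with a fragment sampled from a random
#' genome (artifactual joins that create spurious graph edges).
#'
#' @param genomes output of [generate_genomes()]
#' @param spec the same [community_spec()]
#' @return list with `reads` (named character vector) and `truth`
#'   (data.frame: read, genome, start, len, strand, is_chimera)
#' @export
generate_reads <- function(genomes, spec) {
  set.seed(spec$seed + 1L)
  seqs <- genomes$genomes
  truth_g <- genomes$truth
  reads <- character(0)
  rt <- NULL
  meanlog <- log(spec$read_len_median)
  idx <- 0L
  for (gi in seq_len(nrow(truth_g))) {
    g <- seqs[[gi]]
    L <- nchar(g)
    circ <- truth_g$circular[gi]
    target <- truth_g$coverage[gi] * L
    gg <- if (circ) paste0(g, g) else g
    acc <- 0
    while (acc < target) {
      len <- round(min(max(rlnorm(1, meanlog, spec$read_len_sdlog),
                           spec$read_len_min), 3 * spec$read_len_median))
      len <- min(len, L)
      start <- sample.int(if (circ) L else max(1L, L - len + 1L), 1L)
      frag <- substr(gg, start, start + len - 1L)
      strand <- sample(c("+", "-"), 1L)
      if (strand == "-") frag <- cpp_revcomp(frag)
      frag <- .inject_errors(frag, spec$sub_rate, spec$ins_rate,
                             spec$del_rate)
      idx <- idx + 1L
      is_chim <- runif(1) < spec$chimera_rate
      if (is_chim) {
        gj <- sample.int(nrow(truth_g), 1L)
        g2 <- seqs[[gj]]
        l2 <- max(200L, len %/% 2L)
        s2 <- sample.int(max(1L, nchar(g2) - l2), 1L)
        frag <- paste0(substr(frag, 1L, max(200L, len %/% 2L)),
                       substr(g2, s2, s2 + l2 - 1L))
      }
      nm <- sprintf("read_%06d", idx)
      reads[nm] <- frag
      rt <- rbind(rt, data.frame(read = nm, genome = truth_g$name[gi],
                                 start = start - 1L, len = len,
                                 strand = strand, is_chimera = is_chim))
      acc <- acc + len
    }
  }
  list(reads = reads, truth = rt)
}

#' Simulate a community end to end
#'
#' Convenience wrapper: genomes plus reads, optionally written to disk
#' (genomes.fasta, reads.fasta or reads.fastq, truth TSVs, spec YAML).
#'
#' @param spec a [community_spec()]
#' @param out_dir directory to write files into, or `NULL`
#' @param format "fasta" or "fastq" for the reads
#' @return list with `genomes`, `genome_truth`, `reads`, `read_truth`, `spec`
#' @export
simulate_community <- function(spec = community_spec(), out_dir = NULL,
                               format = c("fasta", "fastq")) {
  format <- match.arg(format)
  g <- generate_genomes(spec)
  r <- generate_reads(g, spec)
  out <- list(genomes = g$genomes, genome_truth = g$truth,
              reads = r$reads, read_truth = r$truth, spec = spec)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_fasta(g$genomes, file.path(out_dir, "genomes.fasta"))
    if (format == "fasta") {
      write_fasta(r$reads, file.path(out_dir, "reads.fasta"))
    } else {
      write_fastq(r$reads, file.path(out_dir, "reads.fastq"))
    }
    utils::write.table(g$truth, file.path(out_dir, "genome_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(r$truth, file.path(out_dir, "read_truth.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    yaml::write_yaml(unclass(spec), file.path(out_dir, "community.yaml"))
  }
  out
}
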