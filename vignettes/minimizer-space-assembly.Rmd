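---
title: "Minimizer-space metagenome assembly with minidbg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Minimizer-space metagenome assembly with minidbg}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Metagenomes sequenced with accurate long reads (HiFi-class, ~99.9% per-base
accuracy, ~10 kb) mix organisms whose abundances span orders of magnitude.
A de Bruijn graph over such data faces two opposing pressures: small k-mers
are sensitive (they recover overlaps in rare, shallowly covered species) but
tangle strains and repeats; large k-mers resolve repeats but lose rare
species and break on residual errors. `minidbg` works in *minimizer space*:
each read is first reduced to the ordered list of its universal minimizers,
and assembly proceeds over windows of k' consecutive minimizers
(k'-min-mers). Because one minimizer stands for ~1/d bases, a k'-min-mer of
k' = 4 already spans ~600 bases, and growing k' by 1 grows the effective
overlap by ~200 bases at negligible cost — the whole multi-k' ladder runs
without ever re-reading the input.

## The model, step by step

**Universal minimizers.** A k-mer m (default k = 13) is a minimizer iff
f(m) < d·H, where f is a seeded 64-bit hash (splitmix64 applied to the 2-bit
encoding of the canonical k-mer), H = 2^64 and d = 0.005. Selection is
position-independent, so an expected fraction d of all k-mers is selected
wherever they occur, and hashing the *canonical* form makes selection
strand-symmetric: a read and its reverse complement yield mirrored minimizer
lists. Reads are homopolymer-compressed first, which hides the dominant
HiFi error mode (homopolymer length) from minimizer space entirely; the
compression map is retained so base-space spans can later be cut from the
original reads with whole runs intact.

**The graph.** Nodes are canonical k'-min-mers (window canonicalization
compares the window against its reversal element-wise). An oriented edge
joins x to y when the (k'-1)-suffix of oriented x equals the (k'-1)-prefix
of oriented y; the graph is bidirected, with every edge's mirror present by
construction. Unitigs are maximal non-branching paths; a unitig's abundance
is the lower median of its nodes' abundances, and its length in
base-equivalents is its spelled minimizer count divided by d.

**Abundance lifecycle.** Raw k'-min-mer counts are filtered read-locally:
with R_cov the median abundance within a read and beta_err = 0.1, an
abundance-1 k'-min-mer is discarded only when 1 < R_cov × beta_err, i.e.
only inside reads covered deeper than 10×. Rare species are left alone.
After each iteration's contigs are generated, abundances are smoothed (every
k'-min-mer of an mContig is set to the mContig's median C_cov) and
abundance-1 nodes inside long mContigs (> 2k' k'-min-mers) are rescued by
one unit. The next iteration assigns each (k'+1)-min-mer the *minimum* of
its two k'-parents' refined abundances — the minimum, not the mean, so an
erroneous parent is never rescued by a correct one — and drops propagated
singletons.

**Local progressive abundance filter.** The core contig generator iterates
an abundance threshold t from 1 to the abundance of the most abundant
unitig. At each t the graph is simplified (tips of ≤ 50 kb-equivalents are
*disconnected* but kept, since they may be rare species; superbubbles of
≤ 50 kb are popped in favour of their maximum-abundance path), compacted,
snapshotted as S_t, and purged of unitigs with abundance ≤ t. Fragmented
unitigs of an abundant genome re-merge as lower-abundance clutter (errors,
inter-genomic repeats, minor strains) disappears below the genome's own
depth. Contigs are then emitted from the snapshots in *descending* t: a
unitig of abundance a in S_t is emitted iff it shares no node with anything
already emitted and a ≥ t / beta_contig (beta_contig = 0.5). Descending
order guarantees each unitig is seen in its longest, maximally merged form
first; the node-set discipline makes the output non-redundant by
construction (and the package re-verifies this invariant on every call).

The threshold comparison is `>=`. The strict form `>` is also available
(`strict_contig_threshold`), but the worked consequence of the published
rule — a unitig of abundance 6 passing at t = 3 with beta = 0.5 — requires
the inclusive form, so that is the default.

**Multi-k'.** k' runs from 4 to round(median HPC read length × d × 2) in
steps of 1. Each iteration feeds the union of mReads and the previous
iteration's mContigs into counting; circular mContigs contribute their
windows cyclically, so a completed circle stays a circle. A circular
mContig with fewer than k' minimizers is a finished replicon and is carried
forward unchanged; short *linear* leftovers stop producing windows and drop
out, as in any multi-k scheme.

**Back to bases.** Final mContigs are indexed by their k'-min-mers at
k' = k'_min = 4 — the one size guaranteed to occur in actual reads — and
mReads are mapped onto them twice (forward and reversed), extending seed
matches maximally and keeping, per contig position, the longest match.
The first window contributes its full base span from its best read; every
later window appends only the bases between the ends of its second-to-last
and last minimizers, so the k'-1 overlap is never duplicated; for circular
contigs every window is "subsequent" cyclically and the pieces partition
the circle exactly. Polishing then assigns each read to one contig by
MS = alignLength × alignIdentity (identity matters when strains compete for
reads), splits contigs into 500-nt windows, and replaces each window with
the per-column majority of up to 20 read fragments, ties keeping the draft
base; insertion calls require a strict fragment majority. Finally,
contigs at least `template_min_len` long (1 Mb by default, after the scale
of real metagenomes) act as immutable templates: shorter contigs lose any
region aligning to a template above 99% identity, and tip-derived contigs
that are mostly duplicate are dropped entirely.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `k` | 13 | bases | minimizer length; short k tolerates residual errors |
| `d` | 0.005 | — | minimizer density; 1/d ≈ bases per minimizer |
| `kprime_min` | 4 | minimizers | first graph order; (k'-1)/d = 600 b overlap |
| `kprime_max` | auto | minimizers | median HPC read length × d × 2 |
| `beta_err` | 0.1 | — | read-local initial filter factor |
| `beta_contig` | 0.5 | — | local emission threshold a ≥ t/beta |
| `tip/bubble caps` | 50000 | bases | simplification length caps (in minimizer-count/d units) |
| `polish_window` | 500 | bases | consensus window |
| `polish_max_frags` | 20 | fragments | consensus depth cap |
| `template_min_len` | 1e6 | bases | purge template floor (set ~45 kb for desk-scale genomes) |

Graph length caps are measured in minimizer-count/d units: the graph never
knows true base lengths, and 1/d bases per minimizer is the expectation
that motivates the proxy.

## The simulator, and what passing tests mean

`community_spec()` describes the package's standard desk-scale benchmark:
five random circular genomes of 30–100 kb with a log-spread abundance
ladder of 5/10/20/40/80×, reads with log-normal lengths (median 10 kb,
sdlog 0.35, truncated to [1 kb, 30 kb]), substitution/insertion/deletion
rates of 6/2/2 × 10⁻⁴ (0.1% total), one strain variant of the 20× genome at
99% ANI and 4× depth, and 1% chimeric reads. Coverage is paired with
genome length deliberately: the rarest (5×) genome is the shortest (30 kb),
so that under Lander–Waterman statistics the probability of a physical
coverage gap — which no assembler can bridge — stays small (~15 reads of
10 kb on a 30 kb circle leave a gap with probability of a few percent).
All randomness flows from a single seed; the package-wide convention is 42.

The simulator emulates coverage spread, strain pairs, chimeras and uniform
random error. It does not emulate real base composition, repeat families,
context-dependent HiFi error profiles, or GC-coverage bias — so a passing
suite demonstrates the algorithmic contracts (exactness, abundance
handling, strain suppression) rather than field performance on real
samples.

## Numerical and design choices

* **Minimizer identity.** A minimizer is identified by the 2-bit integer
  encoding of its canonical 13-mer (k ≤ 15 keeps this inside a 32-bit
  integer); the 64-bit hash is used only for the density test. Any fixed
  total order of minimizer values serves the window canonicalization rule,
  and the encoding order is exact and platform-independent.
* **Medians** are lower medians throughout (read coverage, contig
  smoothing, unitig abundance): deterministic and integer-valued.
* **Superbubble path choice.** The retained path maximizes the lower
  median of its node abundances (consistent with the unitig-abundance
  convention), ties broken by the lexicographically smallest spelled
  sequence. Paths are enumerated exhaustively up to 4096 per bubble;
  denser bubbles (not observed at desk scale) fall back to the
  deterministic bottleneck (max–min) path.
* **Tip/bubble order and idempotence.** Each simplification round clips
  tips once and pops bubbles to a fixed point; popping is idempotent at a
  fixed cap. Sources with out-degree < 2 cannot head a minimal superbubble
  with non-empty interior and are skipped.
* **Conservative aborts.** A bubble candidate is abandoned if any node
  would appear in both orientations, or the source's mirror is inside —
  orientation-inconsistent "bubbles" are left to the abundance filter.
* **Read assignment for polishing** aligns a capped (2.4 kb) window around
  the best anchored match when minimizer evidence alone is not decisive
  (within 2× of the runner-up); the cap is shared by all candidates of a
  read, so the MS comparison is unaffected for long matches.
* **Degenerate inputs.** Empty reads give empty mReads; reads shorter
  than k' contribute nothing; an assembly with no eligible read warns and
  returns an empty contig set; a polishing window with no spanning
  fragment is left as drafted and flagged.
* **Evaluation.** Contigs are chained onto references through exact
  minimizer matches (chain gap 6 kb, safely above the largest expected
  minimizer desert at d = 0.005), each chain is verified by banded
  alignment, and references are graded complete (≥ 99% covered), partial,
  or missed (< 70%) with contigs uniquely assigned by decreasing
  MS and a 30% pre-coverage cap — the reference-based completeness
  protocol of the field, applied symmetrically to our own output.

## Problem sizes

The test suite assembles the five-genome benchmark twice (error-free and at
0.1% error; ~13 Mb of reads each, k' = 4…75), a 50 kb strain pair, and a
two-genome determinism community, and verifies the graph layer against
brute-force oracles on 1000 random graphs of ≤ 12 nodes. These sizes keep
the full suite in the tens of minutes on one core while exercising every
code path the larger regime uses.

Two further numerical safeguards came out of the exactness requirement.
First, a minimizer whose k-window touches the first or last compressed
position of a read is never emitted: the homopolymer run under the window
edge may be truncated by the read boundary, and a span that does not cover
the full run would leak run bases at reconstruction junctions. Second,
polishing aligns each fragment against a 10-base flank-extended copy of
its window and trims the consensus back, so that an indel sitting exactly
on a window junction is still voted on (by the window to its left); the
one junction this cannot reach is the rotation origin of a circular
contig.

## Known limitations

* Genomes shorter than the k'_max span in minimizer space survive only if
  they circularize before read windows run out; short *linear* replicons
  below ~(k'_max)/d bases can be lost late in the ladder.
* The purge step only removes duplicates of contigs longer than
  `template_min_len`; duplicates of shorter contigs (e.g. error-path
  copies of a small, shallow genome) can persist in the output.
* Identity is computed inside a fixed alignment band (±150 bases plus
  length difference); alignments with larger indel drift would be scored
  pessimistically (irrelevant at HiFi error rates).
* The consensus is a majority pileup, not a partial-order alignment; with
  accurate reads the difference is negligible, but at ONT-class error
  rates a POA consensus would be required.
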