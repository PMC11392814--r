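#' Build the minimizer-space de Bruijn graph
#'
#' Nodes are the canonical k'-min-mers of a filtered abundance table; an
#' oriented edge connects x to y whenever the (k'-1)-suffix of oriented x
#' equals the (k'-1)-prefix of oriented y. The graph is bidirected: every
#' oriented edge coexists with its mirror, and algorithms treat the two
#' orientations of a node as one unit.
#'
#' @param table a filtered `abundance_table`
#' @param d minimizer density (used to convert minimizer counts to
#'   base-pair-equivalent lengths, approximately 1/d bases per minimizer)
#' @return an object of class `mdbg`
#' @export
build_mdbg <- function(table, d = 0.005) {
  stopifnot(inherits(table, "abundance_table"))
  e <- cpp_build_edges(table$tuples, table$abundance, table$kprime, d)
  structure(list(kprime = table$kprime,
                 d = d,
                 keys = table$keys,
                 tuples = table$tuples,
                 abundance = table$abundance,
                 tip = rep(FALSE, length(table$keys)),
                 edges = e$edges),
            class = "mdbg")
}

#' @export
print.mdbg <- function(x, ...) {
  cat(sprintf("mdbg: k'=%d, %d nodes, %d edges\n", x$kprime,
              length(x$keys), nrow(x$edges)))
  invisible(x)
}

#' Compact an MDBG into unitigs
#'
#' A unitig is a maximal non-branching path: all internal nodes have in- and
#' out-degree 1 in their traversal orientation. Its abundance is the (lower)
#' median abundance of its constituent k'-min-mers; its length estimate in
#' base pairs is the length of the minimizer list it spells divided by the
#' density d. A simple cycle with no external edges becomes one circular
#' unitig; palindromic and self-looping k'-min-mers form their own unitigs.
#'
#' @param graph an `mdbg`
#' @return a `unitig_set`: list of parallel vectors (`path` holds signed
#'   1-based node indices, positive = forward orientation)
#' @export
compact_mdbg <- function(graph) {
  stopifnot(inherits(graph, "mdbg"))
  u <- cpp_compact(unclass(graph))
  structure(c(u, list(kprime = graph$kprime, d = graph$d)),
            class = "unitig_set")
}

#' @export
print.unitig_set <- function(x, ...) {
  cat(sprintf("unitig_set: %d unitigs (%d circular), abundance range %s\n",
              length(x$path), sum(x$is_circular),
              if (length(x$abundance)) paste(range(x$abundance), collapse = "-")
              else "-"))
  invisible(x)
}

#' Disconnect short tips
#'
#' Unitigs that dead-end on one side, connect to the rest of the graph on
#' the other, and span at most `max_len_bp` (in minimizer-count/d units) are
#' disconnected: the edges tying them to the graph are removed but their
#' nodes are retained as isolated components, flagged as tip-derived. They
#' may belong to rare species, so they are only removed at the very end of
#' assembly if they duplicate another contig at high identity.
#'
#' @param graph an `mdbg`
#' @param max_len_bp tip length cap (default 50000)
#' @return the modified `mdbg`
#' @export
clip_tips <- function(graph, max_len_bp = 50000) {
  stopifnot(inherits(graph, "mdbg"))
  r <- cpp_clip_tips(unclass(graph), max_len_bp)
  graph$edges <- r$edges
  graph$tip <- graph$tip | r$tip
  attr(graph, "n_clipped") <- r$n_clipped
  graph
}

#' Pop superbubbles
#'
#' Detects minimal superbubbles (single source, single sink, acyclic
#' interior, every interior path leading from source to sink) whose interior
#' spans at most `max_len_bp`, and keeps only the path with maximum
#' abundance (lower-median of node abundances along the path; ties broken by
#' the lexicographically smallest spelled minimizer sequence). All other
#' interior nodes are deleted. Popping repeats until no bubble remains, so
#' the operation is idempotent at a fixed threshold.
#'
#' @param graph an `mdbg`
#' @param max_len_bp bubble length cap (default 50000)
#' @return the modified `mdbg` (nodes removed, indices remapped)
#' @export
pop_superbubbles <- function(graph, max_len_bp = 50000) {
  stopifnot(inherits(graph, "mdbg"))
  r <- cpp_pop_superbubbles(unclass(graph), max_len_bp)
  keep <- r$keep
  if (all(keep)) {
    graph$edges <- r$edges
    attr(graph, "n_popped") <- r$n_popped
    return(graph)
  }
  map <- cumsum(keep)
  em <- r$edges
  kept_rows <- keep[em[, 1]] & keep[em[, 3]]
  em <- em[kept_rows, , drop = FALSE]
  em[, 1] <- map[em[, 1]]
  em[, 3] <- map[em[, 3]]
  graph$keys <- graph$keys[keep]
  graph$tuples <- graph$tuples[keep]
  graph$abundance <- graph$abundance[keep]
  graph$tip <- graph$tip[keep]
  graph$edges <- em
  attr(graph, "n_popped") <- r$n_popped
  graph
}

# internal: the minimizer list spelled by a unitig path
.spell_path <- function(path, tuples, circular) {
  oriented <- lapply(path, function(s) {
    tp <- tuples[[abs(s)]]
    if (s > 0) tp else rev(tp)
  })
  if (circular) {
    vapply(oriented, function(tp) tp[length(tp)], integer(1))
  } else {
    first <- oriented[[1]]
    if (length(oriented) == 1L) return(first)
    c(first, vapply(oriented[-1], function(tp) tp[length(tp)], integer(1)))
  }
}

#' Export a compacted assembly graph as GFA 1.0
#'
#' One S-line per unitig (sequence `*`, `LN` the base-pair length estimate,
#' `dp` the unitig abundance) and one L-line per adjacency between unitig
#' ends, with the k'-1 minimizer overlap noted as a `uo` tag (the CIGAR slot
#' carries `*` since unitigs are minimizer-space objects).
#'
#' @param graph an `mdbg`
#' @param units its `unitig_set` (defaults to `compact_mdbg(graph)`)
#' @param file output path
#' @export
write_gfa <- function(graph, file, units = compact_mdbg(graph)) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("H\tVN:Z:1.0\tks:i:%d", graph$kprime), con)
  n_u <- length(units$path)
  if (n_u == 0L) return(invisible(file))
  for (i in seq_len(n_u)) {
    writeLines(sprintf("S\tutg%06d\t*\tLN:i:%d\tdp:f:%g\tcl:Z:%s", i,
                       as.integer(round(units$est_len_bp[i])),
                       units$abundance[i],
                       if (units$is_circular[i]) "circular" else "linear"),
               con)
  }
  # adjacency between unitig ends, recovered from node-level edges: the tail
  # vertex of an oriented unitig is p[end] (+) or -p[1] (-); the head vertex
  # is p[1] (+) or -p[end] (-)
  tailmap <- new.env(parent = emptyenv())
  headmap <- new.env(parent = emptyenv())
  for (i in seq_len(n_u)) {
    p <- units$path[[i]]
    if (units$is_circular[i]) next
    assign(as.character(p[length(p)]), c(i, 1L), envir = tailmap)
    assign(as.character(-p[1]), c(i, -1L), envir = tailmap)
    assign(as.character(p[1]), c(i, 1L), envir = headmap)
    assign(as.character(-p[length(p)]), c(i, -1L), envir = headmap)
  }
  em <- graph$edges
  if (nrow(em)) {
    lines <- character(0)
    lookup <- function(env, v) {
      mget(as.character(v), envir = env, ifnotfound = list(NULL))[[1]]
    }
    for (r in seq_len(nrow(em))) {
      from <- em[r, 1] * (if (em[r, 2] == 1) 1 else -1)
      to <- em[r, 3] * (if (em[r, 4] == 1) 1 else -1)
      for (dir in 1:2) {
        ff <- if (dir == 1) from else -to
        tt <- if (dir == 1) to else -from
        a <- lookup(tailmap, ff)
        b <- lookup(headmap, tt)
        if (is.null(a) || is.null(b)) next
        lines <- c(lines,
                   sprintf("L\tutg%06d\t%s\tutg%06d\t%s\t*\tuo:i:%d",
                           a[1], if (a[2] > 0) "+" else "-",
                           b[1], if (b[2] > 0) "+" else "-",
                           graph$kprime - 1L))
      }
    }
    if (length(lines)) writeLines(sort(unique(lines)), con)
  }
  invisible(file)
}
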