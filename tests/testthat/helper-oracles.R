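# Independent brute-force oracles for the graph layer, written against the
# definitions rather than sharing code with the implementation.

o_canon <- function(w) {
  r <- rev(w)
  n <- length(w)
  for (i in seq_len(n)) {
    if (w[i] < r[i]) return(list(mins = w, rev = FALSE))
    if (r[i] < w[i]) return(list(mins = r, rev = TRUE))
  }
  list(mins = w, rev = FALSE)
}

o_windows <- function(v, circular, kp) {
  n <- length(v)
  if (n < kp) return(list())
  if (circular) {
    lapply(seq_len(n) - 1L, function(j) v[((j + 0:(kp - 1)) %% n) + 1L])
  } else {
    lapply(seq_len(n - kp + 1L) - 1L, function(j) v[(j + 1):(j + kp)])
  }
}

o_count_kminmers <- function(seqs, circular, kp) {
  counts <- new.env(parent = emptyenv())
  for (i in seq_along(seqs)) {
    for (w in o_windows(seqs[[i]], circular[i], kp)) {
      key <- paste(o_canon(w)$mins, collapse = ",")
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
    }
  }
  keys <- sort(ls(counts), method = "radix")
  setNames(vapply(keys, function(k) counts[[k]], integer(1)), keys)
}

# --- oriented-graph oracle ------------------------------------------------
# vertex = list(node index, o in {0 fwd, 1 rev}); encoded as 2*node + o with
# node 0-based, matching the implementation's vertex ids.

o_oriented_seq <- function(tuples, v) {
  tp <- tuples[[(v %/% 2) + 1L]]
  if (v %% 2 == 0L) tp else rev(tp)
}

o_edges <- function(tuples, kp) {
  n <- length(tuples)
  res <- NULL
  for (v in 0:(2 * n - 1)) {
    sv <- o_oriented_seq(tuples, v)
    for (u in 0:(2 * n - 1)) {
      su <- o_oriented_seq(tuples, u)
      if (identical(sv[-1], su[-kp])) res <- rbind(res, c(v, u))
    }
  }
  res
}

# canonical exported edge representation (from,to 1-based, fwd flags),
# mirroring the implementation's dedup rule
o_edge_matrix <- function(tuples, kp) {
  e <- o_edges(tuples, kp)
  if (is.null(e)) return(matrix(integer(0), ncol = 4))
  rows <- unique(t(apply(e, 1, function(vw) {
    v <- vw[1]; w <- vw[2]
    a <- c(v %/% 2, v %% 2, w %/% 2, w %% 2)
    m <- c(bitwXor(w, 1L) %/% 2, bitwXor(w, 1L) %% 2,
           bitwXor(v, 1L) %/% 2, bitwXor(v, 1L) %% 2)
    # keep the numerically (field-by-field) smaller of edge and mirror
    best <- a
    for (f in 1:4) {
      if (m[f] < best[f]) { best <- m; break }
      if (m[f] > best[f]) break
    }
    best
  })))
  out <- cbind(rows[, 1] + 1L, ifelse(rows[, 2] == 0L, 1L, 0L),
               rows[, 3] + 1L, ifelse(rows[, 4] == 0L, 1L, 0L))
  storage.mode(out) <- "integer"
  out[order(out[, 1], out[, 2], out[, 3], out[, 4]), , drop = FALSE]
}

# adjacency lists from an mdbg-style edge matrix over `alive` nodes
o_adj <- function(edges, n, alive = rep(TRUE, n)) {
  out <- vector("list", 2 * n)
  for (v in seq_len(2 * n)) out[[v]] <- integer(0)
  add <- function(v, w) {
    out[[v + 1L]] <<- sort(unique(c(out[[v + 1L]], w)))
  }
  if (nrow(edges)) {
    for (r in seq_len(nrow(edges))) {
      v <- 2L * (edges[r, 1] - 1L) + (if (edges[r, 2] == 1) 0L else 1L)
      w <- 2L * (edges[r, 3] - 1L) + (if (edges[r, 4] == 1) 0L else 1L)
      if (!alive[v %/% 2 + 1] || !alive[w %/% 2 + 1]) next
      add(v, w)
      add(bitwXor(w, 1L), bitwXor(v, 1L))
    }
  }
  out
}

o_is_palin <- function(tp) identical(tp, rev(tp))

o_lower_median <- function(x) sort(x)[(length(x) - 1) %/% 2 + 1]

# independent unitig compaction over the oriented adjacency
o_compact <- function(tuples, abund, edges, alive = rep(TRUE, length(tuples)),
                      kp = length(tuples[[1]])) {
  n <- length(tuples)
  adj <- o_adj(edges, n, alive)
  outdeg <- function(v) length(adj[[v + 1L]])
  indeg <- function(v) length(adj[[bitwXor(v, 1L) + 1L]])
  succ <- function(v) adj[[v + 1L]][1]
  has_self <- function(node) {
    any(vapply(adj[[2 * node + 1L]], function(u) u %/% 2 == node, logical(1))) ||
      any(vapply(adj[[2 * node + 2L]], function(u) u %/% 2 == node, logical(1)))
  }
  visited <- rep(FALSE, n)
  units <- list()
  for (i in seq_len(n) - 1L) {
    if (!alive[i + 1] || visited[i + 1]) next
    visited[i + 1] <- TRUE
    if (o_is_palin(tuples[[i + 1]]) || has_self(i)) {
      circ <- (2L * i) %in% adj[[2L * i + 1L]]
      units[[length(units) + 1L]] <- list(path = 2L * i, circular = circ)
      next
    }
    walk <- function(start) {
      acc <- integer(0)
      cur <- start
      circ <- FALSE
      repeat {
        if (outdeg(cur) != 1L) break
        nxt <- succ(cur)
        if (indeg(nxt) != 1L) break
        nn <- nxt %/% 2
        if (nn == start %/% 2) { if (nxt == start) circ <- TRUE; break }
        if (visited[nn + 1] || o_is_palin(tuples[[nn + 1]]) || has_self(nn))
          break
        acc <- c(acc, nxt)
        visited[nn + 1] <<- TRUE
        cur <- nxt
      }
      list(acc = acc, circ = circ)
    }
    fwd <- walk(2L * i)
    if (fwd$circ) {
      path <- c(2L * i, fwd$acc)
    } else {
      bwd <- walk(2L * i + 1L)
      path <- c(rev(bitwXor(bwd$acc, 1L)), 2L * i, fwd$acc)
    }
    units[[length(units) + 1L]] <- list(path = path, circular = fwd$circ)
  }
  lapply(units, function(u) {
    ab <- o_lower_median(abund[u$path %/% 2 + 1])
    list(path = u$path, circular = u$circular, abundance = ab)
  })
}

# canonical comparable form of a unitig: its spelled full minimizer sequence
# (concatenated oriented tuples), normalized over direction (and rotation
# for circular unitigs)
o_unitig_key <- function(tuples, path, circular) {
  spell <- function(p) {
    unlist(lapply(p, function(v) o_oriented_seq(tuples, v)))
  }
  mirror <- function(p) rev(bitwXor(p, 1L))
  cands <- list(spell(path), spell(mirror(path)))
  if (circular) {
    n <- length(path)
    for (r in seq_len(n - 1)) {
      rot <- c(path[-seq_len(r)], path[seq_len(r)])
      cands <- c(cands, list(spell(rot), spell(mirror(rot))))
    }
  }
  keys <- vapply(cands, paste, character(1), collapse = ",")
  min(keys)
}

o_unitig_set_keys <- function(tuples, units) {
  sort(vapply(units, function(u) {
    paste0(o_unitig_key(tuples, u$path, u$circular), "|", u$abundance, "|",
           u$circular)
  }, character(1)), method = "radix")
}

# --- superbubble oracle ---------------------------------------------------

o_reachable <- function(adj, from, stopv = NULL) {
  seen <- integer(0)
  stack <- from
  while (length(stack)) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v %in% seen) next
    seen <- c(seen, v)
    if (!is.null(stopv) && v == stopv) next
    stack <- c(stack, adj[[v + 1L]])
  }
  seen
}

o_paths <- function(adj, s, t, W) {
  paths <- list()
  dfs <- function(v, cur) {
    if (v == t) { paths[[length(paths) + 1L]] <<- cur; return() }
    for (u in adj[[v + 1L]]) {
      if (!(u %in% W) || u %in% cur) next
      dfs(u, c(cur, u))
    }
  }
  dfs(s, s)
  paths
}

# minimal superbubble with source s, by definition: smallest W such that
# W = reach(s, stop at t) united with t equals co-reach(t, stop at s)
# united with s, induced subgraph acyclic, no edge t->s, no node in both
# orientations, mirror of s not inside
o_find_superbubble <- function(adj, s, alive_vertices) {
  radj <- vector("list", length(adj))
  for (v in seq_along(adj) - 1L) {
    for (u in adj[[v + 1L]]) {
      radj[[u + 1L]] <- c(radj[[u + 1L]], v)
    }
  }
  best <- NULL
  if (length(adj[[s + 1L]]) == 0L) return(NULL)
  for (t in setdiff(alive_vertices, s)) {
    if (t %/% 2 == s %/% 2) next
    Wf <- o_reachable(adj, s, stopv = t)
    if (!(t %in% Wf)) next
    Wb <- o_reachable(radj, t, stopv = s)
    if (!(s %in% Wb)) next
    if (!setequal(Wf, Wb)) next
    W <- Wf
    if (length(W) <= 2L) next
    # no edge t -> s
    if (s %in% adj[[t + 1L]]) next
    # acyclicity of the full induced subgraph on W (including any edges the
    # sink throws back into the bubble): 3-colour DFS
    color <- new.env(parent = emptyenv())
    cyc <- FALSE
    visit <- function(v) {
      if (cyc) return()
      key <- as.character(v)
      st <- color[[key]]
      if (identical(st, 1L)) { cyc <<- TRUE; return() }
      if (identical(st, 2L)) return()
      color[[key]] <- 1L
      for (u in adj[[v + 1L]]) {
        if (u %in% W) visit(u)
      }
      color[[key]] <- 2L
    }
    for (v in W) { if (cyc) break; visit(v) }
    if (cyc) next
    # mirror-of-s / both-orientation exclusions
    if (any((W %/% 2) == (s %/% 2) & W != s)) next
    if (anyDuplicated(W %/% 2)) next
    if (is.null(best) || length(W) < length(best$W)) best <- list(t = t, W = W)
  }
  best
}

o_pop_superbubbles <- function(tuples, abund, edges) {
  n <- length(tuples)
  alive <- rep(TRUE, n)
  repeat {
    adj <- o_adj(edges, n, alive)
    popped <- FALSE
    for (v in 0:(2 * n - 1)) {
      if (!alive[v %/% 2 + 1]) next
      # minimal superbubbles with a non-empty interior branch at the source
      if (length(adj[[v + 1L]]) < 2) next
      av <- which(rep(alive, each = 2)) - 1L
      bub <- o_find_superbubble(adj, v, av)
      if (is.null(bub)) next
      paths <- o_paths(adj, v, bub$t, bub$W)
      sc <- lapply(paths, function(p) {
        med <- o_lower_median(abund[p %/% 2 + 1])
        key <- paste(unlist(lapply(p, function(x) o_oriented_seq(tuples, x))),
                     collapse = ",")
        list(med = med, key = key)
      })
      meds <- vapply(sc, function(x) x$med, numeric(1))
      keys <- vapply(sc, function(x) x$key, character(1))
      best_i <- order(-meds, xtfrm(keys), method = "radix")[1]
      keep_nodes <- unique(paths[[best_i]] %/% 2)
      interior <- setdiff(bub$W, c(v, bub$t))
      kill <- setdiff(unique(interior %/% 2), keep_nodes)
      if (length(kill) == 0L) next
      alive[kill + 1L] <- FALSE
      popped <- TRUE
      break
    }
    if (!popped) break
  }
  alive
}

# random small test graphs: tuples from short random walks with shared
# segments, yielding bubbles/tips/cycles
o_random_graph <- function(seed, kp = 3L, max_nodes = 12L) {
  set.seed(seed)
  alpha <- 1:6
  backbone <- sample(alpha, sample(5:9, 1), replace = TRUE)
  seqs <- list(backbone)
  if (runif(1) < 0.7) { # variant path: mutate interior -> bubble
    v <- backbone
    pos <- sample(seq(2, max(2, length(v) - 1)), 1)
    v[pos] <- sample(alpha, 1)
    seqs <- c(seqs, list(v))
  }
  if (runif(1) < 0.4) { # tip
    cut <- sample(seq_along(backbone), 1)
    tipseq <- c(backbone[seq_len(cut)], sample(alpha, 2, replace = TRUE))
    seqs <- c(seqs, list(tipseq))
  }
  circ <- vapply(seqs, function(s) runif(1) < 0.2 && length(s) >= kp + 1,
                 logical(1))
  tab <- o_count_kminmers(seqs, circ, kp)
  if (length(tab) > max_nodes) tab <- tab[seq_len(max_nodes)]
  tuples <- lapply(names(tab), function(k) {
    as.integer(strsplit(k, ",", fixed = TRUE)[[1]])
  })
  list(tuples = tuples, abund = as.integer(unname(tab)) +
         sample(0:5, length(tab), replace = TRUE), kp = kp)
}
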