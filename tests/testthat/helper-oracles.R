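# Independent oracles used across the suite. These deliberately avoid the
# package's own graph code paths (igraph, subset hashing): components use
# union-find, cliques use exhaustive subset enumeration, communities use
# pairwise clique-intersection plus breadth-first search.

random_adjacency <- function(n, p, seed) {
  set.seed(seed)
  adj <- matrix(FALSE, n, n)
  ut <- upper.tri(adj)
  adj[ut] <- stats::runif(sum(ut)) < p
  adj | t(adj)
}

# wrap a bare adjacency matrix as a thresholded PEN
as_pen_graph <- function(adj, cutoff = -1, channel = "total") {
  n <- nrow(adj)
  res <- residue_table(chain = "A", seq_number = seq_len(n),
                       insertion_code = NA_character_, name = rep("UNK", n))
  dimnames(adj) <- list(res$label, res$label)
  structure(list(residues = res, adjacency = adj, cutoff = cutoff,
                 channel = channel),
            class = "pen_graph")
}

uf_components <- function(adj) {
  n <- nrow(adj)
  parent <- seq_len(n)
  find <- function(x) {
    while (parent[x] != x) x <- parent[x]
    x
  }
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (adj[i, j]) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(n), find, 1L)
  comps <- unname(split(seq_len(n), roots))
  comps <- lapply(comps, sort)
  comps[order(vapply(comps, min, 1L))]
}

bf_k_cliques <- function(adj, k) {
  n <- nrow(adj)
  if (n < k) return(list())
  combos <- utils::combn(n, k)
  pr <- utils::combn(k, 2)
  keep <- vapply(seq_len(ncol(combos)), function(cix) {
    v <- combos[, cix]
    all(adj[cbind(v[pr[1, ]], v[pr[2, ]])])
  }, TRUE)
  lapply(which(keep), function(cix) combos[, cix])
}

# communities as node sets (canonical: each set sorted; sets sorted by
# size descending then smallest member, mirroring the documented order)
bf_communities <- function(adj, k) {
  cl <- bf_k_cliques(adj, k)
  nc <- length(cl)
  if (!nc) return(list())
  cadj <- matrix(FALSE, nc, nc)
  for (a in seq_len(nc)) {
    for (b in seq_len(nc)) {
      if (a < b && length(intersect(cl[[a]], cl[[b]])) >= k - 1) {
        cadj[a, b] <- cadj[b, a] <- TRUE
      }
    }
  }
  visited <- rep(FALSE, nc)
  comms <- list()
  for (s in seq_len(nc)) {
    if (visited[s]) next
    queue <- s; visited[s] <- TRUE; members <- integer(0)
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      members <- c(members, cur)
      nb <- which(cadj[cur, ] & !visited)
      visited[nb] <- TRUE
      queue <- c(queue, nb)
    }
    comms[[length(comms) + 1]] <- sort(unique(unlist(cl[members])))
  }
  sizes <- vapply(comms, length, 1L)
  mins <- vapply(comms, min, 1L)
  comms[order(-sizes, mins)]
}
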