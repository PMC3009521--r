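#' Clusters: connected components of a thresholded PEN
#'
#' Clusters are the connected components of PEN_e. Every residue belongs to
#' exactly one cluster; isolated residues form singleton clusters. Output
#' order is deterministic: clusters are sorted by their smallest member
#' index, members ascending within each cluster.
#'
#' @param g a `pen_graph`.
#' @return a list of integer vectors of residue indices.
#' @export
connected_components <- function(g) {
  stopifnot(inherits(g, "pen_graph"))
  memb <- igraph::components(.as_igraph(g))$membership
  comps <- unname(split(seq_along(memb), memb))
  comps <- lapply(comps, sort)
  comps[order(vapply(comps, min, 1L))]
}

#' Size of the largest connected component
#'
#' The LCC size traced as a function of the cutoff e is the transition
#' profile of the network: near e = 0 nearly everything is connected, and
#' as e grows more negative the network breaks apart.
#'
#' @param g a `pen_graph`.
#' @return node count of the largest component (0 for an empty residue set).
#' @export
lcc_size <- function(g) {
  comps <- connected_components(g)
  if (!length(comps)) return(0L)
  max(vapply(comps, length, 1L))
}

#' Count clusters of at least a minimum size
#'
#' Population profiles count a connected component only when it has at
#' least `min_size` residues (default 3), so isolated residues and bare
#' pairs are ignored.
#'
#' @param g a `pen_graph`.
#' @param min_size smallest component size that counts (>= 1).
#' @return number of qualifying components.
#' @export
count_clusters <- function(g, min_size = 3) {
  stopifnot(min_size >= 1)
  sum(vapply(connected_components(g), length, 1L) >= min_size)
}

#' Hubs: highly connected residues
#'
#' A residue is a hub when its degree in PEN_e is at least
#' `degree_threshold` (default 4, the convention of packing-based protein
#' structure network studies).
#'
#' @param g a `pen_graph`.
#' @param degree_threshold minimum degree (>= 1).
#' @return sorted integer vector of hub residue indices.
#' @export
hubs <- function(g, degree_threshold = 4) {
  stopifnot(inherits(g, "pen_graph"), degree_threshold >= 1)
  which(unname(rowSums(g$adjacency)) >= degree_threshold)
}

#' Enumerate all k-cliques
#'
#' A k-clique is a set of k residues that are pairwise adjacent (the
#' induced subgraph has all k(k-1)/2 edges). Every complete k-subset is
#' enumerated, not only maximal cliques, since clique-percolation
#' communities are built from all of them. Output is deterministic: each
#' clique's members ascending, cliques in lexicographic order.
#'
#' @param g a `pen_graph`.
#' @param k clique size (>= 2).
#' @return a list of sorted integer vectors, each of length k.
#' @export
enumerate_k_cliques <- function(g, k) {
  stopifnot(inherits(g, "pen_graph"))
  if (k < 2) abort("k must be at least 2")
  cl <- igraph::cliques(.as_igraph(g), min = k, max = k)
  cl <- lapply(cl, function(v) sort(as.integer(v)))
  if (!length(cl)) return(cl)
  key <- vapply(cl, function(v) paste(sprintf("%06d", v), collapse = ""), "")
  cl[order(key)]
}

#' Clique-percolation communities
#'
#' Two k-cliques are adjacent when they share k-1 residues; a community is
#' a maximal set of k-cliques chained together by this adjacency (the
#' clique-percolation construction). A community's size is the number of
#' distinct residues in the union of its member cliques. Communities are
#' returned sorted by size descending, then by smallest member residue.
#'
#' @param g a `pen_graph`.
#' @param k clique size (>= 3).
#' @return a list of objects with elements `cliques` (list of integer
#'   vectors) and `nodes` (sorted integer union).
#' @export
clique_communities <- function(g, k) {
  if (k < 3) abort("k must be at least 3 for clique percolation")
  cl <- enumerate_k_cliques(g, k)
  if (!length(cl)) return(list())
  # cliques sharing any (k-1)-subset are adjacent; hash the subsets
  nc <- length(cl)
  sub_keys <- lapply(cl, function(v) {
    vapply(seq_len(k), function(drop) {
      paste(sprintf("%06d", v[-drop]), collapse = "")
    }, "")
  })
  edges <- integer(0)
  seen <- new.env(hash = TRUE, parent = emptyenv())
  for (ci in seq_len(nc)) {
    for (key in sub_keys[[ci]]) {
      prev <- seen[[key]]
      if (is.null(prev)) {
        seen[[key]] <- ci
      } else {
        # chain through the first clique that carries this (k-1)-subset
        edges <- c(edges, prev, ci)
      }
    }
  }
  memb <- if (length(edges)) {
    cg <- igraph::make_graph(edges, n = nc, directed = FALSE)
    igraph::components(cg)$membership
  } else {
    seq_len(nc)
  }
  comms <- lapply(unname(split(seq_len(nc), memb)), function(ix) {
    nodes <- sort(unique(unlist(cl[ix])))
    list(cliques = cl[ix], nodes = nodes)
  })
  sizes <- vapply(comms, function(co) length(co$nodes), 1L)
  mins <- vapply(comms, function(co) min(co$nodes), 1L)
  comms[order(-sizes, mins)]
}

#' Size of the largest clique-percolation community
#'
#' @param g a `pen_graph`.
#' @param k clique size (>= 3).
#' @return residue count of the largest community; 0 when no k-clique exists.
#' @export
largest_community_size <- function(g, k) {
  comms <- clique_communities(g, k)
  if (!length(comms)) return(0L)
  length(comms[[1]]$nodes)
}
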