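#' Build a protein energy network
#'
#' A PEN is a complete weighted graph over a protein's residues whose edge
#' weights are the ensemble-averaged pairwise interaction energies of an
#' [energy_matrix()], carried in up to three channels: `total`, `lj`
#' (Lennard-Jones only) and `coulomb` (electrostatics only). Sign
#' convention, as used throughout the package: "low energy" means small
#' negative magnitude (e.g. -5 kJ/mol, weak attraction), "high energy"
#' means large negative magnitude (e.g. -25 kJ/mol, strong attraction).
#' Positive (repulsive) weights are retained unchanged; they simply never
#' satisfy a negative cutoff.
#'
#' @param m an [energy_matrix()].
#' @return an object of class `pen` wrapping the matrix unchanged.
#' @export
build_pen <- function(m) {
  stopifnot(inherits(m, "energy_matrix"))
  structure(
    list(residues = m$residues, total = m$total, lj = m$lj,
         coulomb = m$coulomb, excluded = m$excluded),
    class = "pen"
  )
}

#' @export
print.pen <- function(x, ...) {
  cat(sprintf("<pen> complete weighted graph on %d residues, channels: %s\n",
              nrow(x$residues), paste(channels(x), collapse = ", ")))
  invisible(x)
}

#' Threshold a PEN at an energy cutoff
#'
#' Converts the weighted PEN into an unweighted graph PEN_e: an edge joins
#' residues i and j exactly when the chosen channel's energy satisfies
#' E_ij <= e (inclusive comparison, taken literally with no tolerance
#' band) and the pair is not excluded by the energy-computation policy.
#' All residues are retained as nodes, including isolated ones. More
#' negative cutoffs keep only stronger attractions, so the edge sets nest:
#' e2 < e1 implies edges(e2) is a subset of edges(e1).
#'
#' @param p a `pen` (or an [energy_matrix()], converted on the fly).
#' @param e energy cutoff, kJ/mol.
#' @param channel `"total"`, `"lj"` or `"coulomb"`; must be present.
#' @return an object of class `pen_graph` with the residue table, the
#'   logical adjacency matrix, `cutoff` and `channel`.
#' @export
threshold_pen <- function(p, e, channel = c("total", "lj", "coulomb")) {
  channel <- match.arg(channel)
  if (inherits(p, "energy_matrix")) p <- build_pen(p)
  stopifnot(inherits(p, "pen"))
  w <- p[[channel]]
  if (is.null(w)) {
    abort(sprintf("channel '%s' is not available in this PEN", channel))
  }
  adj <- (w <= e) & !p$excluded
  diag(adj) <- FALSE
  dimnames(adj) <- list(p$residues$label, p$residues$label)
  structure(
    list(residues = p$residues, adjacency = adj, cutoff = e, channel = channel),
    class = "pen_graph"
  )
}

#' Number of edges in a thresholded PEN
#' @param g a `pen_graph`.
#' @return count of unordered adjacent residue pairs.
#' @export
edge_count <- function(g) {
  stopifnot(inherits(g, "pen_graph"))
  sum(g$adjacency[upper.tri(g$adjacency)])
}

#' @export
print.pen_graph <- function(x, ...) {
  cat(sprintf("<pen_graph> PEN_%g (%s channel): %d nodes, %d edges\n",
              x$cutoff, x$channel, nrow(x$residues), edge_count(x)))
  invisible(x)
}

# igraph view of a thresholded PEN (nodes keep residue attributes)
.as_igraph <- function(g) {
  ig <- igraph::graph_from_adjacency_matrix(g$adjacency, mode = "undirected")
  igraph::V(ig)$chain <- g$residues$chain
  igraph::V(ig)$seq_number <- g$residues$seq_number
  igraph::V(ig)$residue <- g$residues$name
  ig
}
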