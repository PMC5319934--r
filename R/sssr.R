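## Ring perception on the heavy-atom graph.
##
## MQN ring-size and ring-fusion counts need a smallest set of smallest
## rings (SSSR). Candidate cycles are generated as the shortest cycle
## through each non-bridge edge; a size-ordered greedy pass then keeps a set
## of cycles that is linearly independent over GF(2) on the edge space,
## stopping at the circuit rank E - V + components.

mol_graph <- function(n, bonds) {
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(bonds))
    g <- igraph::add_edges(g, as.vector(t(bonds[, c("from", "to"), drop = FALSE])))
  g
}

## logical vector over bond rows: TRUE if the bond lies on a cycle
cyclic_bonds <- function(n, bonds) {
  if (nrow(bonds) == 0) return(logical(0))
  g <- mol_graph(n, bonds)
  br <- as.integer(igraph::bridges(g))
  out <- rep(TRUE, nrow(bonds))
  out[br] <- FALSE
  out
}

## edge-row indices of a ring given as an ordered vertex cycle
ring_edge_indices <- function(ring, bonds) {
  nxt <- c(ring[-1], ring[1])
  key <- paste(pmin(bonds[, "from"], bonds[, "to"]),
               pmax(bonds[, "from"], bonds[, "to"]))
  match(paste(pmin(ring, nxt), pmax(ring, nxt)), key)
}

## list of vertex cycles forming an SSSR
sssr_rings <- function(n, bonds) {
  m <- nrow(bonds)
  if (m == 0) return(list())
  g <- mol_graph(n, bonds)
  rank <- m - n + igraph::count_components(g)
  if (rank <= 0) return(list())

  cyc <- which(cyclic_bonds(n, bonds))
  cand <- list()
  for (e in cyc) {
    u <- bonds[e, "from"]; v <- bonds[e, "to"]
    g2 <- igraph::delete_edges(g, e)
    sp <- suppressWarnings(igraph::shortest_paths(g2, u, v)$vpath[[1]])
    if (length(sp) >= 3) cand[[length(cand) + 1L]] <- as.integer(sp)
  }
  if (!length(cand)) return(list())
  cand <- cand[!duplicated(lapply(cand, function(r) sort(ring_edge_indices(r, bonds))))]
  cand <- cand[order(vapply(cand, length, 0L))]

  basis <- matrix(FALSE, nrow = 0, ncol = m)   # reduced GF(2) basis
  pivots <- integer(0)
  chosen <- list()
  for (r in cand) {
    vec <- logical(m)
    vec[ring_edge_indices(r, bonds)] <- TRUE
    red <- vec
    for (b in seq_len(nrow(basis)))
      if (red[pivots[b]]) red <- xor(red, basis[b, ])
    if (any(red)) {
      basis <- rbind(basis, red)
      pivots <- c(pivots, which(red)[1])
      chosen[[length(chosen) + 1L]] <- r
      if (length(chosen) == rank) break
    }
  }
  chosen
}
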