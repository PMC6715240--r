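# Independent oracles used by the tests: exhaustive enumeration of grid
# placements, permutations, set partitions for modularity maximization, and
# the catalogue of small connected graphs.

# All permutations of 1..n (n small).
permutations_of <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- permutations_of(n - 1L)
  out <- matrix(0L, 0L, n)
  for (k in seq_len(n)) {
    rest <- seq_len(n)[-k]
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  out
}

# Exact minimum layout cost over all injective placements of the entities
# of w on a width x height board, by enumeration (n <= 4 expected).
brute_force_min_cost <- function(w, width, height) {
  n <- nrow(w)
  pts <- as.matrix(expand.grid(x = 0:(width - 1L), y = 0:(height - 1L)))
  npts <- nrow(pts)
  perms <- permutations_of(n)
  pair <- utils::combn(n, 2L)
  best <- Inf
  subsets <- utils::combn(npts, n)
  for (s in seq_len(ncol(subsets))) {
    sel <- pts[subsets[, s], , drop = FALSE]
    d <- abs(outer(sel[, 1L], sel[, 1L], "-")) +
      abs(outer(sel[, 2L], sel[, 2L], "-"))
    for (p in seq_len(nrow(perms))) {
      pm <- perms[p, ]
      cost <- sum(w[cbind(pm[pair[1L, ]], pm[pair[2L, ]])] *
                    d[cbind(pair[1L, ], pair[2L, ])])
      if (cost < best) best <- cost
    }
  }
  best
}

# All set partitions of 1..n (restricted growth strings); n small.
set_partitions_of <- function(n) {
  out <- list()
  recur <- function(assign, kmax) {
    i <- length(assign) + 1L
    if (i > n) {
      out[[length(out) + 1L]] <<- assign
      return(invisible(NULL))
    }
    for (b in seq_len(kmax + 1L)) recur(c(assign, b), max(kmax, b))
  }
  recur(integer(), 0L)
  out
}

# Exhaustive modularity maximization: the best membership vector over all
# set partitions of the graph's vertices.
exhaustive_best_partition <- function(g) {
  n <- igraph::gorder(g)
  parts <- set_partitions_of(n)
  q <- vapply(parts, function(memb) igraph::modularity(g, memb), numeric(1))
  parts[[which.max(q)]]
}

# Non-isomorphic connected graphs on 2-4 nodes, as edge matrices over
# vertices "a".."d".
small_connected_graphs <- function() {
  v <- c("a", "b", "c", "d")
  mk <- function(...) {
    e <- matrix(v[c(...)], ncol = 2L, byrow = TRUE)
    igraph::graph_from_edgelist(e, directed = FALSE)
  }
  list(
    k2 = mk(1, 2),
    p3 = mk(1, 2, 2, 3),
    k3 = mk(1, 2, 2, 3, 1, 3),
    p4 = mk(1, 2, 2, 3, 3, 4),
    star4 = mk(1, 2, 1, 3, 1, 4),
    paw = mk(1, 2, 2, 3, 1, 3, 3, 4),
    c4 = mk(1, 2, 2, 3, 3, 4, 1, 4),
    diamond = mk(1, 2, 2, 3, 1, 3, 1, 4, 3, 4),
    k4 = mk(1, 2, 1, 3, 1, 4, 2, 3, 2, 4, 3, 4)
  )
}

# Single-module total assignment over a network's nodes.
one_module_assignment <- function(network, id = "M1") {
  ids <- igraph::V(network)$name
  module_assignment(stats::setNames(rep(id, length(ids)), ids))
}

# Adjusted Rand index between two labelings (independent of the package).
adjusted_rand <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}
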