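# Layout-quality metrics: connectivity F-measure (precision/recall of
# neighbourhood circles), relative edge length, and edge-edge / node-edge
# crossing ratios.

layout_pos_for <- function(layout, network) {
  ids <- igraph::V(network)$name
  missing <- setdiff(ids, rownames(layout$pos))
  if (length(missing) > 0L)
    stop("layout does not cover node(s): ",
         paste(utils::head(missing, 5L), collapse = ", "))
  layout$pos[ids, , drop = FALSE]
}

#' Precision and recall of a node's neighbourhood circle
#'
#' For node `i` and radius `r`, consider the circle of Euclidean radius
#' `r` centred at `i`'s position. Precision is the fraction of the other
#' nodes inside the circle that are network neighbours of `i`; recall is
#' the fraction of all of `i`'s neighbours that fall inside the circle.
#'
#' @param layout a [grid_layout()] covering the network's nodes.
#' @param network undirected `igraph` graph with vertex names.
#' @param i a node id with degree at least one.
#' @param r circle radius (Euclidean, in grid units); membership is
#'   distance `<= r`.
#' @return Named numeric vector `c(P = ..., R = ...)`; `P` is `NaN` when
#'   the circle contains no other node.
#' @export
precision_recall <- function(layout, network, i, r) {
  pos <- layout_pos_for(layout, network)
  if (!(i %in% rownames(pos)))
    stop("unknown node: ", i)
  deg <- unname(igraph::degree(network, i))
  if (deg == 0L)
    stop("precision/recall undefined for degree-0 node: ", i)
  d <- sqrt((pos[, 1L] - pos[i, 1L])^2 + (pos[, 2L] - pos[i, 2L])^2)
  inside <- d <= r & rownames(pos) != i
  nb <- igraph::V(network)$name %in%
    igraph::neighbors(network, i)$name
  names(nb) <- igraph::V(network)$name
  nb <- nb[rownames(pos)]
  c(P = sum(inside & nb) / sum(inside), R = sum(inside & nb) / deg)
}

#' F-measure from precision and recall
#'
#' Weighted harmonic mean `1 / (alpha / P + (1 - alpha) / R)`; zero when
#' either precision or recall is zero (or undefined).
#'
#' @param P,R precision and recall in `[0, 1]`.
#' @param alpha weight on precision, in `(0, 1)`; 0.5 balances the two.
#' @return A number in `[0, 1]`.
#' @export
f_measure <- function(P, R, alpha = 0.5) {
  if (!is.finite(P) || !is.finite(R) || P <= 0 || R <= 0)
    return(0)
  1 / (alpha / P + (1 - alpha) / R)
}

#' Connectivity F-measure of a layout
#'
#' For each node `i` with degree at least one, the circle radius `r_i` is
#' chosen to maximize the F-measure of [precision_recall()]; since the
#' F-measure is piecewise constant in `r`, only the distinct Euclidean
#' distances from `i` to the other nodes need to be scanned, making the
#' maximization exact. The connectivity F-measure is the mean of the
#' per-node optima over all eligible (degree >= 1) nodes; isolated nodes
#' are excluded because their recall is undefined. Values near 1 mean
#' each node's neighbours — and little else — sit close to it.
#'
#' @inheritParams precision_recall
#' @param alpha precision weight in `(0, 1)` (default 0.5).
#' @return A number in `[0, 1]`, invariant under translation, rotation
#'   and reflection of the layout.
#' @export
connectivity_f_measure <- function(layout, network, alpha = 0.5) {
  if (igraph::gsize(network) < 1L)
    stop("connectivity F-measure needs at least one edge")
  pos <- layout_pos_for(layout, network)
  ids <- rownames(pos)
  adj <- igraph::as_adjacency_matrix(network, sparse = FALSE)
  adj <- adj[ids, ids] > 0
  deg <- rowSums(adj)
  eligible <- which(deg > 0)
  f_i <- vapply(eligible, function(ii) {
    d <- sqrt((pos[, 1L] - pos[ii, 1L])^2 + (pos[, 2L] - pos[ii, 2L])^2)
    d <- d[-ii]
    is_nb <- adj[ii, -ii]
    o <- order(d)
    d <- d[o]
    is_nb <- is_nb[o]
    n_in <- seq_along(d)          # nodes inside at radius d[k]
    a_in <- cumsum(is_nb)         # neighbours inside at radius d[k]
    # radii between tied distances are equivalent; keep the last of each tie
    keep <- c(d[-length(d)] < d[-1L], TRUE)
    P <- a_in[keep] / n_in[keep]
    R <- a_in[keep] / deg[ii]
    f <- ifelse(P > 0 & R > 0, 1 / (alpha / P + (1 - alpha) / R), 0)
    max(f)
  }, numeric(1))
  mean(f_i)
}

#' Relative edge length of a layout
#'
#' Total Manhattan length of all edges divided by the product of the
#' layout area and the edge count. The area is the node bounding box in
#' grid cells, `(x_max - x_min + 1) * (y_max - y_min + 1)`. Smaller values
#' indicate a more compact drawing.
#'
#' @inheritParams precision_recall
#' @return A non-negative number, invariant under translation.
#' @export
relative_edge_length <- function(layout, network) {
  m <- igraph::gsize(network)
  if (m < 1L)
    stop("relative edge length needs at least one edge")
  pos <- layout_pos_for(layout, network)
  el <- igraph::as_edgelist(network)
  len <- abs(pos[el[, 1L], 1L] - pos[el[, 2L], 1L]) +
    abs(pos[el[, 1L], 2L] - pos[el[, 2L], 2L])
  area <- (diff(range(pos[, 1L])) + 1) * (diff(range(pos[, 2L])) + 1)
  sum(len) / (area * m)
}

# Vectorized segment-pair crossing test. Segments are closed; a pair
# counts as crossing when the segments share a point that is not a common
# node endpoint (proper crossings, endpoint touches and collinear overlap
# all count; overlap counts once).
cross_prod2 <- function(ox, oy, ax, ay, bx, by) {
  (ax - ox) * (by - oy) - (ay - oy) * (bx - ox)
}

on_segment <- function(px, py, ax, ay, bx, by) {
  px >= pmin(ax, bx) & px <= pmax(ax, bx) &
    py >= pmin(ay, by) & py <= pmax(ay, by)
}

segments_cross <- function(ax, ay, bx, by, cx, cy, dx, dy) {
  o1 <- sign(cross_prod2(ax, ay, bx, by, cx, cy))
  o2 <- sign(cross_prod2(ax, ay, bx, by, dx, dy))
  o3 <- sign(cross_prod2(cx, cy, dx, dy, ax, ay))
  o4 <- sign(cross_prod2(cx, cy, dx, dy, bx, by))
  proper <- (o1 * o2 < 0) & (o3 * o4 < 0)
  touch <- (o1 == 0 & on_segment(cx, cy, ax, ay, bx, by)) |
    (o2 == 0 & on_segment(dx, dy, ax, ay, bx, by)) |
    (o3 == 0 & on_segment(ax, ay, cx, cy, dx, dy)) |
    (o4 == 0 & on_segment(bx, by, cx, cy, dx, dy))
  proper | touch
}

#' Edge-edge crossing ratio
#'
#' Edges are drawn as straight segments between node positions. A pair of
#' edges counts as crossing when the segments intersect at a point that is
#' not a shared node endpoint (edges sharing a node never count; collinear
#' overlap counts once). The ratio is the number of crossing pairs divided
#' by the total number of edge pairs, `choose(m, 2)`.
#'
#' @inheritParams precision_recall
#' @return A number in `[0, 1]`.
#' @export
edge_edge_crossing_ratio <- function(layout, network) {
  m <- igraph::gsize(network)
  if (m < 2L)
    stop("edge-edge crossing ratio needs at least two edges")
  pos <- layout_pos_for(layout, network)
  idx <- stats::setNames(seq_len(nrow(pos)), rownames(pos))
  el <- igraph::as_edgelist(network)
  e1 <- idx[el[, 1L]]
  e2 <- idx[el[, 2L]]
  pr <- utils::combn(m, 2L)
  a <- e1[pr[1L, ]]; b <- e2[pr[1L, ]]
  c_ <- e1[pr[2L, ]]; d_ <- e2[pr[2L, ]]
  shared <- a == c_ | a == d_ | b == c_ | b == d_
  crossing <- segments_cross(pos[a, 1L], pos[a, 2L], pos[b, 1L], pos[b, 2L],
                             pos[c_, 1L], pos[c_, 2L],
                             pos[d_, 1L], pos[d_, 2L])
  sum(crossing & !shared) / ncol(pr)
}

#' Node-edge crossing ratio
#'
#' A (node, edge) pair counts as a crossing when the node is not an
#' endpoint of the edge and the node's position lies within distance
#' `epsilon` of the closed segment (half a grid cell by default, matching
#' non-overlapping unit-grid node glyphs). The ratio divides the count by
#' the number of eligible pairs, `n * m - 2 * m`.
#'
#' @inheritParams precision_recall
#' @param epsilon node-to-segment distance threshold in grid units.
#' @return A number in `[0, 1]`.
#' @export
node_edge_crossing_ratio <- function(layout, network, epsilon = 0.5) {
  n <- igraph::gorder(network)
  m <- igraph::gsize(network)
  if (n < 1L || m < 1L)
    stop("node-edge crossing ratio needs at least one node and one edge")
  pos <- layout_pos_for(layout, network)
  idx <- stats::setNames(seq_len(nrow(pos)), rownames(pos))
  el <- igraph::as_edgelist(network)
  a <- idx[el[, 1L]]
  b <- idx[el[, 2L]]
  # all (node, edge) combinations
  ni <- rep(seq_len(n), times = m)
  ei <- rep(seq_len(m), each = n)
  ax <- pos[a[ei], 1L]; ay <- pos[a[ei], 2L]
  bx <- pos[b[ei], 1L]; by <- pos[b[ei], 2L]
  px <- pos[ni, 1L]; py <- pos[ni, 2L]
  vx <- bx - ax; vy <- by - ay
  len2 <- vx^2 + vy^2
  t <- ifelse(len2 > 0, ((px - ax) * vx + (py - ay) * vy) / len2, 0)
  t <- pmin(pmax(t, 0), 1)
  dist <- sqrt((px - (ax + t * vx))^2 + (py - (ay + t * vy))^2)
  endpoint <- ni == a[ei] | ni == b[ei]
  eligible <- n * m - 2 * m
  if (eligible <= 0)
    return(0)  # no non-endpoint pairs to cross
  sum(dist <= epsilon & !endpoint) / eligible
}

#' All four layout-quality metrics at once
#'
#' @inheritParams precision_recall
#' @param alpha precision weight of the connectivity F-measure.
#' @param epsilon node-edge proximity threshold in grid units.
#' @return A one-row data frame with columns `connectivity_f`,
#'   `relative_edge_length`, `edge_edge_ratio`, `node_edge_ratio`,
#'   `alpha`, `epsilon`.
#' @export
layout_metrics <- function(layout, network, alpha = 0.5, epsilon = 0.5) {
  data.frame(
    connectivity_f = connectivity_f_measure(layout, network, alpha),
    relative_edge_length = relative_edge_length(layout, network),
    edge_edge_ratio = if (igraph::gsize(network) >= 2L)
      edge_edge_crossing_ratio(layout, network) else NA_real_,
    node_edge_ratio = node_edge_crossing_ratio(layout, network, epsilon),
    alpha = alpha,
    epsilon = epsilon
  )
}
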