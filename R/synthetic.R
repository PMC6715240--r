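# Synthetic inputs: a planted-partition generator for benchmarks and a
# small fixed 24-node illustration network with one predefined module.

#' Generate a planted-partition (modular) network
#'
#' Random graph with known module structure: every intra-module node pair
#' is an edge with probability `p_in`, every inter-module pair with
#' probability `p_out`. With `p_in` well above `p_out` the planted modules
#' are densely connected internally and sparsely connected to the rest —
#' the modular architecture typical of biological networks.
#'
#' @param sizes integer vector of module sizes (one entry per planted
#'   module); must be non-empty.
#' @param p_in,p_out edge probabilities in `[0, 1]`.
#' @param seed optional integer seed; the same seed reproduces the same
#'   edge set exactly.
#' @return A list with elements `network` (undirected simple `igraph`
#'   graph, node ids `"1"`, `"2"`, ...) and `assignment` (the planted
#'   [module_assignment()] with module ids `"M1"`, `"M2"`, ..., none
#'   flagged predefined).
#' @examples
#' net <- generate_modular_network(c(5, 5), p_in = 1, p_out = 0, seed = 1)
#' igraph::gsize(net$network) # two disjoint 5-cliques: 20 edges
#' @export
generate_modular_network <- function(sizes, p_in, p_out, seed = NULL) {
  if (length(sizes) == 0L)
    stop("'sizes' must not be empty")
  sizes <- as.integer(sizes)
  if (any(is.na(sizes)) || any(sizes < 1L))
    stop("'sizes' must be positive integers")
  if (p_in < 0 || p_in > 1 || p_out < 0 || p_out > 1)
    stop("'p_in' and 'p_out' must be probabilities")
  if (!is.null(seed))
    set.seed(seed)
  n <- sum(sizes)
  ids <- as.character(seq_len(n))
  mod <- rep(paste0("M", seq_along(sizes)), sizes)
  pair <- utils::combn(n, 2L)
  same <- mod[pair[1L, ]] == mod[pair[2L, ]]
  p <- ifelse(same, p_in, p_out)
  keep <- stats::runif(ncol(pair)) < p
  edges <- data.frame(from = ids[pair[1L, keep]], to = ids[pair[2L, keep]],
                      stringsAsFactors = FALSE)
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = ids)
  list(network = g,
       assignment = module_assignment(stats::setNames(mod, ids)))
}

#' A fixed 24-node illustration network
#'
#' Small fixture exercising every pipeline feature: 24 nodes, one
#' predefined module `M1 = {19, 20, 21, 22, 24}` whose member 24 is
#' isolated (predefined modules need not be topologically coherent), three
#' densely connected residual groups (`1-6`, `7-12`, and `13-18` with
#' `23`), a few bridge edges between the groups, and one edge from the
#' residual part into the predefined module.
#'
#' @return A list with elements `network` (undirected simple `igraph`
#'   graph) and `predefined` (partial [module_assignment()] covering the
#'   five predefined nodes).
#' @export
example_network_24 <- function() {
  edges <- rbind(
    # group 1: nodes 1-6, dense
    c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4), c(3, 6),
    c(4, 5), c(5, 6), c(1, 6), c(2, 5),
    # group 2: nodes 7-12, dense
    c(7, 8), c(7, 9), c(8, 9), c(8, 10), c(9, 10), c(10, 11), c(10, 12),
    c(11, 12), c(7, 11), c(9, 12),
    # group 3: nodes 13-18 and 23, dense
    c(13, 14), c(13, 15), c(14, 15), c(14, 16), c(15, 16), c(16, 17),
    c(17, 18), c(16, 18), c(13, 18), c(17, 23), c(18, 23), c(15, 23),
    # bridges between residual groups
    c(6, 7), c(9, 13),
    # predefined module internals (node 24 stays isolated)
    c(19, 20), c(19, 22), c(20, 22), c(21, 22),
    # residual-to-predefined edge
    c(2, 21)
  )
  ids <- as.character(1:24)
  g <- igraph::graph_from_data_frame(
    data.frame(from = as.character(edges[, 1L]),
               to = as.character(edges[, 2L]), stringsAsFactors = FALSE),
    directed = FALSE, vertices = ids)
  pre_nodes <- c("19", "20", "21", "22", "24")
  list(network = g,
       predefined = module_assignment(
         stats::setNames(rep("M1", length(pre_nodes)), pre_nodes),
         predefined = "M1"))
}
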