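# Small fixture builders shared across test files.

graph_from_pairs <- function(...) {
  e <- matrix(as.character(c(...)), ncol = 2L, byrow = TRUE)
  igraph::graph_from_edgelist(e, directed = FALSE)
}

path_graph_abc <- function() graph_from_pairs("a", "b", "b", "c")

# Two 4-cliques joined by one bridge edge (1-4 and 5-8, bridge 4-5).
two_cliques_bridge <- function() {
  cl <- function(v) t(utils::combn(v, 2L))
  e <- rbind(cl(as.character(1:4)), cl(as.character(5:8)), c("4", "5"))
  igraph::graph_from_edgelist(e, directed = FALSE)
}

write_lines_tmp <- function(lines, ext = ".txt") {
  path <- withr::local_tempfile(fileext = ext,
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# A two-planted-module network joined by exactly one bridge edge.
bridged_two_module_network <- function(size = 10L, p_in = 0.6, seed = 1L) {
  net <- generate_modular_network(c(size, size), p_in = p_in, p_out = 0,
                                  seed = seed)
  bridge <- c("1", as.character(size + 1L))
  g <- igraph::add_edges(net$network, bridge)
  list(network = igraph::simplify(g), assignment = net$assignment,
       bridge = bridge)
}
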