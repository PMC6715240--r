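# Stage 1: network preprocessing. Predefined-module nodes are filtered out
# and the residual subgraph is partitioned into pseudo modules by multilevel
# modularity maximization.

#' Partition residual nodes into pseudo modules
#'
#' Nodes covered by the (possibly empty) predefined assignment are filtered
#' out first; the subgraph induced by the remaining (residual) nodes is
#' then clustered with the multilevel modularity-maximization algorithm
#' (Louvain, via [igraph::cluster_louvain()]). Edges between residual and
#' predefined nodes do not influence the clustering, mirroring the
#' filter-then-cluster order of the pipeline. Predefined module contents
#' are preserved verbatim; every residual node lands in exactly one pseudo
#' module (named `P1`, `P2`, ...). Residual nodes of degree zero in the
#' residual subgraph end up as singleton pseudo modules.
#'
#' @param network undirected simple `igraph` graph with vertex names.
#' @param predefined a partial [module_assignment()] of predefined modules
#'   (default: none).
#' @param seed optional integer seed making the clustering deterministic.
#' @return A total [module_assignment()] over all network nodes.
#' @export
partition_residual_nodes <- function(network,
                                     predefined = module_assignment(),
                                     seed = NULL) {
  stopifnot(inherits(predefined, "module_assignment"))
  ids <- igraph::V(network)$name
  unknown <- setdiff(names(predefined$module_of), ids)
  if (length(unknown) > 0L)
    stop("predefined assignment covers unknown nodes: ",
         paste(unknown, collapse = ", "))
  residual <- setdiff(ids, names(predefined$module_of))
  if (length(residual) == 0L)
    return(predefined)
  if (!is.null(seed))
    set.seed(seed)
  sub <- igraph::induced_subgraph(network, residual)
  cl <- igraph::cluster_louvain(sub)
  memb <- igraph::membership(cl)
  pseudo <- stats::setNames(paste0("P", as.integer(memb)),
                            igraph::V(sub)$name)
  # keep node order: predefined nodes keep their modules, residual nodes
  # their pseudo modules, ordered as in the network
  all_of <- c(predefined$module_of, pseudo)[ids]
  names(all_of) <- ids
  module_assignment(all_of, predefined = predefined$predefined)
}
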