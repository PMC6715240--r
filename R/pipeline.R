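# End-to-end pipeline (objects in, objects out) and the file-based entry
# points behind the command-line interface.

#' Run the full three-stage layout on a network object
#'
#' Convenience wrapper chaining [partition_residual_nodes()] (Stage 1),
#' [count_intermodule_edges()] + [set_module_weight()] +
#' [layout_modules()] + [expand_modules()] (Stage 2) and
#' [set_node_weight()] + [optimize_nodes()] (Stage 3). One master seed
#' deterministically derives a seed per stage, so a single integer
#' reproduces the whole layout.
#'
#' @param network undirected simple `igraph` graph with vertex names.
#' @param predefined partial [module_assignment()] of predefined modules.
#' @param seed master integer seed.
#' @param niter_module,niter_grid iteration counts of the module-layout
#'   and grid-optimization stages.
#' @param perturb_prob,neighborhood see [optimizer_params()].
#' @param margin region-lattice margin, see [expand_modules()].
#' @param base_weights,extra_weight node weights, see [set_node_weight()].
#' @return A list with elements `layout` (node-level [grid_layout()]),
#'   `assignment` (total), `regions`, `module_layout`, `w_node`, and
#'   `cost` (final node-level cost).
#' @export
gml_layout <- function(network, predefined = module_assignment(),
                       seed = 1L, niter_module = 200L, niter_grid = 500L,
                       perturb_prob = 0.2, neighborhood = "moore",
                       margin = 2L, base_weights = c(40, 0, -10),
                       extra_weight = 40) {
  set.seed(as.integer(seed))
  stage_seeds <- sample.int(.Machine$integer.max - 1L, 3L)
  assignment <- partition_residual_nodes(network, predefined,
                                         seed = stage_seeds[[1L]])
  e <- count_intermodule_edges(network, assignment)
  w_mod <- set_module_weight(e)
  r_mod <- layout_modules(w_mod,
                          optimizer_params(niter = niter_module,
                                           perturb_prob = perturb_prob,
                                           seed = stage_seeds[[2L]],
                                           neighborhood = neighborhood))
  regions <- expand_modules(r_mod, assignment, margin = margin)
  w_node <- set_node_weight(network, assignment,
                            base_weights = base_weights,
                            extra_weight = extra_weight)
  layout <- optimize_nodes(network, w_node, regions, assignment,
                           optimizer_params(niter = niter_grid,
                                            perturb_prob = perturb_prob,
                                            seed = stage_seeds[[3L]],
                                            neighborhood = neighborhood))
  list(layout = layout, assignment = assignment, regions = regions,
       module_layout = r_mod, w_node = w_node,
       cost = layout_cost(w_node, layout))
}

#' File-based layout run (Stage 1 -> 2 -> 3)
#'
#' Reads a network (and optionally a predefined-module table), runs
#' [gml_layout()], and writes `layout.tsv`, `regions.tsv` and
#' `report.json` into `out_dir`. All inputs are validated before any
#' output is written, so a failing run leaves no partial outputs.
#'
#' @param network_path path of the network file.
#' @param out_dir output directory (created if needed).
#' @param predefined_path optional path of a two-column TSV of predefined
#'   modules.
#' @param format network format, see [read_network()].
#' @inheritParams gml_layout
#' @param alpha,epsilon metric parameters, see [layout_metrics()].
#' @return Invisibly, the [gml_layout()] result with an extra `metrics`
#'   element and a `report` element mirroring `report.json`.
#' @export
run_layout <- function(network_path, out_dir, predefined_path = NULL,
                       format = "edgelist", seed = 1L,
                       niter_module = 200L, niter_grid = 500L,
                       perturb_prob = 0.2, neighborhood = "moore",
                       margin = 2L, base_weights = c(40, 0, -10),
                       extra_weight = 40, alpha = 0.5, epsilon = 0.5) {
  network <- read_network(network_path, format = format)
  predefined <- if (!is.null(predefined_path))
    read_predefined_modules(predefined_path, network)
  else
    module_assignment()
  t0 <- proc.time()[["elapsed"]]
  res <- gml_layout(network, predefined, seed = seed,
                    niter_module = niter_module, niter_grid = niter_grid,
                    perturb_prob = perturb_prob, neighborhood = neighborhood,
                    margin = margin, base_weights = base_weights,
                    extra_weight = extra_weight)
  t1 <- proc.time()[["elapsed"]]
  metrics <- layout_metrics(res$layout, network, alpha = alpha,
                            epsilon = epsilon)
  t2 <- proc.time()[["elapsed"]]
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_layout(res$layout, res$assignment, file.path(out_dir, "layout.tsv"))
  write_regions(res$regions, file.path(out_dir, "regions.tsv"))
  report <- list(
    version = as.character(utils::packageVersion("gmlayout")),
    seed = as.integer(seed),
    parameters = list(niter_module = as.integer(niter_module),
                      niter_grid = as.integer(niter_grid),
                      perturb_prob = perturb_prob,
                      neighborhood = neighborhood,
                      margin = as.integer(margin),
                      base_weights = base_weights,
                      extra_weight = extra_weight,
                      alpha = alpha, epsilon = epsilon),
    n_nodes = igraph::gorder(network),
    n_edges = igraph::gsize(network),
    n_modules = length(res$assignment$modules),
    final_cost = res$cost,
    metrics = as.list(metrics),
    timings = list(layout_s = t1 - t0, metrics_s = t2 - t1)
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  res$metrics <- metrics
  res$report <- report
  invisible(res)
}

#' File-based metric evaluation
#'
#' Reads a network and a layout TSV (as written by [write_layout()]),
#' checks that the layout covers the network's nodes, and computes all
#' four quality metrics.
#'
#' @param network_path path of the network file.
#' @param layout_path path of the layout TSV.
#' @param format network format, see [read_network()].
#' @param alpha,epsilon metric parameters, see [layout_metrics()].
#' @param out_path optional path; when given, the one-row metric table is
#'   written there as TSV.
#' @return The one-row metric data frame.
#' @export
run_metrics <- function(network_path, layout_path, format = "edgelist",
                        alpha = 0.5, epsilon = 0.5, out_path = NULL) {
  network <- read_network(network_path, format = format)
  lay <- read_layout(layout_path)
  missing <- setdiff(igraph::V(network)$name, rownames(lay$layout$pos))
  if (length(missing) > 0L)
    stop("layout missing node(s): ", paste(missing, collapse = ", "))
  metrics <- layout_metrics(lay$layout, network, alpha = alpha,
                            epsilon = epsilon)
  if (!is.null(out_path))
    utils::write.table(metrics, out_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  metrics
}
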