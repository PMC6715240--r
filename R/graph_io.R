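# Readers and writers for networks, predefined-module tables and layouts.
# Networks are held as undirected simple igraph graphs whose vertices carry
# string names; vertex order is first-appearance order in the input.

#' Read an undirected network
#'
#' Parses a network file into an undirected simple graph. Duplicate edges
#' are collapsed and self-loops dropped, each with a warning; node order is
#' first-appearance order in the file.
#'
#' Formats:
#' * `edgelist` — whitespace-delimited lines `a b`; a line with a single
#'   token declares an isolated node.
#' * `sif` — Cytoscape simple-interaction format: `a type b c ...` creates
#'   edges a-b, a-c, ...; a single-token line declares an isolated node.
#' * `graphml` — GraphML node/edge elements; only ids/names are used.
#'
#' @param path file path.
#' @param format one of `"edgelist"`, `"sif"`, `"graphml"`.
#' @return An undirected simple `igraph` graph with character vertex names.
#' @export
read_network <- function(path, format = c("edgelist", "sif", "graphml")) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("input file does not exist: ", path)
  if (format == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    if (igraph::gorder(g) == 0L)
      stop("empty network in ", path)
    nm <- igraph::vertex_attr(g, "name")
    if (is.null(nm))
      nm <- igraph::vertex_attr(g, "id")
    if (is.null(nm))
      nm <- as.character(seq_len(igraph::gorder(g)))
    igraph::V(g)$name <- as.character(nm)
    return(simplify_with_warnings(igraph::as_undirected(g, mode = "collapse")))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  if (!any(keep))
    stop("empty network file: ", path)
  nodes <- character()
  from <- character()
  to <- character()
  for (ln in which(keep)) {
    tok <- strsplit(trimws(lines[[ln]]), "[ \t]+")[[1L]]
    if (format == "edgelist") {
      if (length(tok) == 1L) {
        nodes <- c(nodes, tok)
      } else if (length(tok) == 2L) {
        nodes <- c(nodes, tok)
        from <- c(from, tok[[1L]])
        to <- c(to, tok[[2L]])
      } else {
        stop("malformed edge list line ", ln, " in ", path,
             ": expected 1 or 2 tokens, got ", length(tok))
      }
    } else { # sif
      if (length(tok) == 1L) {
        nodes <- c(nodes, tok)
      } else if (length(tok) >= 3L) {
        src <- tok[[1L]]
        partners <- tok[-(1:2)]
        nodes <- c(nodes, src, partners)
        from <- c(from, rep(src, length(partners)))
        to <- c(to, partners)
      } else {
        stop("malformed SIF line ", ln, " in ", path,
             ": expected 1 or >= 3 tokens, got ", length(tok))
      }
    }
  }
  nodes <- unique(nodes)
  g <- igraph::graph_from_data_frame(data.frame(from = from, to = to,
                                                stringsAsFactors = FALSE),
                                     directed = FALSE,
                                     vertices = nodes)
  simplify_with_warnings(g)
}

simplify_with_warnings <- function(g) {
  n_loop <- sum(igraph::which_loop(g))
  n_multi <- sum(igraph::which_multiple(g))
  if (n_loop > 0L)
    warning(n_loop, " self-loop(s) dropped")
  if (n_multi > 0L)
    warning(n_multi, " duplicate edge(s) collapsed")
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write a network as a whitespace edge list
#'
#' One line per edge (`a b`, tab-separated) followed by one bare line per
#' isolated node, in vertex order; reading the file back with
#' [read_network()] reproduces the same network.
#'
#' @param network an undirected `igraph` graph with vertex names.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_network <- function(network, path) {
  el <- igraph::as_edgelist(network)
  iso <- igraph::V(network)$name[igraph::degree(network) == 0L]
  lines <- c(if (nrow(el) > 0L) paste(el[, 1L], el[, 2L], sep = "\t"), iso)
  writeLines(lines, path)
  invisible(path)
}

#' Read a predefined-module table
#'
#' Reads a two-column tab-separated file (`node-id`, `module-id`) naming
#' the nodes that belong to user-predefined modules (e.g. curated pathways
#' or complexes). All listed modules are flagged predefined. The result is
#' a partial assignment: nodes not listed are left for clustering
#' ([partition_residual_nodes()]).
#'
#' @param path file path; an empty file yields an empty assignment.
#' @param network the network the node ids must belong to.
#' @return A partial [module_assignment()] with every listed module
#'   flagged predefined.
#' @export
read_predefined_modules <- function(path, network) {
  if (!file.exists(path))
    stop("predefined-module file does not exist: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L)
    return(module_assignment())
  parts <- strsplit(lines, "\t")
  bad <- which(vapply(parts, length, integer(1)) != 2L)
  if (length(bad) > 0L)
    stop("malformed predefined-module line ", bad[[1L]],
         ": expected two tab-separated columns")
  node <- vapply(parts, `[[`, character(1), 1L)
  mod <- vapply(parts, `[[`, character(1), 2L)
  dup <- duplicated(paste(node, mod))
  node <- node[!dup]
  mod <- mod[!dup]
  conflict <- unique(node[duplicated(node)])
  if (length(conflict) > 0L)
    stop("node assigned to two modules: ",
         paste(conflict, collapse = ", "))
  unknown <- setdiff(node, igraph::V(network)$name)
  if (length(unknown) > 0L)
    stop("node id(s) not in network: ", paste(unknown, collapse = ", "))
  module_assignment(stats::setNames(mod, node), predefined = unique(mod))
}

#' Write a node layout as TSV
#'
#' Writes a header line `node\tx\ty\tmodule\tpredefined` followed by one
#' row per node in layout order. Output is byte-deterministic for a fixed
#' layout, so identical runs produce identical files.
#'
#' @param layout a [grid_layout()] over node ids.
#' @param assignment a [module_assignment()] covering every node in the
#'   layout.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, assignment, path) {
  stopifnot(inherits(layout, "grid_layout"),
            inherits(assignment, "module_assignment"))
  ids <- rownames(layout$pos)
  missing <- setdiff(ids, names(assignment$module_of))
  if (length(missing) > 0L)
    stop("nodes missing from assignment: ", paste(missing, collapse = ", "))
  mods <- unname(assignment$module_of[ids])
  pre <- ifelse(mods %in% assignment$predefined, "true", "false")
  lines <- c("node\tx\ty\tmodule\tpredefined",
             paste(ids, layout$pos[, 1L], layout$pos[, 2L], mods, pre,
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a layout TSV written by [write_layout()]
#'
#' @param path file path.
#' @return A list with elements `layout` (a [grid_layout()]) and
#'   `assignment` (a [module_assignment()]).
#' @export
read_layout <- function(path) {
  if (!file.exists(path))
    stop("layout file does not exist: ", path)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = c("character", "integer", "integer",
                                          "character", "character"))
  if (!identical(names(tab), c("node", "x", "y", "module", "predefined")))
    stop("unexpected layout header in ", path)
  pos <- cbind(x = tab$x, y = tab$y)
  rownames(pos) <- tab$node
  pre <- unique(tab$module[tab$predefined == "true"])
  list(layout = grid_layout(pos),
       assignment = module_assignment(stats::setNames(tab$module, tab$node),
                                      predefined = pre))
}

#' Write module regions as TSV
#'
#' @param regions a `module_regions` data frame from [expand_modules()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  lines <- c("module\tx0\ty0\tside",
             paste(regions$module, regions$x0, regions$y0, regions$side,
                   sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
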