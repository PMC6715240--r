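# Module assignments: a partition (total or partial) of network nodes into
# predefined modules (supplied by the user, e.g. pathways or complexes) and
# pseudo modules (found by clustering).

#' Create a module assignment
#'
#' Maps each node to exactly one module and records which modules are
#' predefined (fixed by prior biological knowledge) as opposed to pseudo
#' modules produced by clustering. An assignment may be partial (covering
#' only some nodes of a network), e.g. when it lists predefined modules
#' only, before clustering fills in the rest.
#'
#' @param module_of named character vector: names are node ids, values are
#'   module ids.
#' @param predefined character vector of module ids flagged as predefined;
#'   must be a subset of the module ids occurring in `module_of`.
#' @return An object of class `module_assignment` with elements
#'   `module_of`, `predefined`, and `modules` (list mapping module id to
#'   the character vector of its nodes, in first-appearance order).
#' @examples
#' module_assignment(c(a = "M1", b = "M1", c = "P1"), predefined = "M1")
#' @export
module_assignment <- function(module_of = character(),
                              predefined = character()) {
  module_of <- vapply(module_of, as.character, character(1))
  if (length(module_of) > 0L && is.null(names(module_of)))
    stop("'module_of' must be named by node ids")
  if (anyDuplicated(names(module_of)))
    stop("node assigned to two modules: ",
         paste(unique(names(module_of)[duplicated(names(module_of))]),
               collapse = ", "))
  predefined <- as.character(predefined)
  extra <- setdiff(predefined, module_of)
  if (length(extra) > 0L)
    stop("predefined module ids absent from assignment: ",
         paste(extra, collapse = ", "))
  mod_ids <- unique(unname(module_of))
  modules <- lapply(mod_ids, function(m) names(module_of)[module_of == m])
  names(modules) <- mod_ids
  structure(list(module_of = module_of, predefined = predefined,
                 modules = modules),
            class = "module_assignment")
}

#' @export
print.module_assignment <- function(x, ...) {
  cat("module assignment:", length(x$module_of), "nodes in",
      length(x$modules), "modules (", length(x$predefined),
      "predefined )\n")
  invisible(x)
}

#' Number of nodes per module
#'
#' @param assignment a [module_assignment()].
#' @return Named integer vector of module sizes.
#' @export
module_sizes <- function(assignment) {
  stopifnot(inherits(assignment, "module_assignment"))
  vapply(assignment$modules, length, integer(1))
}

# Check that an assignment covers exactly the nodes of a network.
assert_total <- function(assignment, network) {
  ids <- igraph::V(network)$name
  missing <- setdiff(ids, names(assignment$module_of))
  if (length(missing) > 0L)
    stop("assignment does not cover nodes: ",
         paste(utils::head(missing, 5L), collapse = ", "))
  extra <- setdiff(names(assignment$module_of), ids)
  if (length(extra) > 0L)
    stop("assignment covers unknown nodes: ",
         paste(utils::head(extra, 5L), collapse = ", "))
  invisible(assignment)
}
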