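# Stage 2: module layout. Modules are treated as single points, placed by
# minimizing the module-level cost (weights from inter-module edge counts),
# then expanded into pairwise-disjoint square regions sized for their
# member nodes.

#' Count edges between modules
#'
#' `e[h, k]` is the number of network edges with one endpoint in module `h`
#' and the other in module `k` (for `h != k`; the diagonal is zero —
#' intra-module edges are not counted here).
#'
#' @param network undirected simple `igraph` graph with vertex names.
#' @param assignment a total [module_assignment()].
#' @return A symmetric integer matrix with module ids as dimnames.
#' @export
count_intermodule_edges <- function(network, assignment) {
  stopifnot(inherits(assignment, "module_assignment"))
  assert_total(assignment, network)
  mods <- names(assignment$modules)
  e <- matrix(0L, length(mods), length(mods), dimnames = list(mods, mods))
  el <- igraph::as_edgelist(network)
  if (nrow(el) > 0L) {
    mh <- assignment$module_of[el[, 1L]]
    mk <- assignment$module_of[el[, 2L]]
    cross <- mh != mk
    for (r in which(cross)) {
      e[mh[[r]], mk[[r]]] <- e[mh[[r]], mk[[r]]] + 1L
      e[mk[[r]], mh[[r]]] <- e[mk[[r]], mh[[r]]] + 1L
    }
  }
  e
}

#' Module-pair weights from inter-module edge counts
#'
#' Builds the module-level weight matrix: module pairs connected by more
#' edges get larger weights, pulling them closer in the module layout. The
#' default mapping is the identity (`w = e`), the simplest monotone
#' choice; any non-decreasing function with `f(0) = 0` may be supplied.
#'
#' @param e symmetric non-negative count matrix from
#'   [count_intermodule_edges()].
#' @param mapping non-decreasing function applied elementwise; must map 0
#'   to 0.
#' @return A symmetric numeric weight matrix.
#' @export
set_module_weight <- function(e, mapping = identity) {
  w <- mapping(e)
  w <- (w + t(w)) / 2  # guard symmetry under any user mapping
  diag(w) <- 0
  storage.mode(w) <- "double"
  w
}

#' Place modules as single points on the grid
#'
#' Each module is one entity; positions are optimized with
#' [reoptimize()] under the module-level cost (weighted Manhattan
#' distances). The initial placement is a seeded random injective
#' placement on a board of side `ceiling(sqrt(k)) + 2` for `k` modules —
#' just enough slack for the descent to rearrange freely. A single module
#' is placed at the origin.
#'
#' @param w_module symmetric weight matrix over module ids (from
#'   [set_module_weight()]).
#' @param params an [optimizer_params()]; its `seed` (if any) makes the
#'   whole placement deterministic.
#' @return A [grid_layout()] over module ids.
#' @export
layout_modules <- function(w_module, params = optimizer_params(niter = 200L)) {
  ids <- rownames(w_module)
  if (is.null(ids))
    stop("'w_module' must have module ids as dimnames")
  k <- length(ids)
  if (k == 0L)
    stop("no modules to lay out")
  if (k == 1L)
    return(grid_layout(matrix(c(0L, 0L), 1L, 2L,
                              dimnames = list(ids, c("x", "y")))))
  if (!is.null(params$seed))
    set.seed(params$seed)
  side <- as.integer(ceiling(sqrt(k))) + 2L
  init <- random_grid_layout(ids, side, side, bounded = TRUE)
  params$seed <- NULL  # RNG already seeded; continue the stream
  reoptimize(w_module, init, params)
}

#' Expand module points into square regions
#'
#' Each module `h` with `n_h` nodes gets a square region of side
#' `l_h = max(2, ceiling(2 * sqrt(n_h)))` grid points, enough to host its
#' nodes with room to show their connections (`l_h^2 >= 4 * n_h`). Module
#' grid coordinates are scaled by `l' = max_h l_h + margin`, the pitch of
#' the region lattice, so the region of module `h` has upper-left corner
#' `(x_h * l', y_h * l')`. Because `l_h <= l'` and module positions are
#' distinct integer points, regions never share a grid point; a positive
#' margin additionally leaves a vacant corridor between neighbouring
#' regions.
#'
#' @param r_module a [grid_layout()] over module ids (from
#'   [layout_modules()]).
#' @param assignment a [module_assignment()] giving module sizes.
#' @param margin non-negative integer added to the lattice pitch
#'   (default 2).
#' @return A data frame of class `module_regions` with columns `module`,
#'   `x0`, `y0` (upper-left corner) and `side`; the region of a module
#'   covers grid points `x0 .. x0+side-1` by `y0 .. y0+side-1`.
#' @export
expand_modules <- function(r_module, assignment, margin = 2L) {
  stopifnot(inherits(r_module, "grid_layout"),
            inherits(assignment, "module_assignment"))
  margin <- as.integer(margin)
  if (is.na(margin) || margin < 0L)
    stop("'margin' must be a non-negative integer")
  ids <- rownames(r_module$pos)
  missing <- setdiff(ids, names(assignment$modules))
  if (length(missing) > 0L)
    stop("modules missing from assignment: ",
         paste(missing, collapse = ", "))
  n_h <- vapply(assignment$modules[ids], length, integer(1))
  side <- pmax(2L, as.integer(ceiling(2 * sqrt(n_h))))
  pitch <- max(side) + margin
  out <- data.frame(module = ids,
                    x0 = r_module$pos[, 1L] * pitch,
                    y0 = r_module$pos[, 2L] * pitch,
                    side = side,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "pitch") <- pitch
  class(out) <- c("module_regions", "data.frame")
  out
}

#' Grid points of one module region
#'
#' @param regions a `module_regions` data frame.
#' @param module a module id present in `regions`.
#' @return A two-column integer matrix of all `side^2` grid points of the
#'   region.
#' @export
region_points <- function(regions, module) {
  r <- regions[regions$module == module, , drop = FALSE]
  if (nrow(r) != 1L)
    stop("module not found in regions: ", module)
  pts <- expand.grid(x = r$x0 + seq_len(r$side) - 1L,
                     y = r$y0 + seq_len(r$side) - 1L)
  cbind(x = as.integer(pts$x), y = as.integer(pts$y))
}
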