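# Core grid machinery: layouts on integer grid points, Manhattan cost,
# single-entity descent, random perturbation, and the
# reoptimization-after-perturbation loop shared by the module-layout and
# grid-optimization stages.

BOUND_SENTINEL <- 1073741824L  # 2^30; effectively unbounded

#' Create a grid layout
#'
#' A grid layout maps entities (nodes or modules) to integer grid
#' coordinates. Occupancy is exclusive: no two entities may share a grid
#' point. Optional bounds restrict where each entity may be placed; bounds
#' are enforced by the constructor and respected by every optimizer move.
#'
#' The coordinate convention is the usual screen convention: x grows to the
#' right, y grows downward, and the origin is arbitrary (all costs depend
#' only on coordinate differences).
#'
#' @param pos two-column matrix (or data frame) of integer x, y
#'   coordinates with entity identifiers as row names.
#' @param bounds either `NULL` (unbounded), a numeric vector
#'   `c(xmin, xmax, ymin, ymax)` applied to every entity, or a four-column
#'   matrix with one row per entity (row names matching `pos`).
#' @return An object of class `grid_layout` with elements `pos` (integer
#'   matrix) and `bounds` (`NULL` or integer matrix).
#' @examples
#' l <- grid_layout(rbind(a = c(0, 0), b = c(2, 1)))
#' layout_cost(weight_matrix(c("a", "b"), rbind(c("a", "b", 3))), l)
#' @export
grid_layout <- function(pos, bounds = NULL) {
  pos <- as.matrix(pos)
  if (ncol(pos) != 2L)
    stop("'pos' must have two columns (x, y)")
  if (is.null(rownames(pos)))
    stop("'pos' must have entity identifiers as row names")
  if (anyDuplicated(rownames(pos)))
    stop("duplicate entity identifiers in 'pos'")
  if (any(!is.finite(pos)) || any(pos != round(pos)))
    stop("grid coordinates must be finite integers")
  storage.mode(pos) <- "integer"
  colnames(pos) <- c("x", "y")
  key <- paste(pos[, 1L], pos[, 2L])
  if (anyDuplicated(key))
    stop("two entities occupy the same grid point")
  bounds <- normalize_bounds(bounds, rownames(pos))
  if (!is.null(bounds)) {
    ok <- pos[, 1L] >= bounds[, 1L] & pos[, 1L] <= bounds[, 2L] &
      pos[, 2L] >= bounds[, 3L] & pos[, 2L] <= bounds[, 4L]
    if (!all(ok))
      stop("positions outside bounds for: ",
           paste(rownames(pos)[!ok], collapse = ", "))
  }
  structure(list(pos = pos, bounds = bounds), class = "grid_layout")
}

normalize_bounds <- function(bounds, ids) {
  if (is.null(bounds))
    return(NULL)
  if (is.null(dim(bounds))) {
    if (length(bounds) != 4L)
      stop("'bounds' vector must be c(xmin, xmax, ymin, ymax)")
    bounds <- matrix(rep(as.integer(bounds), each = length(ids)),
                     ncol = 4L, dimnames = list(ids, NULL))
  } else {
    bounds <- as.matrix(bounds)
    if (ncol(bounds) != 4L)
      stop("'bounds' matrix must have four columns")
    if (is.null(rownames(bounds)))
      rownames(bounds) <- ids
    bounds <- bounds[ids, , drop = FALSE]
  }
  storage.mode(bounds) <- "integer"
  colnames(bounds) <- c("xmin", "xmax", "ymin", "ymax")
  if (any(bounds[, 1L] > bounds[, 2L]) || any(bounds[, 3L] > bounds[, 4L]))
    stop("empty bounds: min exceeds max")
  bounds
}

bounds_or_sentinel <- function(layout) {
  n <- nrow(layout$pos)
  if (!is.null(layout$bounds))
    return(layout$bounds)
  matrix(rep(c(-BOUND_SENTINEL, BOUND_SENTINEL, -BOUND_SENTINEL,
               BOUND_SENTINEL), each = n), ncol = 4L)
}

#' @export
print.grid_layout <- function(x, ...) {
  cat("grid layout of", nrow(x$pos), "entities",
      if (is.null(x$bounds)) "(unbounded)" else "(bounded)", "\n")
  print(utils::head(x$pos, 10L))
  if (nrow(x$pos) > 10L)
    cat("... and", nrow(x$pos) - 10L, "more\n")
  invisible(x)
}

#' Manhattan distance between two grid points
#'
#' The distance used by every layout cost in this package:
#' `|x_a - x_b| + |y_a - y_b|`.
#'
#' @param a,b numeric vectors of length two, `c(x, y)`.
#' @return A non-negative number.
#' @examples
#' manhattan(c(1, 2), c(4, 6)) # 7
#' @export
manhattan <- function(a, b) {
  abs(a[[1L]] - b[[1L]]) + abs(a[[2L]] - b[[2L]])
}

#' Construct a symmetric pairwise weight matrix
#'
#' Convenience constructor for the weight matrices driving the layout cost:
#' absent pairs default to weight zero and entries are mirrored so the
#' matrix is symmetric.
#'
#' @param ids character vector of entity identifiers.
#' @param entries optional three-column matrix or data frame
#'   (`id_i`, `id_j`, `weight`) of nonzero entries.
#' @return A symmetric numeric matrix with `ids` as dimnames and zero
#'   diagonal.
#' @examples
#' weight_matrix(c("a", "b", "c"), rbind(c("a", "b", 40)))
#' @export
weight_matrix <- function(ids, entries = NULL) {
  w <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  if (!is.null(entries)) {
    entries <- as.matrix(entries)
    for (r in seq_len(nrow(entries))) {
      i <- entries[r, 1L]
      j <- entries[r, 2L]
      v <- as.numeric(entries[r, 3L])
      w[i, j] <- v
      w[j, i] <- v
    }
  }
  w
}

# Align a weight matrix to the layout's entity order; every entity carrying
# weight must be present in the layout.
align_weights <- function(w, layout) {
  ids <- rownames(layout$pos)
  if (is.null(dimnames(w)) && nrow(w) == length(ids)) {
    dimnames(w) <- list(ids, ids)
  }
  missing <- setdiff(rownames(w), ids)
  if (length(missing) > 0L)
    stop("entities in weight matrix missing from layout: ",
         paste(missing, collapse = ", "))
  if (!isSymmetric(unname(w)))
    stop("weight matrix must be symmetric")
  full <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  full[rownames(w), colnames(w)] <- w
  diag(full) <- 0
  full
}

#' Layout cost: weighted sum of pairwise Manhattan distances
#'
#' `C(W, R) = sum over unordered pairs of w_ij * d_ij`, where `d_ij` is the
#' Manhattan distance between the grid positions of entities i and j. The
#' same cost form drives both the module-layout stage (weights from
#' inter-module edge counts) and the grid-optimization stage (weights from
#' path lengths).
#'
#' @param w symmetric weight matrix (dimnames are entity ids).
#' @param layout a [grid_layout()] covering every entity in `w`.
#' @return A single number; translation of the whole layout leaves it
#'   unchanged.
#' @export
layout_cost <- function(w, layout) {
  stopifnot(inherits(layout, "grid_layout"))
  w <- align_weights(w, layout)
  grid_cost_cpp(layout$pos, w)
}

#' Optimizer parameters for reoptimization after perturbation
#'
#' @param niter number of perturb-and-reoptimize rounds (`>= 0`).
#' @param perturb_prob probability in `[0, 1]` that an entity is kicked to
#'   a random vacant neighbouring point in each perturbation.
#' @param seed optional integer seed; when given, the optimizer seeds R's
#'   RNG so runs are exactly reproducible.
#' @param neighborhood `"moore"` (8 surrounding points, the default) or
#'   `"von_neumann"` (4 axis-aligned points) for both descent moves and
#'   perturbation kicks.
#' @return A list of class `optimizer_params`.
#' @export
optimizer_params <- function(niter = 500L, perturb_prob = 0.2, seed = NULL,
                             neighborhood = c("moore", "von_neumann")) {
  neighborhood <- match.arg(neighborhood)
  niter <- as.integer(niter)
  if (is.na(niter) || niter < 0L)
    stop("'niter' must be a non-negative integer")
  if (!is.numeric(perturb_prob) || perturb_prob < 0 || perturb_prob > 1)
    stop("'perturb_prob' must be in [0, 1]")
  if (!is.null(seed))
    seed <- as.integer(seed)
  structure(list(niter = niter, perturb_prob = perturb_prob, seed = seed,
                 neighborhood = neighborhood),
            class = "optimizer_params")
}

#' Single-entity descent to a local cost minimum
#'
#' Sweeps all entities in a fixed order; each entity is scored against its
#' vacant neighbouring grid points (within its bounds) and moved to the one
#' with the largest strictly negative cost change. Sweeps repeat until a
#' full sweep commits no move, so the result is a local minimum under
#' single-entity moves and its cost never exceeds the input cost.
#'
#' @inheritParams layout_cost
#' @param neighborhood see [optimizer_params()].
#' @return A `grid_layout` with the same entities and bounds.
#' @export
partial_optimize <- function(w, layout,
                             neighborhood = c("moore", "von_neumann")) {
  stopifnot(inherits(layout, "grid_layout"))
  neighborhood <- match.arg(neighborhood)
  w <- align_weights(w, layout)
  pos <- grid_partial_optimize_cpp(layout$pos, w, bounds_or_sentinel(layout),
                                   neighborhood == "moore")
  dimnames(pos) <- dimnames(layout$pos)
  structure(list(pos = pos, bounds = layout$bounds), class = "grid_layout")
}

#' Randomly perturb a layout
#'
#' Each entity independently, with probability `perturb_prob`, jumps to a
#' uniformly chosen vacant neighbouring grid point inside its bounds (it
#' stays put when no neighbour is vacant). Exclusive occupancy and bounds
#' are preserved. Uses R's RNG stream: call `set.seed()` beforehand for
#' reproducibility.
#'
#' @param layout a [grid_layout()].
#' @param perturb_prob kick probability in `[0, 1]`.
#' @param neighborhood see [optimizer_params()].
#' @return A `grid_layout`.
#' @export
perturb_layout <- function(layout, perturb_prob,
                           neighborhood = c("moore", "von_neumann")) {
  stopifnot(inherits(layout, "grid_layout"))
  neighborhood <- match.arg(neighborhood)
  if (perturb_prob < 0 || perturb_prob > 1)
    stop("'perturb_prob' must be in [0, 1]")
  pos <- grid_perturb_cpp(layout$pos, perturb_prob,
                          bounds_or_sentinel(layout),
                          neighborhood == "moore")
  dimnames(pos) <- dimnames(layout$pos)
  structure(list(pos = pos, bounds = layout$bounds), class = "grid_layout")
}

#' Reoptimization after perturbation
#'
#' The global heuristic used by both layout stages. The initial layout is
#' first brought to a local minimum with [partial_optimize()]; then, for
#' `niter` rounds, the incumbent is perturbed ([perturb_layout()]) and
#' re-optimized, and the candidate replaces the incumbent only when its
#' cost is strictly lower. The returned cost therefore never exceeds the
#' cost of the locally optimized initial layout, and the incumbent cost is
#' non-increasing across rounds.
#'
#' @inheritParams layout_cost
#' @param params an [optimizer_params()] object.
#' @return A `grid_layout`.
#' @export
reoptimize <- function(w, layout, params = optimizer_params()) {
  stopifnot(inherits(layout, "grid_layout"),
            inherits(params, "optimizer_params"))
  if (!is.null(params$seed))
    set.seed(params$seed)
  w <- align_weights(w, layout)
  pos <- grid_reoptimize_cpp(layout$pos, w, bounds_or_sentinel(layout),
                             params$niter, params$perturb_prob,
                             params$neighborhood == "moore")
  dimnames(pos) <- dimnames(layout$pos)
  structure(list(pos = pos, bounds = layout$bounds), class = "grid_layout")
}

#' Random injective placement on a rectangular board
#'
#' Places entities uniformly at random on distinct grid points of the board
#' `[0, width) x [0, height)`. Used for optimizer initialization and as the
#' random-layout baseline in quality comparisons.
#'
#' @param ids character vector of entity identifiers.
#' @param width,height board dimensions in grid points;
#'   `width * height >= length(ids)` is required.
#' @param bounded if `TRUE` the board is attached as bounds of the
#'   resulting layout.
#' @return A `grid_layout`.
#' @export
random_grid_layout <- function(ids, width, height, bounded = FALSE) {
  width <- as.integer(width)
  height <- as.integer(height)
  n <- length(ids)
  if (width * height < n)
    stop("board too small: ", width, "x", height, " for ", n, " entities")
  cells <- sample.int(width * height, n) - 1L
  pos <- cbind(x = cells %% width, y = cells %/% width)
  rownames(pos) <- ids
  grid_layout(pos, bounds = if (bounded) c(0L, width - 1L, 0L, height - 1L))
}

#' Translate a layout by an integer offset
#'
#' @param layout a [grid_layout()].
#' @param dx,dy integer offsets added to every x / y coordinate (bounds, if
#'   any, are shifted along).
#' @return A `grid_layout`.
#' @export
translate_layout <- function(layout, dx, dy) {
  stopifnot(inherits(layout, "grid_layout"))
  pos <- layout$pos
  pos[, 1L] <- pos[, 1L] + as.integer(dx)
  pos[, 2L] <- pos[, 2L] + as.integer(dy)
  bounds <- layout$bounds
  if (!is.null(bounds)) {
    bounds[, 1:2] <- bounds[, 1:2] + as.integer(dx)
    bounds[, 3:4] <- bounds[, 3:4] + as.integer(dy)
  }
  structure(list(pos = pos, bounds = bounds), class = "grid_layout")
}
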