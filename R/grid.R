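#' Define a regular 3-D grid
#'
#' A grid is the cartesian product of `shape[i]` nodes per axis starting at
#' `origin` with uniform `spacing`. Node `(i, j, k)` (1-based) sits at
#' `origin + (c(i, j, k) - 1) * spacing`.
#'
#' @param origin numeric length-3, Angstrom; position of the first node.
#' @param spacing positive scalar, Angstrom.
#' @param shape integer length-3, nodes per axis; each must be at least 8.
#' @return An object of class `grid_spec`.
#' @examples
#' g <- grid_spec(c(-5, -5, -5), 1, c(11, 11, 11))
#' g
#' @export
grid_spec <- function(origin, spacing, shape) {
  origin <- as.numeric(origin)
  shape <- as.integer(shape)
  stopifnot(length(origin) == 3, length(shape) == 3)
  if (!is.finite(spacing) || spacing <= 0) stop("grid spacing must be > 0")
  if (any(shape < 8L)) stop("each grid dimension must be >= 8 nodes")
  structure(list(origin = origin, spacing = as.numeric(spacing), shape = shape),
            class = "grid_spec")
}

#' @export
print.grid_spec <- function(x, ...) {
  cat(sprintf("grid_spec: %d x %d x %d nodes, spacing %g A, origin (%g, %g, %g)\n",
              x$shape[1], x$shape[2], x$shape[3], x$spacing,
              x$origin[1], x$origin[2], x$origin[3]))
  invisible(x)
}

#' Node coordinates along each grid axis
#' @param grid a `grid_spec`.
#' @return list of three numeric vectors (x, y, z node coordinates).
#' @export
grid_axes <- function(grid) {
  stopifnot(inherits(grid, "grid_spec"))
  lapply(1:3, function(d) grid$origin[d] + (seq_len(grid$shape[d]) - 1) * grid$spacing)
}

#' Auto-centred grid around one or more structures
#'
#' Centres the box on the centroid of all atoms. When `shape` is NULL the
#' box is sized so that every atom has at least `margin` Angstrom of grid on
#' all sides (the margin guards the Dirichlet boundary and the skin).
#'
#' @param structures a `mif_structure` or list of them.
#' @param spacing grid spacing in Angstrom (default 1, the usual
#'   electrostatics resolution).
#' @param shape optional fixed shape (e.g. `c(110, 110, 110)` for
#'   production-scale runs); checked to enclose the atoms.
#' @param margin minimum clearance between any atom centre and the box
#'   faces, Angstrom.
#' @return a `grid_spec`.
#' @export
default_grid <- function(structures, spacing = 1.0, shape = NULL, margin = 10.0) {
  if (inherits(structures, "mif_structure")) structures <- list(structures)
  xyz <- do.call(rbind, lapply(structures, function(s) s$atoms[, c("x", "y", "z")]))
  xyz <- as.matrix(xyz)
  lo <- apply(xyz, 2, min); hi <- apply(xyz, 2, max)
  centre <- (lo + hi) / 2
  if (is.null(shape)) {
    half <- (hi - lo) / 2 + margin
    n <- 2L * as.integer(ceiling(half / spacing)) + 1L
    shape <- pmax(n, 9L)
  } else {
    shape <- as.integer(shape)
  }
  origin <- centre - (shape - 1L) / 2 * spacing
  g <- grid_spec(origin, spacing, shape)
  ext <- origin + (shape - 1L) * spacing
  if (any(lo < origin) || any(hi > ext))
    stop("requested grid shape does not enclose the structure(s)")
  g
}

#' Refine a grid by an integer factor (shared origin, nested nodes)
#'
#' The refined grid keeps the same physical extent; every node of the
#' coarse grid coincides with a node of the fine grid.
#' @param grid a `grid_spec`.
#' @param factor integer >= 2.
#' @export
refine_grid <- function(grid, factor = 2L) {
  factor <- as.integer(factor)
  stopifnot(factor >= 2L)
  grid_spec(grid$origin, grid$spacing / factor, (grid$shape - 1L) * factor + 1L)
}

#' Scalar field on a grid
#'
#' The universal MIF container: one real value per grid node plus units and
#' a kind label ("electrostatic" in kT/e or "hydrophobic" in kcal/mol).
#'
#' @param grid a `grid_spec`.
#' @param values numeric 3-D array with `dim == grid$shape`, all finite.
#' @param units unit label.
#' @param kind `"electrostatic"` or `"hydrophobic"` (or `"mask"` for 0/1
#'   exports).
#' @return an object of class `scalar_field`.
#' @export
scalar_field <- function(grid, values, units = "kT/e", kind = "electrostatic") {
  stopifnot(inherits(grid, "grid_spec"))
  values <- as.array(values)
  if (!identical(dim(values), as.integer(grid$shape)))
    stop("values dimensions do not match the grid shape")
  if (!all(is.finite(values))) stop("scalar_field values must all be finite")
  structure(list(grid = grid, values = values, units = units, kind = kind),
            class = "scalar_field")
}

#' @export
print.scalar_field <- function(x, ...) {
  cat(sprintf("scalar_field (%s, %s): %d x %d x %d, range [%.4g, %.4g]\n",
              x$kind, x$units, dim(x$values)[1], dim(x$values)[2], dim(x$values)[3],
              min(x$values), max(x$values)))
  invisible(x)
}

#' Downsample a field computed on a refined grid back to its parent grid
#'
#' Takes every `factor`-th node; the grids must be nested (same origin,
#' `spacing * factor`, compatible shape). Used to bring 0.5-Angstrom
#' hydrophobic fields onto the 1-Angstrom electrostatics grid so that one
#' skin mask serves both field kinds.
#' @param field a `scalar_field` on the fine grid.
#' @param factor integer stride.
#' @export
downsample_field <- function(field, factor = 2L) {
  stopifnot(inherits(field, "scalar_field"))
  factor <- as.integer(factor)
  sh <- field$grid$shape
  if (any((sh - 1L) %% factor != 0L))
    stop("grid shape is not nested for this downsampling factor")
  idx <- lapply(sh, function(n) seq(1L, n, by = factor))
  vals <- field$values[idx[[1]], idx[[2]], idx[[3]], drop = FALSE]
  g <- grid_spec(field$grid$origin, field$grid$spacing * factor,
                 (sh - 1L) %/% factor + 1L)
  scalar_field(g, vals, units = field$units, kind = field$kind)
}

# grids equal up to tolerance (shared container contract for comparisons)
grids_identical <- function(a, b, tol = 1e-9) {
  identical(a$shape, b$shape) &&
    abs(a$spacing - b$spacing) <= tol &&
    all(abs(a$origin - b$origin) <= tol)
}

# Minimum gap field: at each node, min over atoms of (distance - radius),
# computed only where it can be <= cutoff_gap; +Inf elsewhere. The shared
# geometric primitive behind dielectric maps, ion accessibility and skins.
min_gap_field <- function(structure, grid, cutoff_gap) {
  ax <- grid_axes(grid)
  sh <- grid$shape
  gap <- array(Inf, dim = sh)
  at <- structure$atoms
  h <- grid$spacing
  for (i in seq_len(nrow(at))) {
    r <- at$radius[i]
    reach <- r + cutoff_gap + h
    ix <- which(abs(ax[[1]] - at$x[i]) <= reach)
    iy <- which(abs(ax[[2]] - at$y[i]) <= reach)
    iz <- which(abs(ax[[3]] - at$z[i]) <= reach)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (ax[[1]][ix] - at$x[i])^2
    dy2 <- (ax[[2]][iy] - at$y[i])^2
    dz2 <- (ax[[3]][iz] - at$z[i])^2
    d <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
    sub <- gap[ix, iy, iz, drop = FALSE]
    gap[ix, iy, iz] <- pmin(sub, d - r)
  }
  gap
}
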