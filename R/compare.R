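#' Field-comparison settings
#'
#' The comparison shell ("skin") holds the grid points whose gap to the
#' nearest atom surface lies between `skin_probe` and `skin_probe +
#' skin_thickness` -- the region a binding partner's atoms can actually
#' occupy. Local comparisons use spheres of `sphere_radius` around each
#' residue's C-alpha. A similarity index is only defined when at least
#' `min_points` grid points survive the masking.
#'
#' @param skin_probe Angstrom, offset of the skin from the atom surfaces.
#' @param skin_thickness Angstrom.
#' @param sphere_radius Angstrom, for the per-residue scan.
#' @param min_points minimum masked points for a defined index.
#' @return an object of class `comparison_spec`.
#' @export
comparison_spec <- function(skin_probe = 2.0, skin_thickness = 3.0,
                            sphere_radius = 15.0, min_points = 50L) {
  if (skin_probe <= 0 || skin_thickness <= 0 || sphere_radius <= 0)
    stop("comparison_spec lengths must be positive")
  min_points <- as.integer(min_points)
  if (min_points < 1L) stop("min_points must be >= 1")
  structure(list(skin_probe = skin_probe, skin_thickness = skin_thickness,
                 sphere_radius = sphere_radius, min_points = min_points),
            class = "comparison_spec")
}

#' Skin mask: the comparison shell around a structure
#'
#' Selects every grid point whose smallest gap to an atom surface
#' (`|p - x_i| - r_i`, minimised over atoms) lies in
#' `[skin_probe, skin_probe + skin_thickness]`.
#'
#' @param structure a `mif_structure` inside the grid.
#' @param grid a `grid_spec`.
#' @param spec a `comparison_spec`.
#' @param enforce_min error when fewer than `spec$min_points` points are
#'   selected (default TRUE for global skins).
#' @return an object of class `skin_mask`.
#' @export
skin_mask <- function(structure, grid, spec = comparison_spec(),
                      enforce_min = TRUE) {
  stopifnot(inherits(grid, "grid_spec"))
  gap <- min_gap_field(structure, grid, spec$skin_probe + spec$skin_thickness)
  sel <- gap >= spec$skin_probe & gap <= spec$skin_probe + spec$skin_thickness
  m <- structure(list(grid = grid, selected = sel, n_selected = sum(sel)),
                 class = "skin_mask")
  if (enforce_min && m$n_selected < spec$min_points)
    stop(sprintf("degenerate skin: only %d points selected (min_points = %d)",
                 m$n_selected, spec$min_points))
  m
}

#' @export
print.skin_mask <- function(x, ...) {
  cat(sprintf("skin_mask: %d of %d grid points selected\n",
              x$n_selected, prod(x$grid$shape)))
  invisible(x)
}

#' Intersect / unite two skin masks
#' @param a,b `skin_mask`s on the same grid.
#' @param op `"intersection"` or `"union"`.
#' @export
combine_masks <- function(a, b, op = c("intersection", "union")) {
  op <- match.arg(op)
  if (!grids_identical(a$grid, b$grid)) stop("masks live on different grids")
  sel <- if (op == "intersection") a$selected & b$selected else a$selected | b$selected
  structure(list(grid = a$grid, selected = sel, n_selected = sum(sel)),
            class = "skin_mask")
}

#' Restrict a skin mask to a sphere
#'
#' `selected = base AND |p - center| <= sphere_radius`. An empty result is
#' allowed; downstream similarity calls flag it as undefined.
#'
#' @param base a `skin_mask`.
#' @param center numeric length-3, Angstrom; must lie inside the grid.
#' @param spec a `comparison_spec` (uses `sphere_radius`).
#' @return a `skin_mask`.
#' @export
sphere_mask <- function(base, center, spec = comparison_spec()) {
  stopifnot(inherits(base, "skin_mask"))
  g <- base$grid
  ext <- g$origin + (g$shape - 1L) * g$spacing
  if (any(center < g$origin) || any(center > ext))
    stop("sphere center lies outside the grid")
  sel <- base$selected & .sphere_sel(g, center, spec$sphere_radius)
  structure(list(grid = g, selected = sel, n_selected = sum(sel)),
            class = "skin_mask")
}

.sphere_sel <- function(grid, center, radius) {
  ax <- grid_axes(grid)
  dx2 <- (ax[[1]] - center[1])^2
  dy2 <- (ax[[2]] - center[2])^2
  dz2 <- (ax[[3]] - center[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= radius^2
}

#' Hodgkin similarity index of two fields over a mask
#'
#' `SI = 2 * sum(a*b) / (sum(a^2) + sum(b^2))`, sums over the masked grid
#' points only. Ranges from -1 (anticorrelated) to +1 (fully correlated).
#' When both fields vanish on the mask the index is undefined -- that is a
#' distinct condition from SI = 0 (uncorrelated) and raises an error here;
#' the matrix-level drivers record it as a flagged entry instead.
#'
#' @param field_a,field_b `scalar_field`s on the mask's grid.
#' @param mask a `skin_mask` with at least one selected point.
#' @return scalar in `[-1, 1]`.
#' @export
hodgkin_si <- function(field_a, field_b, mask) {
  r <- .hodgkin_raw(field_a, field_b, mask, min_points = 1L)
  if (!r$defined)
    stop("undefined Hodgkin SI: both fields are identically zero on the mask")
  r$si
}

.hodgkin_raw <- function(field_a, field_b, mask, min_points = 1L) {
  stopifnot(inherits(field_a, "scalar_field"), inherits(field_b, "scalar_field"),
            inherits(mask, "skin_mask"))
  if (!grids_identical(field_a$grid, mask$grid) ||
      !grids_identical(field_b$grid, mask$grid))
    stop("fields and mask must share one grid")
  if (mask$n_selected < 1L) return(list(si = NA_real_, defined = FALSE, n = 0L))
  a <- field_a$values[mask$selected]
  b <- field_b$values[mask$selected]
  if (length(a) < min_points) return(list(si = NA_real_, defined = FALSE, n = length(a)))
  denom <- sum(a * a) + sum(b * b)
  if (denom == 0) return(list(si = NA_real_, defined = FALSE, n = length(a)))
  list(si = 2 * sum(a * b) / denom, defined = TRUE, n = length(a))
}

#' Similarity index to epogram distance
#'
#' `d = sqrt(2 - 2*SI)`: 0 for fully correlated fields (SI = +1) up to 2
#' for anticorrelated fields (SI = -1).
#'
#' @param si numeric in `[-1, 1]` (vectorised); values beyond the range by
#'   more than 1e-9 are a domain error, tiny excursions are clamped.
#' @return distances in `[0, 2]`.
#' @export
si_to_distance <- function(si) {
  if (any(!is.finite(si)) || any(si < -1 - 1e-9) || any(si > 1 + 1e-9))
    stop("similarity index outside [-1, 1]")
  si <- pmin(1, pmax(-1, si))
  sqrt(2 - 2 * si)
}

#' Construct a similarity matrix object
#' @param si symmetric numeric matrix of Hodgkin indices.
#' @param labels protein identifiers (rown/colnames).
#' @param field_kind `"electrostatic"` or `"hydrophobic"`.
#' @param scope `"global"` or a residue identifier.
#' @param defined logical matrix marking defined entries (default all).
#' @export
si_matrix <- function(si, labels, field_kind, scope = "global", defined = NULL) {
  si <- as.matrix(si)
  stopifnot(nrow(si) == ncol(si), length(labels) == nrow(si))
  if (is.null(defined)) defined <- !is.na(si)
  ok <- defined & !is.na(si)
  if (any(abs(si[ok]) > 1 + 1e-9)) stop("similarity entries must lie in [-1, 1]")
  if (any(abs(si[ok & t(ok)] - t(si)[ok & t(ok)]) > 1e-12))
    stop("similarity matrix must be symmetric")
  dimnames(si) <- list(labels, labels)
  dimnames(defined) <- list(labels, labels)
  structure(list(labels = labels, si = si, defined = defined,
                 field_kind = field_kind, scope = scope),
            class = "si_matrix")
}

#' @export
print.si_matrix <- function(x, ...) {
  cat(sprintf("si_matrix (%s, scope %s): %d proteins, %d undefined entries\n",
              x$field_kind, x$scope, length(x$labels), sum(!x$defined)))
  print(round(x$si, 3))
  invisible(x)
}

#' All-pairs global Hodgkin similarity matrix
#'
#' Computes every unordered pair's SI over the pair's combined skin:
#' by default the intersection of the two structures' skins (robust to
#' shape variation), alternatively their union or the first structure's
#' skin as a fixed reference.
#'
#' @param fields list of `scalar_field`s on one common grid, same kind.
#' @param structures matching list of `mif_structure`s (for the skins).
#' @param spec a `comparison_spec`.
#' @param mask_policy `"intersection"`, `"union"` or `"reference"`.
#' @return a `si_matrix` with scope `"global"`.
#' @export
pairwise_global <- function(fields, structures, spec = comparison_spec(),
                            mask_policy = c("intersection", "union", "reference")) {
  mask_policy <- match.arg(mask_policy)
  n <- length(fields)
  stopifnot(n >= 2, length(structures) == n)
  kinds <- unique(vapply(fields, `[[`, character(1), "kind"))
  if (length(kinds) != 1) stop("all fields must share one kind; got: ",
                               paste(kinds, collapse = ", "))
  g <- fields[[1]]$grid
  for (f in fields) if (!grids_identical(f$grid, g))
    stop("all fields must live on one common grid")
  labels <- vapply(structures, `[[`, character(1), "label")
  if (anyDuplicated(labels)) labels <- make.unique(labels)
  skins <- lapply(structures, skin_mask, grid = g, spec = spec)
  si <- diag(1, n); defined <- matrix(TRUE, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    m <- switch(mask_policy,
                intersection = combine_masks(skins[[i]], skins[[j]], "intersection"),
                union = combine_masks(skins[[i]], skins[[j]], "union"),
                reference = skins[[1]])
    r <- .hodgkin_raw(fields[[i]], fields[[j]], m, min_points = spec$min_points)
    si[i, j] <- si[j, i] <- r$si
    defined[i, j] <- defined[j, i] <- r$defined
  }
  # diagonal: defined iff the field is nonzero on its own skin
  for (i in seq_len(n)) {
    r <- .hodgkin_raw(fields[[i]], fields[[i]], skins[[i]],
                      min_points = spec$min_points)
    si[i, i] <- if (r$defined) 1 else NA_real_
    defined[i, i] <- r$defined
  }
  si_matrix(si, labels, kinds, scope = "global", defined = defined)
}

#' Per-residue spherical similarity scan
#'
#' For every residue, restricts each pair's comparison mask to a sphere of
#' `spec$sphere_radius` around the consensus C-alpha (the mean C-alpha
#' position across the cohort, or the first structure's) and computes the
#' pair's Hodgkin SI there. Spheres with fewer than `min_points` masked
#' points, or on which both fields vanish (e.g. all-clamped hydrophobic
#' regions), yield flagged undefined entries.
#'
#' @param fields list of `scalar_field`s on one common grid, same kind.
#' @param structures matching list of `mif_structure`s with equal residue
#'   counts and corresponding residue indexing.
#' @param spec a `comparison_spec`.
#' @param mask_policy as in [pairwise_global()].
#' @param consensus `"mean"` or `"first"` C-alpha sphere centres.
#' @return list of `si_matrix`, one per residue (scope `"residue:<k>"`).
#' @export
residue_scan <- function(fields, structures, spec = comparison_spec(),
                         mask_policy = c("intersection", "union", "reference"),
                         consensus = c("mean", "first")) {
  mask_policy <- match.arg(mask_policy)
  consensus <- match.arg(consensus)
  n <- length(fields)
  stopifnot(n >= 2, length(structures) == n)
  nres <- vapply(structures, n_residues, integer(1))
  if (length(unique(nres)) != 1)
    stop("structures have unequal residue counts (", paste(nres, collapse = ", "),
         "); supply a residue mapping / pre-aligned cohort")
  kinds <- unique(vapply(fields, `[[`, character(1), "kind"))
  if (length(kinds) != 1) stop("all fields must share one kind")
  g <- fields[[1]]$grid
  for (f in fields) if (!grids_identical(f$grid, g))
    stop("all fields must live on one common grid")
  labels <- vapply(structures, `[[`, character(1), "label")
  if (anyDuplicated(labels)) labels <- make.unique(labels)
  skins <- lapply(structures, skin_mask, grid = g, spec = spec)
  pair_masks <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    pair_masks[[paste(i, j)]] <- switch(mask_policy,
      intersection = combine_masks(skins[[i]], skins[[j]], "intersection"),
      union = combine_masks(skins[[i]], skins[[j]], "union"),
      reference = skins[[1]])
  }
  ca <- lapply(structures, calpha_coords)
  centers <- if (consensus == "mean") Reduce(`+`, ca) / n else ca[[1]]
  R <- nres[1]
  out <- vector("list", R)
  for (k in seq_len(R)) {
    sph <- .sphere_sel(g, centers[k, ], spec$sphere_radius)
    si <- diag(1, n); defined <- matrix(TRUE, n, n)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      pm <- pair_masks[[paste(i, j)]]
      sel <- pm$selected & sph
      m <- structure(list(grid = g, selected = sel, n_selected = sum(sel)),
                     class = "skin_mask")
      r <- .hodgkin_raw(fields[[i]], fields[[j]], m, min_points = spec$min_points)
      si[i, j] <- si[j, i] <- r$si
      defined[i, j] <- defined[j, i] <- r$defined
    }
    out[[k]] <- si_matrix(si, labels, kinds, scope = sprintf("residue:%d", k - 1L),
                          defined = defined)
  }
  out
}

#' Per-residue conservation profile
#'
#' Averages the defined upper-triangle SI values of each residue's
#' similarity matrix. A residue with no defined pair (for hydrophobic
#' fields: every sphere clamped to zero, i.e. a highly polar region) is
#' flagged and scored 0, mirroring the convention of blacking out regions
#' where no hydrophobic index exists.
#'
#' @param scan list of `si_matrix` from [residue_scan()].
#' @param conformation_tag free label carried into the profile.
#' @return an object of class `conservation_profile`: data.frame with
#'   `residue_index`, `score`, `flagged`, `n_pairs`.
#' @export
conservation_profile <- function(scan, conformation_tag = "") {
  stopifnot(length(scan) >= 1)
  field_kind <- scan[[1]]$field_kind
  rows <- lapply(seq_along(scan), function(k) {
    m <- scan[[k]]
    ut <- upper.tri(m$si)
    vals <- m$si[ut & m$defined]
    if (length(vals) == 0)
      data.frame(residue_index = k - 1L, score = 0, flagged = TRUE, n_pairs = 0L)
    else
      data.frame(residue_index = k - 1L, score = mean(vals), flagged = FALSE,
                 n_pairs = length(vals))
  })
  df <- do.call(rbind, rows)
  structure(list(profile = df, field_kind = field_kind,
                 conformation_tag = conformation_tag),
            class = "conservation_profile")
}

#' @export
print.conservation_profile <- function(x, ...) {
  ok <- !x$profile$flagged
  cat(sprintf("conservation_profile (%s%s): %d residues, %d flagged, mean SI %.3f\n",
              x$field_kind,
              if (nzchar(x$conformation_tag)) paste0(", ", x$conformation_tag) else "",
              nrow(x$profile), sum(x$profile$flagged),
              if (any(ok)) mean(x$profile$score[ok]) else NA_real_))
  invisible(x)
}

#' Write / read a similarity (or distance) matrix as TSV
#'
#' Tab-separated with a header row and a leading label column; undefined
#' entries are written as `NA`.
#' @param m a `si_matrix` or plain labelled matrix.
#' @param path file path.
#' @export
write_si_tsv <- function(m, path) {
  mat <- if (inherits(m, "si_matrix")) {
    x <- m$si; x[!m$defined] <- NA_real_; x
  } else as.matrix(m)
  df <- data.frame(label = rownames(mat), mat, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_si_tsv
#' @export
read_si_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                   stringsAsFactors = FALSE)
  mat <- as.matrix(df[, -1, drop = FALSE])
  rownames(mat) <- df[[1]]
  storage.mode(mat) <- "double"
  mat
}

#' Write a conservation profile as TSV
#' @param profile a `conservation_profile`.
#' @param path file path.
#' @export
write_profile_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "conservation_profile"))
  write.table(profile$profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
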