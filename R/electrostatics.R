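#' Solvent/dielectric model parameters
#'
#' Continuum-electrostatics settings for the linearized Poisson-Boltzmann
#' solve: a low-dielectric protein interior (default 4) embedded in water
#' (default 78) with 50 mM monovalent salt, the molecular surface defined
#' by a 1.4-Angstrom water probe, and a 2-Angstrom Stern (ion-exclusion)
#' layer outside the atoms.
#'
#' @param eps_interior protein dielectric constant.
#' @param eps_exterior solvent dielectric constant.
#' @param ionic_strength mol/L.
#' @param temperature Kelvin (enters the kT/e unit and the Debye length).
#' @param surface_probe_radius Angstrom; water probe defining the
#'   dielectric boundary.
#' @param stern_layer Angstrom; ion exclusion beyond atom radius + probe.
#' @return an object of class `solvent_spec`.
#' @export
solvent_spec <- function(eps_interior = 4.0, eps_exterior = 78.0,
                         ionic_strength = 0.050, temperature = 298.15,
                         surface_probe_radius = 1.4, stern_layer = 2.0) {
  vals <- c(eps_interior, eps_exterior, temperature, surface_probe_radius,
            stern_layer, ionic_strength)
  if (any(!is.finite(vals)) || eps_interior <= 0 || eps_exterior <= 0 ||
      temperature <= 0 || surface_probe_radius < 0 || stern_layer < 0 ||
      ionic_strength < 0)
    stop("solvent_spec parameters must be finite and non-negative (dielectrics > 0)")
  if (eps_exterior < eps_interior)
    stop("eps_exterior must be >= eps_interior")
  structure(list(eps_interior = eps_interior, eps_exterior = eps_exterior,
                 ionic_strength = ionic_strength, temperature = temperature,
                 surface_probe_radius = surface_probe_radius,
                 stern_layer = stern_layer),
            class = "solvent_spec")
}

#' Dielectric and ion-accessibility maps on a grid
#'
#' The dielectric boundary is the molecular (solvent-excluded) surface for
#' a spherical probe: a two-pass morphological construction first marks
#' nodes within `radius + probe` of any atom as solvent-excluded
#' candidates, then re-opens candidates that a probe-sized sphere centred
#' on free solvent can still reach. Nodes inside the resulting surface get
#' `eps_interior`, the rest `eps_exterior`. Ion accessibility is 0 within
#' `radius + probe + stern_layer` of any atom and 1 elsewhere.
#'
#' @param structure a `mif_structure`; every atom must lie inside the grid.
#' @param grid a `grid_spec`.
#' @param solvent a `solvent_spec`.
#' @return list with `eps` and `ion_acc`, both `scalar_field`s, plus the
#'   interior logical array as `interior`.
#' @export
build_dielectric_maps <- function(structure, grid, solvent = solvent_spec()) {
  stopifnot(inherits(structure, "mif_structure"), inherits(grid, "grid_spec"))
  at <- structure$atoms
  ax <- grid_axes(grid)
  ext <- grid$origin + (grid$shape - 1L) * grid$spacing
  if (any(at$x < grid$origin[1]) || any(at$x > ext[1]) ||
      any(at$y < grid$origin[2]) || any(at$y > ext[2]) ||
      any(at$z < grid$origin[3]) || any(at$z > ext[3]))
    stop("atom outside grid: enlarge the box or recentre it")
  probe <- solvent$surface_probe_radius
  stern <- solvent$stern_layer
  cutoff <- probe + stern + grid$spacing
  gap <- min_gap_field(structure, grid, cutoff)
  # pass 1: probe-inflated union of spheres = solvent-excluded candidates
  candidate <- gap <= probe
  if (probe > 0) {
    # pass 2: re-open candidates reachable by a probe centred on free solvent
    solv_reach <- .dilate_mask(!candidate, probe, grid$spacing)
    interior <- candidate & !solv_reach
    # atom cores always interior regardless of re-opening
    interior <- interior | (gap <= 0)
  } else {
    interior <- candidate
  }
  eps <- array(solvent$eps_exterior, dim = grid$shape)
  eps[interior] <- solvent$eps_interior
  ion <- array(1, dim = grid$shape)
  ion[gap <= probe + stern] <- 0
  list(eps = scalar_field(grid, eps, units = "", kind = "dielectric"),
       ion_acc = scalar_field(grid, ion, units = "", kind = "ion_accessibility"),
       interior = interior)
}

# binary dilation of a logical 3-D array by a digital sphere of radius r (A)
.dilate_mask <- function(mask, r, spacing) {
  n <- floor(r / spacing)
  offs <- expand.grid(dx = -n:n, dy = -n:n, dz = -n:n)
  offs <- offs[offs$dx^2 + offs$dy^2 + offs$dz^2 <= (r / spacing)^2, , drop = FALSE]
  sh <- dim(mask)
  out <- array(FALSE, dim = sh)
  for (i in seq_len(nrow(offs))) {
    sx <- .shift_idx(sh[1], offs$dx[i]); sy <- .shift_idx(sh[2], offs$dy[i])
    sz <- .shift_idx(sh[3], offs$dz[i])
    out[sx$dst, sy$dst, sz$dst] <- out[sx$dst, sy$dst, sz$dst] |
      mask[sx$src, sy$src, sz$src]
  }
  out
}

.shift_idx <- function(n, d) {
  if (d >= 0) list(dst = (1 + d):n, src = 1:(n - d))
  else list(dst = 1:(n + d), src = (1 - d):n)
}

# trilinear spreading of point charges onto grid nodes (e per node)
.spread_charges <- function(structure, grid) {
  at <- structure$atoms
  q <- array(0, dim = grid$shape)
  h <- grid$spacing
  charged <- which(at$charge != 0)
  for (i in charged) {
    f <- (c(at$x[i], at$y[i], at$z[i]) - grid$origin) / h
    i0 <- floor(f)
    w1 <- f - i0
    w0 <- 1 - w1
    i0 <- as.integer(i0) + 1L  # 1-based lower node
    if (any(i0 < 2L) || any(i0 + 1L > grid$shape - 1L))
      stop("charged atom too close to the grid boundary for charge spreading")
    wx <- c(w0[1], w1[1]); wy <- c(w0[2], w1[2]); wz <- c(w0[3], w1[3])
    for (a in 0:1) for (b in 0:1) for (cc in 0:1) {
      q[i0[1] + a, i0[2] + b, i0[3] + cc] <-
        q[i0[1] + a, i0[2] + b, i0[3] + cc] +
        at$charge[i] * wx[a + 1] * wy[b + 1] * wz[cc + 1]
    }
  }
  q
}

# Debye-Hueckel boundary values: sum over charges of C q exp(-kappa d)/(eps d)
.dh_boundary <- function(structure, grid, solvent) {
  at <- structure$atoms
  charged <- at[at$charge != 0, , drop = FALSE]
  sh <- grid$shape
  bc <- array(0, dim = sh)
  if (!nrow(charged)) return(bc)
  C <- coulomb_kT(solvent$temperature)
  kap <- sqrt(debye_kappa2(solvent$ionic_strength, solvent$eps_exterior,
                           solvent$temperature))
  ax <- grid_axes(grid)
  face_fill <- function(ix, iy, iz) {
    pts <- as.matrix(expand.grid(x = ax[[1]][ix], y = ax[[2]][iy], z = ax[[3]][iz]))
    v <- numeric(nrow(pts))
    for (i in seq_len(nrow(charged))) {
      d <- sqrt((pts[, 1] - charged$x[i])^2 + (pts[, 2] - charged$y[i])^2 +
                (pts[, 3] - charged$z[i])^2)
      d <- pmax(d, 1e-6)
      v <- v + C * charged$charge[i] * exp(-kap * d) / (solvent$eps_exterior * d)
    }
    array(v, dim = c(length(ix), length(iy), length(iz)))
  }
  bc[1, , ] <- face_fill(1L, seq_len(sh[2]), seq_len(sh[3]))
  bc[sh[1], , ] <- face_fill(sh[1], seq_len(sh[2]), seq_len(sh[3]))
  bc[, 1, ] <- face_fill(seq_len(sh[1]), 1L, seq_len(sh[3]))
  bc[, sh[2], ] <- face_fill(seq_len(sh[1]), sh[2], seq_len(sh[3]))
  bc[, , 1] <- face_fill(seq_len(sh[1]), seq_len(sh[2]), 1L)
  bc[, , sh[3]] <- face_fill(seq_len(sh[1]), seq_len(sh[2]), sh[3])
  bc
}

#' Solve the linearized Poisson-Boltzmann equation on a grid
#'
#' Finite-difference solution of `div(eps grad phi) - eps_ext kappa^2
#' lambda(r) phi = -4 pi C rho` with the 7-point stencil, harmonic-mean
#' interface dielectrics, trilinear charge spreading, Dirichlet boundary
#' values from per-charge Debye-Hueckel potentials, and red-black
#' successive over-relaxation. The returned potential is in kT/e at the
#' solvent temperature.
#'
#' @param structure a `mif_structure`.
#' @param grid a `grid_spec`; defaults to [default_grid()] around the
#'   structure at 1 Angstrom spacing.
#' @param solvent a `solvent_spec`.
#' @param tol relative residual target (L2, against the source norm), in
#'   (0, 1).
#' @param max_iter iteration cap.
#' @param omega SOR relaxation factor; `NULL` picks `2/(1+sin(pi/n))` for
#'   the largest grid dimension n.
#' @return a `scalar_field` of kind `"electrostatic"` with attributes
#'   `iterations`, `residual` and `converged`.
#' @export
solve_lpbe <- function(structure, grid = NULL, solvent = solvent_spec(),
                       tol = 1e-5, max_iter = 10000L, omega = NULL) {
  stopifnot(inherits(structure, "mif_structure"))
  if (is.null(grid)) grid <- default_grid(structure)
  if (!(tol > 0 && tol < 1)) stop("tol must be in (0, 1)")
  maps <- build_dielectric_maps(structure, grid, solvent)
  h <- grid$spacing
  C <- coulomb_kT(solvent$temperature)
  kap2 <- debye_kappa2(solvent$ionic_strength, solvent$eps_exterior,
                       solvent$temperature)
  qgrid <- .spread_charges(structure, grid)
  src <- 4 * pi * C * qgrid / h          # volume-integrated source / h
  kbar <- solvent$eps_exterior * kap2 * maps$ion_acc$values
  u0 <- .dh_boundary(structure, grid, solvent)
  if (is.null(omega)) omega <- 2 / (1 + sin(pi / max(grid$shape)))
  res <- sor_lpbe_cpp(maps$eps$values, kbar, src, u0, h, omega,
                      tol, as.integer(max_iter), 10L)
  if (isTRUE(res$diverged))
    stop("LPBE solver diverged; residual trace: ",
         paste(signif(res$residual_trace, 4), collapse = " "))
  phi <- scalar_field(grid, res$u, units = "kT/e", kind = "electrostatic")
  attr(phi, "iterations") <- res$iterations
  attr(phi, "residual") <- res$residual
  attr(phi, "converged") <- res$converged
  phi
}
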