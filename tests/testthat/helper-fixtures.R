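# shared fixture builders: tiny structures, grids and fields built in code

point_structure <- function(charge = 1, radius = 0.5, pos = c(0, 0, 0),
                            label = "point") {
  mif_structure(data.frame(x = pos[1], y = pos[2], z = pos[3],
                           charge = charge, radius = radius, name = "CA",
                           residue_index = 0L, residue_name = "GLY"),
                label = label)
}

# uniform-dielectric solvent: no surface, no Stern layer; for closed-form
# point-charge oracles
uniform_solvent <- function(ionic_strength = 0) {
  solvent_spec(eps_interior = 78, eps_exterior = 78,
               ionic_strength = ionic_strength,
               surface_probe_radius = 0, stern_layer = 0)
}

cube_grid <- function(n, spacing = 1) {
  half <- (n - 1) / 2 * spacing
  grid_spec(c(-half, -half, -half), spacing, c(n, n, n))
}

rand_field <- function(grid, seed = 1, kind = "electrostatic") {
  set.seed(seed)
  scalar_field(grid, array(rnorm(prod(grid$shape)), dim = grid$shape),
               kind = kind)
}

rand_mask <- function(grid, seed = 1, frac = 0.3) {
  set.seed(seed)
  sel <- array(runif(prod(grid$shape)) < frac, dim = grid$shape)
  structure(list(grid = grid, selected = sel, n_selected = sum(sel)),
            class = "skin_mask")
}

# radial distance of every node from a centre
node_dist <- function(grid, center = c(0, 0, 0)) {
  ax <- grid_axes(grid)
  sqrt(outer(outer((ax[[1]] - center[1])^2, (ax[[2]] - center[2])^2, "+"),
             (ax[[3]] - center[3])^2, "+"))
}

# a pair of decorated backbones that differ by one flipped charge
flipped_charge_pair <- function(n_residues = 30L, charge_sites = c(2L, 8L, 14L, 20L, 26L),
                                flip_at = 2L) {
  bb <- make_backbone(n_residues)
  q <- rep_len(c(1, -1), length(charge_sites))
  a <- decorate_charges(bb, data.frame(residue_index = charge_sites, charge = q))
  q2 <- q
  q2[charge_sites == flip_at] <- -q2[charge_sites == flip_at]
  b <- decorate_charges(bb, data.frame(residue_index = charge_sites, charge = q2))
  a$label <- "A"; b$label <- "B"
  list(a = a, b = b)
}
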