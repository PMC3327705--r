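test_that("zero-probe dielectric interior is exactly the union of atom spheres", {
  s <- point_structure(radius = 2)
  g <- cube_grid(33)
  sol <- solvent_spec(surface_probe_radius = 0, stern_layer = 0)
  maps <- build_dielectric_maps(s, g, sol)
  # brute-force point-in-sphere oracle
  inside <- node_dist(g) <= 2
  expect_identical(maps$interior, inside)
  expect_equal(unique(maps$eps$values[inside]), sol$eps_interior)
  expect_equal(unique(maps$eps$values[!inside]), sol$eps_exterior)
})

test_that("molecular-surface maps have the right far field and ion exclusion", {
  s <- point_structure(radius = 2)
  g <- cube_grid(41)
  sol <- solvent_spec()  # probe 1.4, stern 2.0
  maps <- build_dielectric_maps(s, g, sol)
  d <- node_dist(g)
  expect_equal(maps$eps$values[d > 14.9], rep(78, sum(d > 14.9)))
  # interior region approximates the 2 A sphere after probe roll-back
  expect_equal(unique(maps$eps$values[d <= 1.5]), 4)
  # ion accessibility: 0 within radius + probe + stern, 1 well outside
  expect_true(all(maps$ion_acc$values[d <= 2 + 1.4 + 2.0] == 0))
  expect_true(all(maps$ion_acc$values[d > 2 + 1.4 + 2.0 + 1] == 1))
})

test_that("structures hugging the box edge raise a geometry error", {
  s <- point_structure(pos = c(20, 0, 0))
  g <- cube_grid(33)  # extends to 16
  expect_error(build_dielectric_maps(s, g, solvent_spec()), "outside grid")
})

test_that("a charge-free structure yields the identically zero potential", {
  s <- point_structure(charge = 0, radius = 1.7)
  phi <- solve_lpbe(s, cube_grid(17), uniform_solvent())
  expect_identical(unique(as.vector(phi$values)), 0)
})

test_that("point charge in uniform eps=78 matches Coulomb within 5% (<=3% refined)", {
  s <- point_structure(charge = 1, radius = 0.5)
  g <- cube_grid(49)
  phi <- solve_lpbe(s, g, uniform_solvent(0), tol = 1e-6)
  expect_true(attr(phi, "converged"))
  C <- mifscan:::coulomb_kT(298.15)
  r <- node_dist(g)
  sel <- r >= 10 & r <= 16
  rel <- abs(phi$values[sel] - C / (78 * r[sel])) / (C / (78 * r[sel]))
  expect_lt(max(rel), 0.05)
  # halving the spacing tightens the Coulomb error bound
  phi2 <- solve_lpbe(s, refine_grid(g, 2L), uniform_solvent(0), tol = 1e-6)
  r2 <- node_dist(phi2$grid)
  sel2 <- r2 >= 10 & r2 <= 16
  rel2 <- abs(phi2$values[sel2] - C / (78 * r2[sel2])) / (C / (78 * r2[sel2]))
  expect_lt(max(rel2), 0.03)
  expect_lt(max(rel2), max(rel))
})

test_that("50 mM salt reproduces the Debye-Hueckel closed form within 5%", {
  s <- point_structure(charge = 1, radius = 0.5)
  g <- cube_grid(49)
  phi <- solve_lpbe(s, g, uniform_solvent(0.050), tol = 1e-6)
  C <- mifscan:::coulomb_kT(298.15)
  kap <- sqrt(mifscan:::debye_kappa2(0.050, 78, 298.15))
  # 50 mM monovalent salt in water: Debye length ~13.6 A
  expect_equal(1 / kap, 13.56, tolerance = 0.01)
  r <- node_dist(g)
  sel <- r >= 10 & r <= 16
  dh <- C * exp(-kap * r[sel]) / (78 * r[sel])
  expect_lt(max(abs(phi$values[sel] - dh) / dh), 0.05)
})

test_that("the LPBE operator is linear: negation, scaling, superposition", {
  bb <- make_backbone(8)
  s <- decorate_charges(bb, data.frame(residue_index = c(1L, 5L), charge = c(1, -1)))
  g <- default_grid(s, spacing = 1)
  tol <- 1e-6
  phi <- solve_lpbe(s, g, solvent_spec(), tol = tol)
  sneg <- s; sneg$atoms$charge <- -sneg$atoms$charge
  s2 <- s; s2$atoms$charge <- 2 * s2$atoms$charge
  phin <- solve_lpbe(sneg, g, solvent_spec(), tol = tol)
  phi2 <- solve_lpbe(s2, g, solvent_spec(), tol = tol)
  scale <- max(abs(phi$values))
  expect_lt(max(abs(phin$values + phi$values)) / scale, 10 * tol)
  expect_lt(max(abs(phi2$values - 2 * phi$values)) / scale, 10 * tol)

  # superposition: split the charge pattern into its two sites
  charged <- which(s$atoms$charge != 0)
  qa <- s; qa$atoms$charge <- ifelse(seq_along(s$atoms$charge) == charged[1],
                                     s$atoms$charge, 0)
  qb <- s; qb$atoms$charge <- ifelse(seq_along(s$atoms$charge) == charged[2],
                                     s$atoms$charge, 0)
  pa <- solve_lpbe(qa, g, solvent_spec(), tol = tol)
  pb <- solve_lpbe(qb, g, solvent_spec(), tol = tol)
  expect_lt(max(abs(pa$values + pb$values - phi$values)) / scale, 10 * tol)
})

test_that("boundary faces carry the analytic Debye-Hueckel values", {
  s <- point_structure(charge = 1, radius = 1.0)
  g <- cube_grid(17)
  sol <- solvent_spec()
  phi <- solve_lpbe(s, g, sol)
  C <- mifscan:::coulomb_kT(sol$temperature)
  kap <- sqrt(mifscan:::debye_kappa2(sol$ionic_strength, sol$eps_exterior,
                                     sol$temperature))
  ax <- grid_axes(g)
  d <- sqrt(ax[[1]][1]^2 + outer(ax[[2]]^2, ax[[3]]^2, "+"))  # x = min face
  face <- C * exp(-kap * d) / (sol$eps_exterior * d)
  expect_equal(phi$values[1, , ], face, tolerance = 1e-12)
})

test_that("potential magnitude decays monotonically beyond the ion-exclusion shell", {
  s <- point_structure(charge = 1, radius = 1.0)
  g <- cube_grid(41)
  phi <- solve_lpbe(s, g, solvent_spec())
  r <- node_dist(g)
  shells <- cut(r[r >= 6 & r <= 18], breaks = seq(6, 18, by = 2))
  means <- tapply(abs(phi$values[r >= 6 & r <= 18]), shells, mean)
  expect_true(all(diff(means) < 0))
})
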