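test_that("identical structures scan to all-ones matrices and a constant profile", {
  bb <- make_backbone(10)
  s <- decorate_charges(bb, data.frame(residue_index = c(1L, 5L, 8L),
                                       charge = c(1, -1, 1)))
  s2 <- s; s2$label <- "copy"
  g <- default_grid(s, spacing = 1)
  f <- solve_lpbe(s, g, solvent_spec())
  spec <- comparison_spec(min_points = 10L)
  scan <- residue_scan(list(f, f), list(s, s2), spec)
  expect_length(scan, 10L)
  for (m in scan) if (all(m$defined)) expect_equal(unname(m$si), matrix(1, 2, 2))
  prof <- conservation_profile(scan)
  expect_true(all(prof$profile$score[!prof$profile$flagged] == 1))
})

test_that("a sphere covering the grid reproduces the global comparison exactly", {
  pair <- flipped_charge_pair(n_residues = 12L, charge_sites = c(1L, 5L, 9L),
                              flip_at = 1L)
  g <- default_grid(list(pair$a, pair$b), spacing = 1)
  fa <- solve_lpbe(pair$a, g, solvent_spec())
  fb <- solve_lpbe(pair$b, g, solvent_spec())
  diam <- sqrt(sum(((g$shape - 1) * g$spacing)^2))
  spec <- comparison_spec(sphere_radius = 2 * diam, min_points = 10L)
  glob <- pairwise_global(list(fa, fb), list(pair$a, pair$b), spec)
  scan <- residue_scan(list(fa, fb), list(pair$a, pair$b), spec)
  for (m in scan)
    expect_equal(m$si["A", "B"], glob$si["A", "B"], tolerance = 1e-12)
})

test_that("a flipped charge depresses local similarity near the perturbed residue", {
  pair <- flipped_charge_pair(n_residues = 30L,
                              charge_sites = c(2L, 8L, 14L, 20L, 26L),
                              flip_at = 2L)
  g <- default_grid(list(pair$a, pair$b), spacing = 1)
  fa <- solve_lpbe(pair$a, g, solvent_spec())
  fb <- solve_lpbe(pair$b, g, solvent_spec())
  spec <- comparison_spec(min_points = 10L)
  scan <- residue_scan(list(fa, fb), list(pair$a, pair$b), spec)
  si <- vapply(scan, function(m) m$si["A", "B"], numeric(1))
  ca <- calpha_coords(pair$a)
  dist_from_flip <- sqrt(rowSums((ca - matrix(ca[3, ], nrow(ca), 3, byrow = TRUE))^2))
  far <- which(dist_from_flip > 25)
  expect_gt(length(far), 0)
  expect_true(all(si[3] < si[far]))
  # direct field differencing confirms the perturbation is local
  dphi <- abs(fa$values - fb$values)
  near_sel <- node_dist(g, ca[3, ]) < 10
  far_sel <- node_dist(g, ca[far[1], ]) < 10
  expect_gt(max(dphi[near_sel]), 10 * max(dphi[far_sel]))
})

test_that("all-clamped hydrophobic spheres are flagged and scored zero", {
  # polar-only structures: the DRY surrogate clamps everything to zero
  bb <- make_backbone(8)
  at <- bb$atoms
  at$residue_name <- "UNK"
  at$name[at$name == "CA"] <- "NA1"
  at$name[at$name == "CB"] <- "OD1"
  at$is_calpha <- bb$atoms$is_calpha
  s1 <- mif_structure(at, "p1"); s2 <- mif_structure(at, "p2")
  g <- default_grid(s1, spacing = 1)
  f1 <- dry_field(s1, grid = g, params = hydrophobic_params(spacing = 1))
  f2 <- dry_field(s2, grid = g, params = hydrophobic_params(spacing = 1))
  expect_identical(unique(as.vector(f1$values)), 0)
  scan <- residue_scan(list(f1, f2), list(s1, s2), comparison_spec(min_points = 10L))
  expect_true(all(vapply(scan, function(m) !m$defined["p1", "p2"], logical(1))))
  prof <- conservation_profile(scan)
  expect_true(all(prof$profile$flagged))
  expect_true(all(prof$profile$score == 0))
})

test_that("conservation scores average the defined upper-triangle indices", {
  mk <- function(si12, si13, si23, defined = TRUE) {
    si <- diag(1, 3)
    si[1, 2] <- si[2, 1] <- si12
    si[1, 3] <- si[3, 1] <- si13
    si[2, 3] <- si[3, 2] <- si23
    si_matrix(si, c("a", "b", "c"), "electrostatic", scope = "residue:0")
  }
  prof <- conservation_profile(list(mk(1.0, 0.5, 0.0)))
  expect_equal(prof$profile$score, 0.5)
  # two-protein scan: profile equals the single pairwise SI
  si <- matrix(c(1, 0.37, 0.37, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  prof2 <- conservation_profile(list(si_matrix(si, c("a", "b"), "electrostatic")))
  expect_equal(prof2$profile$score, 0.37)
})

test_that("unequal residue counts are an alignment error", {
  a <- make_backbone(8); b <- make_backbone(9)
  g <- default_grid(list(a, b), spacing = 1)
  f <- scalar_field(g, array(1, dim = g$shape))
  expect_error(residue_scan(list(f, f), list(a, b)), "residue mapping|unequal")
})
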