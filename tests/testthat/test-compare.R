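test_that("skin selection matches a brute-force distance check", {
  s <- point_structure(radius = 1.5)
  g <- cube_grid(17)
  spec <- comparison_spec(skin_probe = 2, skin_thickness = 3)
  m <- skin_mask(s, g, spec)
  d <- node_dist(g)
  oracle <- d - 1.5 >= 2 & d - 1.5 <= 5  # centre distance in [3.5, 6.5]
  expect_identical(m$selected, oracle)
  expect_identical(m$n_selected, sum(oracle))
  # identical structures give bitwise-identical masks
  m2 <- skin_mask(point_structure(radius = 1.5), g, spec)
  expect_identical(m$selected, m2$selected)
})

test_that("a vanishing skin raises a degenerate-skin error", {
  s <- point_structure(radius = 1.5)
  expect_error(skin_mask(s, cube_grid(9), comparison_spec(skin_thickness = 0.01)),
               "degenerate skin")
})

test_that("sphere restriction behaves as base AND ball, verified brute force", {
  s <- point_structure(radius = 1.5)
  g <- cube_grid(17)
  base <- skin_mask(s, g, comparison_spec())
  # radius covering the whole grid returns the base unchanged
  big <- sphere_mask(base, c(0, 0, 0), comparison_spec(sphere_radius = 100))
  expect_identical(big$selected, base$selected)
  # off-centre sphere: brute-force count
  ctr <- c(4, 3, -2)
  sm <- sphere_mask(base, ctr, comparison_spec(sphere_radius = 5))
  oracle <- base$selected & node_dist(g, ctr) <= 5
  expect_identical(sm$selected, oracle)
  # centred far from the skin shell: empty mask, no error
  empty <- sphere_mask(base, c(7.5, 7.5, 7.5), comparison_spec(sphere_radius = 1))
  expect_identical(empty$n_selected, 0L)
  # monotonicity in the radius
  n <- vapply(c(2, 4, 6, 8), function(r)
    sphere_mask(base, c(0, 0, 0), comparison_spec(sphere_radius = r))$n_selected,
    integer(1))
  expect_true(all(diff(n) >= 0))
})

test_that("Hodgkin index obeys its algebraic identities on random fields", {
  g <- cube_grid(11)
  for (seed in 1:5) {
    f <- rand_field(g, seed)
    mask <- rand_mask(g, seed + 100)
    fneg <- scalar_field(g, -f$values)
    f2 <- scalar_field(g, 2 * f$values)
    expect_equal(hodgkin_si(f, f, mask), 1, tolerance = 1e-12)
    expect_equal(hodgkin_si(f, fneg, mask), -1, tolerance = 1e-12)
    expect_equal(hodgkin_si(f, f2, mask), 0.8, tolerance = 1e-12)  # 2k/(1+k^2), k=2
    # Cauchy-Schwarz keeps the index in bounds
    a <- f$values[mask$selected]; b <- rand_field(g, seed + 200)$values[mask$selected]
    expect_lte(abs(2 * sum(a * b)), sum(a^2) + sum(b^2))
  }
})

test_that("the undefined index (both fields zero on the mask) is an error, not 0", {
  g <- cube_grid(11)
  z <- scalar_field(g, array(0, dim = g$shape))
  expect_error(hodgkin_si(z, z, rand_mask(g, 1)), "undefined")
  # one-sided zero is defined and equals 0
  expect_equal(hodgkin_si(z, rand_field(g, 1), rand_mask(g, 1)), 0)
})

test_that("the SI-to-distance transform hits its endpoints exactly", {
  expect_identical(si_to_distance(-1), 2)
  expect_identical(si_to_distance(1), 0)
  expect_identical(si_to_distance(0), sqrt(2))
  expect_error(si_to_distance(1.1), "outside")
  expect_error(si_to_distance(-1.0000001), "outside")
  # tiny numerical excursions are clamped, not fatal
  expect_identical(si_to_distance(1 + 1e-12), 0)
})

test_that("pairwise_global reproduces hodgkin identities matrix-wide", {
  bb <- make_backbone(8)
  s <- decorate_charges(bb, data.frame(residue_index = c(0L, 4L), charge = c(1, -1)))
  g <- default_grid(s, spacing = 1)
  f <- solve_lpbe(s, g, solvent_spec())
  fneg <- scalar_field(g, -f$values)
  strs <- list(s, s, s)
  strs[[1]]$label <- "a"; strs[[2]]$label <- "b"; strs[[3]]$label <- "c"
  m <- pairwise_global(list(f, fneg, f), strs, comparison_spec())
  expect_equal(unname(m$si),
               matrix(c(1, -1, 1, -1, 1, -1, 1, -1, 1), 3), tolerance = 1e-12)
  # mixed field kinds are refused
  h <- scalar_field(g, pmin(f$values, 0), units = "kcal/mol", kind = "hydrophobic")
  expect_error(pairwise_global(list(f, h), strs[1:2], comparison_spec()), "kind")
})

test_that("graded charge scaling yields the algebraic SI ladder through the solver", {
  bb <- make_backbone(10)
  base <- decorate_charges(bb, data.frame(residue_index = c(1L, 4L, 7L),
                                          charge = c(1, -1, 1)))
  scale_structure <- function(s, k, lab) {
    s$atoms$charge <- s$atoms$charge * k; s$label <- lab; s
  }
  strs <- list(scale_structure(base, 1, "s1"),
               scale_structure(base, 0.5, "s05"),
               scale_structure(base, 0.25, "s025"))
  g <- default_grid(strs, spacing = 1)
  fields <- lapply(strs, solve_lpbe, grid = g, solvent = solvent_spec())
  m <- pairwise_global(fields, strs, comparison_spec())
  expect_equal(m$si["s1", "s05"], 2 * 0.5 / (1 + 0.25), tolerance = 1e-12)
  expect_equal(m$si["s05", "s025"], 2 * 0.5 / (1 + 0.25), tolerance = 1e-12)
  expect_equal(m$si["s1", "s025"], 2 * 0.25 / (1 + 0.0625), tolerance = 1e-12)
})

test_that("similarity matrices round-trip through TSV", {
  si <- matrix(c(1, 0.5, 0.5, 1), 2, dimnames = list(c("a", "b"), c("a", "b")))
  m <- si_matrix(si, c("a", "b"), "electrostatic")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_si_tsv(m, p)
  expect_equal(read_si_tsv(p), si)
})
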