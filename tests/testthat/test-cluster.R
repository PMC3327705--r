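si_from_d <- function(d) 1 - d^2 / 2  # inverse of d = sqrt(2 - 2 si)

test_that("UPGMA reproduces hand-computed merge heights on a 4-leaf matrix", {
  # d(A,B) = 0.2, d(C,D) = 0.3, all cross distances 1.0
  d <- matrix(1, 4, 4, dimnames = list(LETTERS[1:4], LETTERS[1:4]))
  diag(d) <- 0
  d["A", "B"] <- d["B", "A"] <- 0.2
  d["C", "D"] <- d["D", "C"] <- 0.3
  m <- si_matrix(si_from_d(d), LETTERS[1:4], "electrostatic")
  epo <- build_epogram(m, linkage = "upgma")
  expect_equal(sort(epo$heights), c(0.1, 0.15, 0.5), tolerance = 1e-12)
  # ultrametric tree depths agree: root at max height
  depths <- ape::node.depth.edgelength(epo$phylo)
  expect_equal(max(depths), 0.5, tolerance = 1e-12)
  # (A,B) is the first clade
  cl <- cut_epogram(epo, 3)
  expect_identical(cl[["A"]], cl[["B"]])
  expect_false(cl[["C"]] == cl[["D"]] && cl[["C"]] == cl[["A"]])
})

test_that("a zero-distance pair forms the first clade at height zero", {
  d <- matrix(1, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  diag(d) <- 0
  d["A", "B"] <- d["B", "A"] <- 0
  epo <- build_epogram(si_matrix(si_from_d(d), c("A", "B", "C"), "electrostatic"))
  expect_equal(min(epo$heights), 0)
  cl <- cut_epogram(epo, 2)
  expect_identical(cl[["A"]], cl[["B"]])
})

test_that("epograms are invariant to the input label order", {
  set.seed(11)
  n <- 6
  si <- matrix(0, n, n)
  si[upper.tri(si)] <- runif(n * (n - 1) / 2, -0.5, 0.9)
  si <- si + t(si); diag(si) <- 1
  labs <- paste0("p", 1:n)
  dimnames(si) <- list(labs, labs)
  e1 <- build_epogram(si_matrix(si, labs, "electrostatic"))
  perm <- c(4, 2, 6, 1, 3, 5)
  e2 <- build_epogram(si_matrix(si[perm, perm], labs[perm], "electrostatic"))
  c1 <- stats::cophenetic(e1$hclust); c2 <- stats::cophenetic(e2$hclust)
  expect_equal(as.matrix(c1)[labs, labs], as.matrix(c2)[labs, labs])
  expect_identical(ape::write.tree(e1$phylo), ape::write.tree(e2$phylo))
})

test_that("undefined similarity entries block clustering with a clear error", {
  si <- diag(1, 3)
  si[1, 2] <- si[2, 1] <- NA
  si[1, 3] <- si[3, 1] <- 0.5; si[2, 3] <- si[3, 2] <- 0.5
  labs <- c("a", "b", "c")
  dimnames(si) <- list(labs, labs)
  m <- si_matrix(si, labs, "electrostatic",
                 defined = !is.na(si))
  expect_error(build_epogram(m), "undefined")
})

test_that("heatmaps order by the dendrogram and round-trip through TSV", {
  d <- matrix(1, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  diag(d) <- 0
  d["A", "C"] <- d["C", "A"] <- 0.1  # A and C cluster first
  m <- si_matrix(si_from_d(d), c("A", "B", "C"), "electrostatic")
  epo <- build_epogram(m)
  p <- withr::local_tempfile(fileext = ".tsv")
  ordered <- mif_heatmap(m, epo, p)
  leaf <- epo$hclust$labels[epo$hclust$order]
  expect_identical(rownames(ordered), leaf)
  expect_true(which(leaf == "A") %in% c(which(leaf == "C") - 1, which(leaf == "C") + 1))
  back <- read_si_tsv(p)
  expect_equal(back, ordered, tolerance = 1e-9)

  # identity cohort: uniform zero-distance map
  si1 <- matrix(1, 3, 3, dimnames = dimnames(d))
  m1 <- si_matrix(si1, c("A", "B", "C"), "electrostatic")
  o1 <- mif_heatmap(m1, build_epogram(m1), withr::local_tempfile(fileext = ".tsv"))
  expect_true(all(o1 == 0))
  # anticorrelated pair sits at the maximum distance 2
  si2 <- matrix(c(1, -1, -1, 1), 2, dimnames = list(c("A", "B"), c("A", "B")))
  m2 <- si_matrix(si2, c("A", "B"), "electrostatic")
  o2 <- mif_heatmap(m2, build_epogram(m2), withr::local_tempfile(fileext = ".tsv"))
  expect_identical(o2["A", "B"], 2)
})

test_that("conservation colours hit their endpoints and black out flagged residues", {
  df <- data.frame(residue_index = 0:3, score = c(1, -1, 0, 0),
                   flagged = c(FALSE, FALSE, FALSE, TRUE), n_pairs = c(3, 3, 3, 0))
  prof <- structure(list(profile = df, field_kind = "electrostatic",
                         conformation_tag = ""), class = "conservation_profile")
  col <- color_profile(prof)
  expect_identical(col$color[1], "#FF0000")  # conserved end
  expect_identical(col$color[2], "#0000FF")  # variable end
  expect_identical(col$color[4], "#000000")  # flagged
  # hydrophobic profiles map [0, 1]
  profh <- structure(list(profile = df[1:3, ], field_kind = "hydrophobic",
                          conformation_tag = ""), class = "conservation_profile")
  colh <- color_profile(profh)
  expect_identical(colh$color[1], "#FF0000")
  expect_identical(colh$color[3], "#0000FF")  # 0 is the variable end for HIF
})
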