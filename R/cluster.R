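#' Build an epogram (field-similarity dendrogram)
#'
#' Converts the similarity matrix to distances `d = sqrt(2 - 2*SI)` and
#' clusters agglomeratively, UPGMA (average linkage) by default. Labels
#' are sorted before linkage so the result is invariant to input order;
#' equal-distance merges are thereby resolved deterministically. Node
#' heights follow the ultrametric convention: a pair merging at distance d
#' sits under a node of height d/2 (so leaf-to-leaf cophenetic distance
#' equals the merge distance).
#'
#' @param matrix a `si_matrix` with all entries defined, or a plain
#'   labelled similarity matrix.
#' @param linkage `"upgma"` (alias `"average"`), `"single"` or
#'   `"complete"`.
#' @return an object of class `epogram`: list with `phylo` (ape tree),
#'   `hclust`, `heights` (merge heights, distance/2), `labels`, `linkage`.
#' @export
build_epogram <- function(matrix, linkage = c("upgma", "average", "single", "complete")) {
  linkage <- match.arg(linkage)
  method <- if (linkage %in% c("upgma", "average")) "average" else linkage
  if (inherits(matrix, "si_matrix")) {
    if (!all(matrix$defined))
      stop("similarity matrix has undefined entries; impute or drop those proteins first")
    si <- matrix$si
  } else {
    si <- as.matrix(matrix)
    if (anyNA(si))
      stop("similarity matrix has undefined entries; impute or drop those proteins first")
  }
  if (nrow(si) < 2) stop("need at least 2 proteins to cluster")
  if (is.null(rownames(si))) rownames(si) <- colnames(si) <- paste0("p", seq_len(nrow(si)))
  d <- matrix(si_to_distance(pmin(si, 1)), nrow(si), ncol(si),
              dimnames = dimnames(si))
  diag(d) <- 0
  ord <- order(rownames(d))
  d <- d[ord, ord]
  hc <- hclust(as.dist(d), method = method)
  ph <- ape::as.phylo(hc)  # leaf depth = merge height / 2 (ultrametric)
  structure(list(phylo = ph, hclust = hc, heights = hc$height / 2,
                 labels = hc$labels, linkage = linkage),
            class = "epogram")
}

#' @export
print.epogram <- function(x, ...) {
  cat(sprintf("epogram: %d leaves, %s linkage, root height %.4g\n",
              length(x$labels), x$linkage, max(x$heights)))
  cat(ape::write.tree(x$phylo), "\n")
  invisible(x)
}

#' Cut an epogram into k clusters
#' @param epogram an `epogram`.
#' @param k number of clusters.
#' @return named integer vector of cluster memberships.
#' @export
cut_epogram <- function(epogram, k) {
  stopifnot(inherits(epogram, "epogram"))
  cutree(epogram$hclust, k = k)
}

#' Write an epogram as Newick
#' @param epogram an `epogram`.
#' @param path file path.
#' @export
write_epogram <- function(epogram, path) {
  stopifnot(inherits(epogram, "epogram"))
  ape::write.tree(epogram$phylo, file = path)
  invisible(path)
}

#' Ordered distance heatmap of a similarity matrix
#'
#' Permutes the distance matrix `d = sqrt(2 - 2*SI)` to the epogram's leaf
#' order, writes it as TSV (the tested artifact) and optionally renders a
#' PNG with a diverging red (d = 0, identical) to blue (d = 2,
#' anticorrelated) colour scale.
#'
#' @param matrix a `si_matrix` (fully defined).
#' @param order an `epogram` built from it.
#' @param tsv_path output TSV path.
#' @param png_path optional output PNG path.
#' @return the ordered distance matrix, invisibly.
#' @export
mif_heatmap <- function(matrix, order, tsv_path, png_path = NULL) {
  stopifnot(inherits(matrix, "si_matrix"), inherits(order, "epogram"))
  if (!setequal(order$labels, matrix$labels))
    stop("epogram leaves and matrix labels do not match")
  if (!all(matrix$defined))
    stop("similarity matrix has undefined entries")
  d <- si_to_distance(pmin(matrix$si, 1))
  d <- matrix(d, nrow(matrix$si), dimnames = dimnames(matrix$si))
  diag(d) <- 0
  leaf_order <- order$hclust$labels[order$hclust$order]
  d <- d[leaf_order, leaf_order]
  write_si_tsv(d, tsv_path)
  if (!is.null(png_path)) {
    pal <- grDevices::colorRampPalette(c("red", "white", "blue"))(256)
    grDevices::png(png_path, width = 800, height = 800)
    on.exit(grDevices::dev.off())
    n <- nrow(d)
    graphics::image(seq_len(n), seq_len(n), t(d[n:1, ]),
                    zlim = c(0, 2), col = pal, axes = FALSE,
                    xlab = "", ylab = "",
                    main = sprintf("MIF distance (%s)", matrix$field_kind))
    graphics::axis(1, at = seq_len(n), labels = colnames(d), las = 2, cex.axis = 0.7)
    graphics::axis(2, at = seq_len(n), labels = rev(rownames(d)), las = 2, cex.axis = 0.7)
  }
  invisible(d)
}

#' Colour table for a conservation profile
#'
#' Maps scores linearly onto a blue (variable) - green - red (conserved)
#' gradient: electrostatic scores over `[-1, 1]`, hydrophobic scores over
#' `[0, 1]`. Flagged residues (no defined index, e.g. fully clamped
#' hydrophobic spheres) are black.
#'
#' @param profile a `conservation_profile`.
#' @return data.frame `residue_index, score, flagged, color` (hex).
#' @export
color_profile <- function(profile) {
  stopifnot(inherits(profile, "conservation_profile"))
  rng <- if (profile$field_kind == "hydrophobic") c(0, 1) else c(-1, 1)
  pal <- grDevices::colorRampPalette(c("blue", "green", "red"))(256)
  df <- profile$profile
  t01 <- (pmin(pmax(df$score, rng[1]), rng[2]) - rng[1]) / (rng[2] - rng[1])
  col <- pal[1L + as.integer(round(t01 * 255))]
  col[df$flagged] <- "#000000"
  data.frame(residue_index = df$residue_index, score = df$score,
             flagged = df$flagged, color = col, stringsAsFactors = FALSE)
}
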