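#' Specification of a synthetic pseudo-protein cohort
#'
#' Desk-scale stand-in for a family of homology models built on one
#' template: every member shares an identical idealised backbone and
#' differs only in a controlled surface-charge pattern (plus optional
#' coordinate jitter), so group structure, field divergence and local
#' conservation are known by construction.
#'
#' Defaults describe a cohort of 12 proteins in 3 groups of 4: 24-residue
#' helical backbones carrying 8 unit charges; group archetypes differ by 4
#' charge-sign flips (half the sites -- a strong, subfamily-scale
#' divergence), members within a group flip each site independently with
#' probability 0.05 (mild isoform-scale variation) and jitter coordinates
#' by 0.1 Angstrom.
#'
#' @param n_residues residues per protein.
#' @param n_proteins cohort size.
#' @param n_groups number of archetype groups.
#' @param charges_per_protein charged side-chain sites per protein.
#' @param within_group_flip_prob per-site sign-flip probability for group
#'   members.
#' @param between_group_flip_count sign flips separating each group
#'   archetype from the base pattern.
#' @param coordinate_jitter Angstrom, sd of isotropic coordinate noise.
#' @param seed RNG seed for reproducibility.
#' @return an object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_residues = 24L, n_proteins = 12L, n_groups = 3L,
                        charges_per_protein = 8L, within_group_flip_prob = 0.05,
                        between_group_flip_count = 4L, coordinate_jitter = 0.1,
                        seed = 42L) {
  if (n_groups > n_proteins) stop("n_groups must be <= n_proteins")
  if (within_group_flip_prob < 0 || within_group_flip_prob > 1)
    stop("within_group_flip_prob must be in [0, 1]")
  if (coordinate_jitter < 0) stop("coordinate_jitter must be >= 0")
  if (charges_per_protein > n_residues)
    stop("charges_per_protein cannot exceed n_residues")
  if (between_group_flip_count > charges_per_protein)
    stop("between_group_flip_count cannot exceed charges_per_protein")
  structure(list(n_residues = as.integer(n_residues),
                 n_proteins = as.integer(n_proteins),
                 n_groups = as.integer(n_groups),
                 charges_per_protein = as.integer(charges_per_protein),
                 within_group_flip_prob = within_group_flip_prob,
                 between_group_flip_count = as.integer(between_group_flip_count),
                 coordinate_jitter = coordinate_jitter,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Idealised helical pseudo-protein backbone
#'
#' An alpha-helical C-alpha trace (1.5 Angstrom rise, 100 degrees per
#' residue, 2.3 Angstrom helix radius -- consecutive C-alphas come out
#' ~3.8 Angstrom apart) with one side-chain pseudo-atom (`CB`, radius 1.9)
#' per residue, placed radially outward. All charges start at zero.
#' Residues alternate the synthetic class names `APO` (apolar) and `POL`
#' (polar side chain) so hydrophobic fields have structure.
#'
#' @param n_residues at least 5.
#' @param seed unused randomness hook kept for interface symmetry; the
#'   backbone is deterministic.
#' @param label protein identifier.
#' @return a `mif_structure`.
#' @export
make_backbone <- function(n_residues, seed = 0L, label = "synthetic") {
  n_residues <- as.integer(n_residues)
  if (n_residues < 5L) stop("n_residues must be >= 5")
  i <- seq_len(n_residues) - 1L
  turn <- 100 * pi / 180
  rise <- 1.5
  r_ca <- 2.3
  r_cb <- 5.3
  ang <- i * turn
  ca <- cbind(r_ca * cos(ang), r_ca * sin(ang), i * rise)
  cb <- cbind(r_cb * cos(ang), r_cb * sin(ang), i * rise)
  resnames <- ifelse(i %% 2L == 0L, "APO", "POL")
  atoms <- data.frame(
    x = c(rbind(ca[, 1], cb[, 1])),
    y = c(rbind(ca[, 2], cb[, 2])),
    z = c(rbind(ca[, 3], cb[, 3])),
    charge = 0,
    radius = rep(c(2.0, 1.9), n_residues),
    name = rep(c("CA", "CB"), n_residues),
    residue_index = rep(i, each = 2L),
    residue_name = rep(resnames, each = 2L),
    stringsAsFactors = FALSE)
  mif_structure(atoms, label = label)
}

#' Overwrite side-chain charges at selected residues
#'
#' Sets the `CB` pseudo-atom charge of each listed residue to the listed
#' value (assignment, not accumulation: re-decorating overwrites).
#' Geometry is untouched.
#'
#' @param backbone a `mif_structure` from [make_backbone()].
#' @param pattern data.frame (or 2-column matrix) with columns
#'   `residue_index` (0-based) and `charge`, possibly empty.
#' @return a new `mif_structure`.
#' @export
decorate_charges <- function(backbone, pattern) {
  stopifnot(inherits(backbone, "mif_structure"))
  pattern <- as.data.frame(pattern)
  if (nrow(pattern) == 0) return(backbone)
  names(pattern)[1:2] <- c("residue_index", "charge")
  R <- n_residues(backbone)
  if (any(pattern$residue_index < 0 | pattern$residue_index >= R))
    stop("pattern residue_index out of range 0..", R - 1L)
  at <- backbone$atoms
  for (row in seq_len(nrow(pattern))) {
    sel <- at$residue_index == pattern$residue_index[row] & at$name == "CB"
    at$charge[sel] <- pattern$charge[row]
  }
  mif_structure(at, label = backbone$label,
                conformation_tag = backbone$conformation_tag)
}

#' Generate a synthetic cohort with known group structure
#'
#' Builds `n_groups` archetype charge patterns over a shared backbone: a
#' base pattern of alternating +1/-1 charges on randomly chosen residues,
#' with each non-base group flipping the signs of
#' `between_group_flip_count` distinct sites. Members inherit their
#' group's archetype, then flip each charged site independently with
#' `within_group_flip_prob` and jitter all coordinates with isotropic
#' Gaussian noise. Fully reproducible from `spec$seed`.
#'
#' @param spec a `cohort_spec`.
#' @return list with `structures` (list of `mif_structure`, labelled
#'   `g<group>_m<member>`), `labels` (true group index per protein) and
#'   `spec`.
#' @export
make_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  backbone <- make_backbone(spec$n_residues)
  sites <- sort(sample(seq_len(spec$n_residues) - 1L, spec$charges_per_protein))
  base_q <- rep_len(c(1, -1), spec$charges_per_protein)
  archetypes <- vector("list", spec$n_groups)
  archetypes[[1]] <- base_q
  for (gidx in seq_len(spec$n_groups)[-1]) {
    flip <- sample(seq_len(spec$charges_per_protein), spec$between_group_flip_count)
    q <- base_q
    q[flip] <- -q[flip]
    archetypes[[gidx]] <- q
  }
  group_of <- rep_len(seq_len(spec$n_groups), spec$n_proteins)
  group_of <- sort(group_of)
  structures <- vector("list", spec$n_proteins)
  member_no <- integer(spec$n_groups)
  for (p in seq_len(spec$n_proteins)) {
    gidx <- group_of[p]
    member_no[gidx] <- member_no[gidx] + 1L
    q <- archetypes[[gidx]]
    if (spec$within_group_flip_prob > 0) {
      flips <- stats::runif(length(q)) < spec$within_group_flip_prob
      q[flips] <- -q[flips]
    }
    s <- decorate_charges(backbone, data.frame(residue_index = sites, charge = q))
    if (spec$coordinate_jitter > 0) {
      at <- s$atoms
      at$x <- at$x + stats::rnorm(nrow(at), 0, spec$coordinate_jitter)
      at$y <- at$y + stats::rnorm(nrow(at), 0, spec$coordinate_jitter)
      at$z <- at$z + stats::rnorm(nrow(at), 0, spec$coordinate_jitter)
      s <- mif_structure(at, label = s$label)
    }
    s$label <- sprintf("g%d_m%d", gidx, member_no[gidx])
    structures[[p]] <- s
  }
  list(structures = structures, labels = group_of, spec = spec)
}
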