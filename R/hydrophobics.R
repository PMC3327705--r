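#' Parameters of the DRY-style hydrophobic probe
#'
#' The hydrophobic interaction energy at a grid point is assembled as
#' `E = sum(E_LJ) + WENT - sum(E_HB)`: Lennard-Jones attraction of a
#' neutral probe to apolar atoms, a constant water-entropy reward inside
#' the first solvation shell of the apolar surface, and a hydrogen-bond
#' competition penalty near donor/acceptor atoms (favourable water-protein
#' hydrogen bonds that the probe cannot replace). Positive (unfavourable)
#' totals are reset to zero, so polar regions carry no hydrophobic field.
#'
#' @param lj_epsilon named numeric, kcal/mol well depth per atom class
#'   (`apolar`, `polar`). The polar class defaults to 0: donors/acceptors
#'   enter only through the hydrogen-bond penalty.
#' @param lj_rmin named numeric, Angstrom; probe-atom distance at the LJ
#'   minimum per class.
#' @param lj_cutoff Angstrom; LJ interactions are shift-truncated here.
#' @param entropy_reward kcal/mol, negative (favourable); applied where the
#'   gap to the nearest apolar atom surface is at most `shell_width`.
#' @param shell_width Angstrom; thickness of the first solvation shell.
#' @param hbond_penalty_strength kcal/mol, positive; maximum penalty per
#'   donor/acceptor atom.
#' @param hbond_cutoff Angstrom; the penalty decays linearly to zero here.
#' @param spacing Angstrom; default grid spacing for hydrophobic fields
#'   (finer than the electrostatics grid because the field is short-range).
#' @return an object of class `hydrophobic_params`.
#' @export
hydrophobic_params <- function(lj_epsilon = c(apolar = 0.15, polar = 0.0),
                               lj_rmin = c(apolar = 3.6, polar = 3.2),
                               lj_cutoff = 8.0,
                               entropy_reward = -0.85, shell_width = 1.5,
                               hbond_penalty_strength = 2.5, hbond_cutoff = 4.0,
                               spacing = 0.5) {
  if (spacing <= 0 || lj_cutoff <= 0 || hbond_cutoff <= 0 || shell_width <= 0)
    stop("hydrophobic_params cutoffs and spacing must be positive")
  if (entropy_reward > 0) stop("entropy_reward must be <= 0 (favourable)")
  if (hbond_penalty_strength < 0) stop("hbond_penalty_strength must be >= 0")
  stopifnot(all(c("apolar", "polar") %in% names(lj_epsilon)),
            all(c("apolar", "polar") %in% names(lj_rmin)))
  structure(list(lj_epsilon = lj_epsilon, lj_rmin = lj_rmin,
                 lj_cutoff = lj_cutoff, entropy_reward = entropy_reward,
                 shell_width = shell_width,
                 hbond_penalty_strength = hbond_penalty_strength,
                 hbond_cutoff = hbond_cutoff, spacing = spacing),
            class = "hydrophobic_params")
}

#' Classify atoms as apolar or polar (hydrogen-bond donor/acceptor)
#'
#' Classification is by residue/atom-name lookup: the synthetic residue
#' names `APO`/`POL` map directly; otherwise the leading element letter
#' decides (C, S apolar; N, O polar; H follows its heavy-atom context and
#' is treated as apolar). In strict mode an unclassifiable atom raises an
#' error; in lenient mode it is treated as polar (the conservative choice:
#' it suppresses rather than creates hydrophobic signal).
#'
#' @param structure a `mif_structure`.
#' @param strict logical.
#' @return character vector, `"apolar"` or `"polar"`, one per atom.
#' @export
classify_atoms <- function(structure, strict = TRUE) {
  at <- structure$atoms
  cls <- rep(NA_character_, nrow(at))
  cls[at$residue_name == "APO"] <- "apolar"
  cls[at$residue_name == "POL" & at$is_calpha] <- "apolar"  # backbone carbon
  cls[at$residue_name == "POL" & !at$is_calpha] <- "polar"
  el <- substr(at$name, 1, 1)
  cls[is.na(cls) & el %in% c("C", "S", "H")] <- "apolar"
  cls[is.na(cls) & el %in% c("N", "O")] <- "polar"
  if (anyNA(cls)) {
    if (strict)
      stop("unclassifiable atom name(s): ",
           paste(unique(at$name[is.na(cls)]), collapse = ", "))
    cls[is.na(cls)] <- "polar"
  }
  cls
}

#' Compute a DRY-style hydrophobic interaction field
#'
#' Evaluates the probe energy at every grid node, then applies the
#' polar-region clamp: any positive value is reset to 0, and nodes inside
#' an atom core (closer than the atom radius) are 0. The result is
#' everywhere non-positive, with favourable (negative) shells over apolar
#' surface patches.
#'
#' @param structure a `mif_structure`.
#' @param grid a `grid_spec`; defaults to [default_grid()] at
#'   `params$spacing`.
#' @param params a `hydrophobic_params`.
#' @param strict passed to [classify_atoms()].
#' @return a `scalar_field` of kind `"hydrophobic"`, units kcal/mol.
#' @export
dry_field <- function(structure, grid = NULL, params = hydrophobic_params(),
                      strict = TRUE) {
  stopifnot(inherits(structure, "mif_structure"))
  if (is.null(grid)) grid <- default_grid(structure, spacing = params$spacing)
  cls <- classify_atoms(structure, strict = strict)
  at <- structure$atoms
  ax <- grid_axes(grid)
  sh <- grid$shape
  energy <- array(0, dim = sh)
  apolar_gap <- array(Inf, dim = sh)  # gap to nearest apolar atom surface
  core <- array(FALSE, dim = sh)
  reach <- max(params$lj_cutoff, params$hbond_cutoff) + grid$spacing

  for (i in seq_len(nrow(at))) {
    ix <- which(abs(ax[[1]] - at$x[i]) <= reach)
    iy <- which(abs(ax[[2]] - at$y[i]) <= reach)
    iz <- which(abs(ax[[3]] - at$z[i]) <= reach)
    if (!length(ix) || !length(iy) || !length(iz)) next
    dx2 <- (ax[[1]][ix] - at$x[i])^2
    dy2 <- (ax[[2]][iy] - at$y[i])^2
    dz2 <- (ax[[3]][iz] - at$z[i])^2
    d <- sqrt(outer(outer(dx2, dy2, "+"), dz2, "+"))
    core[ix, iy, iz] <- core[ix, iy, iz] | (d < at$radius[i])
    contrib <- array(0, dim = dim(d))
    if (cls[i] == "apolar") {
      apolar_gap[ix, iy, iz] <- pmin(apolar_gap[ix, iy, iz], d - at$radius[i])
      epsc <- params$lj_epsilon[["apolar"]]; rm <- params$lj_rmin[["apolar"]]
      contrib <- contrib + .lj_shifted(d, epsc, rm, params$lj_cutoff)
    } else {
      epsc <- params$lj_epsilon[["polar"]]; rm <- params$lj_rmin[["polar"]]
      if (epsc != 0)
        contrib <- contrib + .lj_shifted(d, epsc, rm, params$lj_cutoff)
      # hydrogen-bond competition: linear decay to zero at the cutoff
      s <- pmax(0, 1 - d / params$hbond_cutoff)
      contrib <- contrib + params$hbond_penalty_strength * s
    }
    energy[ix, iy, iz] <- energy[ix, iy, iz] + contrib
  }
  energy[apolar_gap <= params$shell_width] <-
    energy[apolar_gap <= params$shell_width] + params$entropy_reward
  energy[energy > 0] <- 0
  energy[core] <- 0
  scalar_field(grid, energy, units = "kcal/mol", kind = "hydrophobic")
}

# shift-truncated 12-6 Lennard-Jones: eps*((rm/d)^12 - 2(rm/d)^6) minus its
# value at the cutoff, zero beyond; d is clamped away from 0 (cores are
# zeroed afterwards anyway)
.lj_shifted <- function(d, eps, rmin, cutoff) {
  d <- pmax(d, 0.5)
  x6 <- (rmin / d)^6
  e <- eps * (x6 * x6 - 2 * x6)
  xc6 <- (rmin / cutoff)^6
  ec <- eps * (xc6 * xc6 - 2 * xc6)
  out <- e - ec
  out[d >= cutoff] <- 0
  out
}
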