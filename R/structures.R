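#' Construct a charged structure
#'
#' The atomic container used by both field calculators: coordinates,
#' partial charges (e), radii (Angstrom) and residue bookkeeping. Residue
#' indices are 0-based and contiguous; every residue must carry exactly one
#' C-alpha atom (name `"CA"`), which anchors the per-residue spherical scan.
#'
#' @param atoms data.frame with columns `x, y, z` (Angstrom), `charge` (e),
#'   `radius` (Angstrom, > 0), `name` (atom label), `residue_index`
#'   (0-based), `residue_name` (3-letter code). A logical `is_calpha`
#'   column is derived from `name == "CA"` if absent.
#' @param label protein identifier.
#' @param conformation_tag free label, e.g. `"active"` / `"inactive"`.
#' @return an object of class `mif_structure`.
#' @export
mif_structure <- function(atoms, label = "protein", conformation_tag = "") {
  atoms <- as.data.frame(atoms)
  need <- c("x", "y", "z", "charge", "radius", "name", "residue_index", "residue_name")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atoms is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) < 1) stop("a structure must contain at least one atom")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("atom positions must be finite")
  if (!all(is.finite(atoms$charge))) stop("atom charges must be finite")
  if (!all(is.finite(atoms$radius) & atoms$radius > 0))
    stop("atom radii must be positive")
  if (is.null(atoms$is_calpha)) atoms$is_calpha <- atoms$name == "CA"
  ri <- atoms$residue_index
  nres <- max(ri) + 1L
  if (!setequal(unique(ri), 0:(nres - 1L)))
    stop("residue_index values must form a contiguous 0..R-1 set")
  nca <- tapply(atoms$is_calpha, ri, sum)
  bad <- names(nca)[nca != 1L]
  if (length(bad))
    stop("each residue needs exactly one CA atom; offending residue_index: ",
         paste(bad, collapse = ", "))
  structure(list(atoms = atoms, label = label, conformation_tag = conformation_tag),
            class = "mif_structure")
}

#' @export
print.mif_structure <- function(x, ...) {
  cat(sprintf("mif_structure '%s'%s: %d atoms, %d residues, net charge %+.3f e\n",
              x$label,
              if (nzchar(x$conformation_tag)) paste0(" [", x$conformation_tag, "]") else "",
              nrow(x$atoms), n_residues(x), total_charge(x)))
  invisible(x)
}

#' Number of residues in a structure
#' @param structure a `mif_structure`.
#' @export
n_residues <- function(structure) max(structure$atoms$residue_index) + 1L

#' Net charge of a structure (sum of atomic partial charges, e)
#' @param structure a `mif_structure`.
#' @export
total_charge <- function(structure) sum(structure$atoms$charge)

#' C-alpha coordinates, one row per residue in residue order
#' @param structure a `mif_structure`.
#' @return numeric matrix R x 3.
#' @export
calpha_coords <- function(structure) {
  at <- structure$atoms[structure$atoms$is_calpha, ]
  at <- at[order(at$residue_index), ]
  as.matrix(at[, c("x", "y", "z")])
}

#' Read a PQR file
#'
#' Parses the whitespace-delimited (APBS dialect) PQR format: ATOM/HETATM
#' records carrying `x y z charge radius` as the last five numeric fields.
#' An optional chain identifier between the residue name and the residue
#' number is tolerated and ignored. Residues are renumbered to a 0-based
#' contiguous index in order of first appearance.
#'
#' @param path file path.
#' @param label protein identifier; defaults to the file basename.
#' @param conformation_tag free label stored on the structure.
#' @return a `mif_structure`.
#' @export
read_pqr <- function(path, label = NULL, conformation_tag = "") {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  lines <- readLines(path, warn = FALSE)
  keep <- grepl("^(ATOM|HETATM)", lines)
  recs <- lines[keep]
  lineno <- which(keep)
  if (!length(recs)) stop("no ATOM/HETATM records in ", path)
  toks <- strsplit(trimws(recs), "\\s+")
  parse_one <- function(tk, ln) {
    # ATOM serial name resName [chain] resSeq x y z q r
    if (length(tk) < 10L)
      stop(sprintf("malformed PQR record at line %d: expected >= 10 fields, got %d",
                   ln, length(tk)))
    num5 <- suppressWarnings(as.numeric(tk[(length(tk) - 4):length(tk)]))
    if (any(is.na(num5)))
      stop(sprintf("malformed PQR record at line %d: non-numeric x/y/z/charge/radius", ln))
    resseq_pos <- length(tk) - 5L
    data.frame(name = tk[3], residue_name = tk[4], resseq = tk[resseq_pos],
               x = num5[1], y = num5[2], z = num5[3],
               charge = num5[4], radius = num5[5], stringsAsFactors = FALSE)
  }
  df <- do.call(rbind, Map(parse_one, toks, lineno))
  df$residue_index <- match(df$resseq, unique(df$resseq)) - 1L
  df$resseq <- NULL
  df$is_calpha <- df$name == "CA"
  nca <- tapply(df$is_calpha, df$residue_index, sum)
  bad <- names(nca)[nca != 1L]
  if (length(bad))
    stop("PQR residue(s) without exactly one CA atom (0-based index): ",
         paste(bad, collapse = ", "))
  mif_structure(df, label = label, conformation_tag = conformation_tag)
}

#' Write a structure as PQR
#'
#' Fixed-width, whitespace-separated ATOM records readable by [read_pqr()]
#' and by APBS-family tools; coordinates, charges and radii are written
#' with 4 decimals so a round trip preserves them to much better than
#' 1e-3.
#'
#' @param structure a `mif_structure`.
#' @param path output file path.
#' @export
write_pqr <- function(structure, path) {
  stopifnot(inherits(structure, "mif_structure"))
  at <- structure$atoms
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("REMARK  generated by mifscan: %s", structure$label), con)
  lines <- sprintf("ATOM  %5d %-4s %-4s %5d    %10.4f %10.4f %10.4f %8.4f %7.4f",
                   seq_len(nrow(at)), at$name, at$residue_name,
                   at$residue_index + 1L, at$x, at$y, at$z, at$charge, at$radius)
  writeLines(lines, con)
  writeLines("END", con)
  invisible(path)
}

#' Minimal charge/radius parameter ruleset
#'
#' Maps `(residue_name, atom_name)` to a partial charge and radius, with
#' Bondi-like per-element fallback radii. The bundled defaults place unit
#' formal charges on charged side-chain terminal atoms: Asp OD1/OD2 and Glu
#' OE1/OE2 at -0.5 each, Lys NZ +1, Arg NH1/NH2 +0.5 each; His neutral;
#' backbone neutral. This reproduces the sign structure of surface
#' potentials for comparative similarity work; it is not a force field.
#'
#' @param charges optional data.frame with columns `residue_name,
#'   atom_name, charge, radius` overriding the bundled table.
#' @param element_radii named numeric vector of fallback radii by leading
#'   element letter.
#' @return an object of class `parameter_ruleset`.
#' @export
default_ruleset <- function(charges = NULL,
                            element_radii = c(H = 1.2, C = 1.7, N = 1.55,
                                              O = 1.52, S = 1.8, P = 1.8)) {
  if (is.null(charges)) {
    charges <- data.frame(
      residue_name = c("ASP", "ASP", "GLU", "GLU", "LYS", "ARG", "ARG"),
      atom_name   = c("OD1", "OD2", "OE1", "OE2", "NZ", "NH1", "NH2"),
      charge      = c(-0.5, -0.5, -0.5, -0.5, 1.0, 0.5, 0.5),
      radius      = c(1.52, 1.52, 1.52, 1.52, 1.55, 1.55, 1.55),
      stringsAsFactors = FALSE)
  }
  if (any(charges$radius < 0)) stop("ruleset radii must be non-negative")
  if (any(element_radii <= 0)) stop("element default radii must be positive")
  structure(list(charges = charges, element_radii = element_radii,
                 default_radius = 1.7),
            class = "parameter_ruleset")
}

#' Read a ruleset from a key-value text file
#'
#' Whitespace-delimited columns `residue_name atom_name charge radius`;
#' lines starting with `#` are comments.
#' @param path file path.
#' @export
read_ruleset <- function(path) {
  df <- read.table(path, header = FALSE, comment.char = "#",
                   col.names = c("residue_name", "atom_name", "charge", "radius"),
                   stringsAsFactors = FALSE)
  default_ruleset(charges = df)
}

# look up (charge, radius, hit) for one atom
.ruleset_lookup <- function(ruleset, residue_name, atom_name) {
  i <- which(ruleset$charges$residue_name == residue_name &
             ruleset$charges$atom_name == atom_name)
  if (length(i)) {
    return(list(charge = ruleset$charges$charge[i[1]],
                radius = ruleset$charges$radius[i[1]], hit = TRUE))
  }
  el <- substr(atom_name, 1, 1)
  r <- ruleset$element_radii[el]
  if (is.na(r)) r <- ruleset$default_radius
  list(charge = 0, radius = unname(r), hit = FALSE)
}

#' Read a PDB file and assign charges/radii from a ruleset
#'
#' Reads ATOM records (first model only, chains merged) via
#' \code{bio3d::read.pdb} and parameterises each atom with
#' [default_ruleset()]-style lookups. Atoms not resolved by the ruleset get
#' charge 0 and the element-default radius; the number of such fallbacks is
#' reported as a warning and stored in the `n_unresolved` attribute.
#'
#' @param path PDB file path.
#' @param ruleset a `parameter_ruleset`.
#' @param label protein identifier; defaults to the file basename.
#' @param conformation_tag free label.
#' @return a `mif_structure`.
#' @export
read_pdb <- function(path, ruleset = default_ruleset(), label = NULL,
                     conformation_tag = "") {
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(label)) label <- sub("\\.[^.]*$", "", basename(path))
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom[pdb$atom$type == "ATOM", ]
  if (!nrow(at)) stop("no ATOM records in ", path)
  pars <- Map(function(rn, an) .ruleset_lookup(ruleset, rn, an), at$resid, at$elety)
  n_unresolved <- sum(!vapply(pars, `[[`, logical(1), "hit"))
  reskey <- paste(at$chain, at$resno, at$insert, sep = "|")
  df <- data.frame(
    name = at$elety, residue_name = at$resid,
    x = at$x, y = at$y, z = at$z,
    charge = vapply(pars, `[[`, numeric(1), "charge"),
    radius = vapply(pars, `[[`, numeric(1), "radius"),
    residue_index = match(reskey, unique(reskey)) - 1L,
    stringsAsFactors = FALSE)
  df$is_calpha <- df$name == "CA"
  if (n_unresolved > 0)
    warning(sprintf("%d atom(s) not in ruleset: charge 0, element-default radius",
                    n_unresolved))
  s <- mif_structure(df, label = label, conformation_tag = conformation_tag)
  attr(s, "n_unresolved") <- n_unresolved
  s
}
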