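#' Write a scalar field in OpenDX format (APBS dialect)
#'
#' Emits the `gridpositions`/`gridconnections`/`data follows` layout used
#' by APBS and read by most visualisation tools. Values are written in x-
#' fastest-last order (z fastest), three per line, full double precision.
#'
#' @param field a `scalar_field` (or a `skin_mask`, exported as 0/1).
#' @param path output file path.
#' @export
write_dx <- function(field, path) {
  if (inherits(field, "skin_mask"))
    field <- scalar_field(field$grid, array(as.numeric(field$selected),
                                            dim = field$grid$shape),
                          units = "bool", kind = "mask")
  stopifnot(inherits(field, "scalar_field"))
  g <- field$grid
  con <- file(path, open = "wt")
  on.exit(close(con))
  n <- prod(g$shape)
  writeLines(c(
    sprintf("# OpenDX scalar field written by mifscan (%s, %s)", field$kind, field$units),
    sprintf("object 1 class gridpositions counts %d %d %d", g$shape[1], g$shape[2], g$shape[3]),
    sprintf("origin %.6e %.6e %.6e", g$origin[1], g$origin[2], g$origin[3]),
    sprintf("delta %.6e 0.000000e+00 0.000000e+00", g$spacing),
    sprintf("delta 0.000000e+00 %.6e 0.000000e+00", g$spacing),
    sprintf("delta 0.000000e+00 0.000000e+00 %.6e", g$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", g$shape[1], g$shape[2], g$shape[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows", n)
  ), con)
  # APBS order: z varies fastest
  v <- aperm(field$values, c(3, 2, 1))
  v <- as.vector(v)  # now x slowest
  pad <- (3 - length(v) %% 3) %% 3
  if (pad) v <- c(v, rep(NA_real_, pad))
  m <- matrix(v, ncol = 3, byrow = TRUE)
  lines <- apply(m, 1, function(r) paste(sprintf("%.12e", r[!is.na(r)]), collapse = " "))
  writeLines(lines, con)
  writeLines(c("attribute \"dep\" string \"positions\"",
               "object \"regular positions regular connections\" class field",
               "component \"positions\" value 1",
               "component \"connections\" value 2",
               "component \"data\" value 3"), con)
  invisible(path)
}

#' Read an OpenDX scalar field (APBS dialect)
#'
#' @param path file path.
#' @param units,kind metadata labels to attach (DX files do not carry them
#'   in a standard place).
#' @return a `scalar_field`.
#' @export
read_dx <- function(path, units = "kT/e", kind = "electrostatic") {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^#", lines)]
  gp <- grep("class gridpositions counts", lines, value = TRUE)[1]
  if (is.na(gp)) stop("not an OpenDX gridpositions file: ", path)
  shape <- as.integer(tail(strsplit(trimws(gp), "\\s+")[[1]], 3))
  org <- grep("^origin", lines, value = TRUE)[1]
  origin <- as.numeric(strsplit(trimws(org), "\\s+")[[1]][2:4])
  deltas <- grep("^delta", lines, value = TRUE)[1:3]
  dmat <- t(vapply(deltas, function(l) as.numeric(strsplit(trimws(l), "\\s+")[[1]][2:4]),
                   numeric(3)))
  if (any(abs(dmat - diag(diag(dmat))) > 1e-12))
    stop("only axis-aligned grids are supported")
  sp <- diag(dmat)
  if (max(sp) - min(sp) > 1e-9) stop("anisotropic grid spacing is not supported")
  hdr <- grep("data follows", lines)
  if (!length(hdr)) stop("no 'data follows' section in ", path)
  n <- prod(shape)
  body <- lines[(hdr[1] + 1):length(lines)]
  body <- body[!grepl("^(attribute|object|component)", body)]
  vals <- suppressWarnings(as.numeric(unlist(strsplit(trimws(body), "\\s+"))))
  vals <- vals[!is.na(vals)]
  if (length(vals) < n) stop("DX data section is short: ", length(vals), " < ", n)
  arr <- aperm(array(vals[seq_len(n)], dim = rev(shape)), c(3, 2, 1))
  scalar_field(grid_spec(origin, sp[1], shape), arr, units = units, kind = kind)
}

#' @importFrom utils tail
NULL
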