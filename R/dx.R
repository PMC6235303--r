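#' Write a scalar field to an OpenDX grid file
#'
#' Standard regular-grid OpenDX format (gridpositions / gridconnections /
#' data follows), x fastest in memory, written in the format's z-fastest
#' order.  Values are written with full double precision so a read-back is
#' bit-identical.
#'
#' @param values numeric 3D array.
#' @param origin grid corner (3-vector, Angstrom).
#' @param spacing voxel edge (Angstrom).
#' @param path output file.
#' @export
write_dx <- function(values, origin, spacing, path) {
  d <- dim(values)
  if (length(d) != 3) stop("values must be a 3D array")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# OpenDX scalar field",
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %.6f %.6f %.6f", origin[1], origin[2], origin[3]),
    sprintf("delta %.6f 0 0", spacing),
    sprintf("delta 0 %.6f 0", spacing),
    sprintf("delta 0 0 %.6f", spacing),
    sprintf("object 2 class gridconnections counts %d %d %d", d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))), con)
  v <- aperm(values, c(3, 2, 1))  # DX order: z fastest -> flatten x slowest
  v <- as.numeric(v)
  n <- length(v)
  pad <- (3 - n %% 3) %% 3
  m <- matrix(c(sprintf("%.17g", v), rep("", pad)), nrow = 3)
  writeLines(trimws(apply(m, 2, paste, collapse = " ")), con)
  writeLines(c('attribute "dep" string "positions"',
               'object "density" class field',
               'component "positions" value 1',
               'component "connections" value 2',
               'component "data" value 3'), con)
  invisible(path)
}

#' Read an OpenDX scalar field
#'
#' @param path OpenDX file written by [write_dx()] (or compatible regular
#'   grids with diagonal deltas).
#' @return list with `values` (3D array), `origin`, `spacing`, `dims`.
#' @export
read_dx <- function(path) {
  lines <- readLines(path, warn = FALSE)
  gp <- grep("class gridpositions counts", lines, value = TRUE)[1]
  dims <- as.integer(strsplit(trimws(sub(".*counts", "", gp)), "[[:space:]]+")[[1]])
  org <- as.numeric(strsplit(trimws(sub("origin", "",
    grep("^origin", lines, value = TRUE)[1])), "[[:space:]]+")[[1]])
  deltas <- grep("^delta", lines, value = TRUE)
  dmat <- do.call(rbind, lapply(deltas[1:3], function(l)
    as.numeric(strsplit(trimws(sub("delta", "", l)), "[[:space:]]+")[[1]])))
  spacing <- dmat[1, 1]
  if (any(abs(dmat - diag(rep(spacing, 3))) > 1e-9))
    stop("only axis-aligned cubic-voxel DX grids are supported")
  start <- grep("data follows", lines)[1] + 1L
  n <- prod(dims)
  vals <- numeric(0)
  i <- start
  while (length(vals) < n && i <= length(lines)) {
    if (grepl("^(attribute|object)", lines[i])) break
    vals <- c(vals, as.numeric(strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]))
    i <- i + 1L
  }
  if (length(vals) != n) stop("DX data block has wrong length")
  arr <- aperm(array(vals, dim = rev(dims)), c(3, 2, 1))
  list(values = arr, origin = org, spacing = spacing, dims = dims)
}

#' Export a voxel-grid quantity as an OpenDX density map
#'
#' @param grid a populated [voxel_grid()].
#' @param path output file.
#' @param quantity `"g"` (dimensionless density, needs `rho0`) or
#'   `"number_density"` (molecules/Angstrom^3).
#' @param rho0 bulk density for `quantity = "g"`.
#' @export
export_density <- function(grid, path, quantity = c("g", "number_density"),
                           rho0 = NULL) {
  quantity <- match.arg(quantity)
  if (grid$n_frames < 1) stop("grid has no accumulated frames")
  vals <- switch(quantity,
    g = {
      if (is.null(rho0)) stop("rho0 required for quantity = 'g'")
      voxel_g(grid, rho0)
    },
    number_density = grid$n_k / (grid$spacing^3 * grid$n_frames))
  write_dx(vals, grid$origin + grid$spacing / 2, grid$spacing, path)
}
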