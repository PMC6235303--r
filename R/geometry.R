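#' Orthorhombic periodic box
#'
#' @param lx,ly,lz box edge lengths in Angstrom; all must be positive.
#' @return an object of class `box` (named numeric vector of lengths).
#' @examples
#' b <- box(10, 10, 10)
#' box_volume(b)
#' @export
box <- function(lx, ly, lz) {
  len <- c(lx = lx, ly = ly, lz = lz)
  if (any(!is.finite(len)) || any(len <= 0))
    stop("box lengths must be positive and finite")
  structure(len, class = "box")
}

#' @rdname box
#' @param b a `box` object or length-3 numeric vector.
#' @export
box_volume <- function(b) prod(as.numeric(b)[1:3])

as_box <- function(b) {
  if (inherits(b, "box")) return(b)
  b <- as.numeric(b)
  if (length(b) != 3) stop("box must have three lengths")
  box(b[1], b[2], b[3])
}

## minimum-image displacement; d is an n x 3 matrix of raw differences
.pbc_delta <- function(d, b) {
  b <- as.numeric(b)
  d - rep(b, each = nrow(d)) * round(d / rep(b, each = nrow(d)))
}

#' Minimum-image distance under orthorhombic periodicity
#'
#' @param p,q numeric 3-vectors (Angstrom).
#' @param b a [box()].
#' @return Euclidean distance to the nearest periodic image of `q`.
#' @examples
#' min_image_distance(c(0, 0, 0), c(9, 0, 0), box(10, 10, 10)) # 1
#' @export
min_image_distance <- function(p, q, b) {
  b <- as_box(b)
  d <- .pbc_delta(matrix(p - q, nrow = 1), b)
  sqrt(sum(d * d))
}

## squared minimum-image distance matrix between row sets P (n x 3), Q (m x 3)
.pbc_dist2_mat <- function(P, Q, b) {
  b <- as.numeric(b)
  d2 <- 0
  for (k in 1:3) {
    dk <- outer(P[, k], Q[, k], "-")
    dk <- dk - b[k] * round(dk / b[k])
    d2 <- d2 + dk * dk
  }
  d2
}

.pbc_dist_mat <- function(P, Q, b) sqrt(.pbc_dist2_mat(P, Q, b))

## for every row of Q, the minimum-image distance to the nearest row of P
.min_dist_to_set <- function(Q, P, b, chunk = 2048L) {
  n <- nrow(Q)
  out <- numeric(n)
  for (i0 in seq(1L, n, by = chunk)) {
    i1 <- min(i0 + chunk - 1L, n)
    d2 <- .pbc_dist2_mat(P, Q[i0:i1, , drop = FALSE], b)
    out[i0:i1] <- sqrt(do.call(pmin, lapply(seq_len(nrow(d2)), function(r) d2[r, ])))
  }
  out
}

## angle (degrees) between vectors u and v
.angle_deg <- function(u, v) {
  cosang <- sum(u * v) / sqrt(sum(u * u) * sum(v * v))
  acos(max(-1, min(1, cosang))) * 180 / pi
}

.cross3 <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

.unit <- function(v) {
  n <- sqrt(sum(v * v))
  if (n < 1e-12) stop("degenerate (zero-length) vector")
  v / n
}

## run an expression under a fixed RNG seed, restoring the caller's RNG state
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}
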