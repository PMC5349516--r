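# Internal helpers shared across the pipeline.

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded internals (k-means++
#' restarts, phantom noise) never disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, expr) {
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

# 3D cross product
cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v^2))

#' Bilinear interpolation on a matrix
#'
#' Samples `img` at fractional 1-based coordinates; coordinates outside the
#' grid return `fill`.
#'
#' @param img numeric matrix.
#' @param x,y numeric vectors of equal length (rows, columns; 1-based).
#' @param fill value for out-of-grid samples.
#' @return numeric vector of samples.
#' @keywords internal
#' @noRd
bilinear <- function(img, x, y, fill = 0) {
  M <- nrow(img); N <- ncol(img)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  out <- rep(fill, length(x))
  ok <- x >= 1 & x <= M & y >= 1 & y <= N
  if (!any(ok)) return(out)
  x0 <- pmin(pmax(x0[ok], 1L), M); y0 <- pmin(pmax(y0[ok], 1L), N)
  x1 <- pmin(x0 + 1, M); y1 <- pmin(y0 + 1, N)
  fxo <- fx[ok]; fyo <- fy[ok]
  v00 <- img[cbind(x0, y0)]; v10 <- img[cbind(x1, y0)]
  v01 <- img[cbind(x0, y1)]; v11 <- img[cbind(x1, y1)]
  out[ok] <- (1 - fxo) * (1 - fyo) * v00 + fxo * (1 - fyo) * v10 +
    (1 - fxo) * fyo * v01 + fxo * fyo * v11
  out
}

#' Trilinear interpolation in a 3D array
#'
#' Samples `vol` at fractional 1-based coordinates (x = first index,
#' y = second, z = slice). Out-of-volume samples return `fill`.
#'
#' @param vol numeric 3D array.
#' @param x,y,z numeric vectors of equal length.
#' @param fill value for out-of-volume samples.
#' @return numeric vector of samples.
#' @keywords internal
#' @noRd
trilinear <- function(vol, x, y, z, fill = 0) {
  d <- dim(vol)
  out <- rep(fill, length(x))
  ok <- x >= 1 & x <= d[1] & y >= 1 & y <= d[2] & z >= 1 & z <= d[3]
  if (!any(ok)) return(out)
  x <- x[ok]; y <- y[ok]; z <- z[ok]
  x0 <- pmin(pmax(floor(x), 1L), d[1]); fx <- x - x0
  y0 <- pmin(pmax(floor(y), 1L), d[2]); fy <- y - y0
  z0 <- pmin(pmax(floor(z), 1L), d[3]); fz <- z - z0
  x1 <- pmin(x0 + 1, d[1]); y1 <- pmin(y0 + 1, d[2]); z1 <- pmin(z0 + 1, d[3])
  idx <- function(i, j, k) vol[cbind(i, j, k)]
  v <- (1 - fz) * ((1 - fy) * ((1 - fx) * idx(x0, y0, z0) + fx * idx(x1, y0, z0)) +
                   fy * ((1 - fx) * idx(x0, y1, z0) + fx * idx(x1, y1, z0))) +
       fz * ((1 - fy) * ((1 - fx) * idx(x0, y0, z1) + fx * idx(x1, y0, z1)) +
             fy * ((1 - fx) * idx(x0, y1, z1) + fx * idx(x1, y1, z1)))
  out[ok] <- v
  out
}

# stopifnot-style check with a formatted message
check <- function(cond, fmt, ...) {
  if (!isTRUE(cond)) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}
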