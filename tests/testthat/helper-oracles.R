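# Independent oracles used across the test files. These deliberately avoid
# the package's own numerics: convolution is done by direct spatial
# summation, geometric shapes by dense area sampling, and line fits by the
# closed-form least-squares formulas.

# True 2D convolution with mirror padding, by direct summation.
# out[i, j] = sum_{da, db} k[c + da, c + db] * padded[i - da, j - db]
conv2_brute <- function(img, kernel, pad) {
  M <- nrow(img); N <- ncol(img)
  s <- nrow(kernel); hk <- (s - 1L) %/% 2L
  ix <- c(pad:1, 1:M, M:(M - pad + 1L))
  iy <- c(pad:1, 1:N, N:(N - pad + 1L))
  P <- img[ix, iy]
  out <- matrix(0, M, N)
  for (i in seq_len(M)) {
    for (j in seq_len(N)) {
      # kernel[c + da, c + db] pairs with P[i + pad - da, j + pad - db]:
      # the padded window is traversed in reverse (convolution, not
      # correlation)
      win <- P[(i + pad + hk):(i + pad - hk), (j + pad + hk):(j + pad - hk)]
      out[i, j] <- sum(kernel * win)
    }
  }
  out
}

# Anti-aliased annulus image by dense subpixel area sampling: pixel value =
# fraction of the pixel inside r_in <= r <= r_out.
make_annulus <- function(n, center, r_in, r_out, sub = 4L) {
  off <- (seq_len(sub) - 0.5) / sub - 0.5
  img <- matrix(0, n, n)
  for (ox in off) {
    for (oy in off) {
      X <- matrix(seq_len(n) + ox - center[1], n, n)
      Y <- matrix(seq_len(n) + oy - center[2], n, n, byrow = TRUE)
      R <- sqrt(X^2 + Y^2)
      img <- img + (R >= r_in & R <= r_out)
    }
  }
  img / sub^2
}

# Straight synthetic tube mask volume: annulus per slice, optional taper
# (radii as functions of slice index), hard (non-anti-aliased) mask.
make_tube_mask <- function(dims, center, r_in_px, r_out_px) {
  X <- matrix(seq_len(dims[1]) - center[1], dims[1], dims[2])
  Y <- matrix(seq_len(dims[2]) - center[2], dims[1], dims[2], byrow = TRUE)
  R <- sqrt(X^2 + Y^2)
  vol <- array(FALSE, dims)
  for (z in seq_len(dims[3])) {
    ri <- if (is.function(r_in_px)) r_in_px(z) else r_in_px
    ro <- if (is.function(r_out_px)) r_out_px(z) else r_out_px
    vol[, , z] <- R >= ri & R <= ro
  }
  vol
}

# Closed-form simple linear regression slope/intercept.
ols_line <- function(x, y) {
  sx <- sum(x); sy <- sum(y); n <- length(x)
  k <- (n * sum(x * y) - sx * sy) / (n * sum(x^2) - sx^2)
  c(k = k, m = (sy - k * sx) / n)
}
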