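# Texture filter bank: 36 Gabor quadrature filters + 4 difference-of-Gaussians.
#
# The bank follows the classic receptive-field-inspired design: Gabors model
# oriented simple cells (a sinusoid under an isotropic Gaussian window), DoGs
# model center-surround cells. All kernels are DC-free so that homogeneous
# image regions map to zero response, and the Gabors carry unit L2 norm so
# that Euclidean distances in response space weight all orientations and
# scales comparably.

#' Construct a Gabor kernel
#'
#' A 2D Gabor filter: a sinusoid of spatial frequency `omega` (cycles/pixel)
#' along orientation `theta`, with phase `phi`, windowed by an isotropic
#' Gaussian of standard deviation `sigma` (pixels). The kernel is corrected
#' to zero mean and normalized to unit L2 norm, so constant image regions
#' give zero response and all Gabors respond on a comparable scale.
#'
#' @param omega spatial frequency in cycles per pixel (> 0).
#' @param theta orientation in radians.
#' @param phi phase in radians; `0` gives the even (cosine) member of a
#'   quadrature pair, `pi/2` the odd one.
#' @param sigma standard deviation of the circular Gaussian window (pixels).
#' @param support side length of the (square, odd) kernel; defaults to
#'   covering +-3 sigma.
#' @return an object of class `ct_kernel`: a list with `values` (matrix),
#'   `kind = "gabor"` and `params`.
#' @examples
#' k <- gabor_kernel(0.25, pi / 6, 0, 2)
#' sum(k$values)              # ~ 0 (DC-free)
#' sum(k$values^2)            # 1 (unit L2 norm)
#' @export
gabor_kernel <- function(omega, theta, phi, sigma,
                         support = 2L * ceiling(3 * sigma) + 1L) {
  check(is.numeric(omega) && omega > 0, "gabor_kernel: omega must be > 0")
  check(is.numeric(sigma) && sigma > 0, "gabor_kernel: sigma must be > 0")
  support <- as.integer(support)
  check(support %% 2L == 1L && support >= 3L,
        "gabor_kernel: support must be odd and >= 3")
  h <- (support - 1L) / 2L
  xs <- -h:h
  X <- matrix(xs, support, support)
  Y <- matrix(xs, support, support, byrow = TRUE)
  u <- X * cos(theta) + Y * sin(theta)
  v <- exp(-(X^2 + Y^2) / (2 * sigma^2)) * cos(2 * pi * omega * u + phi)
  v <- v - mean(v)
  nrm <- sqrt(sum(v^2))
  check(nrm > 0, "gabor_kernel: degenerate (all-zero) kernel")
  structure(list(values = v / nrm, kind = "gabor",
                 params = list(omega = omega, theta = theta, phi = phi,
                               sigma = sigma)),
            class = "ct_kernel")
}

#' Construct a difference-of-Gaussians kernel
#'
#' Center-surround filter: the difference of two concentric Gaussians, each
#' normalized to unit discrete sum before subtraction, so the kernel has a
#' positive center (since `sigma_center < sigma_surround`) and exactly zero
#' sum.
#'
#' @param sigma_center standard deviation of the (narrow) center Gaussian,
#'   pixels.
#' @param sigma_surround standard deviation of the (wide) surround Gaussian,
#'   pixels; must exceed `sigma_center`.
#' @param support side length of the (square, odd) kernel; defaults to
#'   covering +-3 surround sigma.
#' @return an object of class `ct_kernel` with `kind = "dog"`.
#' @export
dog_kernel <- function(sigma_center, sigma_surround,
                       support = 2L * ceiling(3 * sigma_surround) + 1L) {
  check(is.numeric(sigma_center) && sigma_center > 0,
        "dog_kernel: sigma_center must be > 0")
  check(sigma_center < sigma_surround,
        "dog_kernel: sigma_center must be < sigma_surround")
  support <- as.integer(support)
  check(support %% 2L == 1L && support >= 3L,
        "dog_kernel: support must be odd and >= 3")
  h <- (support - 1L) / 2L
  xs <- -h:h
  R2 <- outer(xs^2, xs^2, "+")
  g1 <- exp(-R2 / (2 * sigma_center^2));   g1 <- g1 / sum(g1)
  g2 <- exp(-R2 / (2 * sigma_surround^2)); g2 <- g2 / sum(g2)
  structure(list(values = g1 - g2, kind = "dog",
                 params = list(sigma_center = sigma_center,
                               sigma_surround = sigma_surround)),
            class = "ct_kernel")
}

#' Default filter-bank configuration
#'
#' Three octave-spaced Gabor frequencies, six orientations, two phases
#' (quadrature pairs), and four DoG sigma pairs. The DoG pairs are
#' dimensionless fractions of `base_support` (pixels); the Gabor window is
#' inversely proportional to frequency, `sigma = C / omega`, with the
#' constant chosen so that the largest Gabor window matches the largest DoG
#' surround scale.
#'
#' @param base_support pixel scale that converts the dimensionless DoG sigma
#'   fractions into pixel sigmas (default 21, sized so the largest windows
#'   span the cortical shell without washing out its boundaries).
#' @return a list with components `frequencies`, `orientations`, `phases`,
#'   `dog_sigma_pairs`, `base_support`.
#' @export
default_bank_config <- function(base_support = 21) {
  list(
    frequencies = c(1 / 4, 1 / 8, 1 / 16),
    orientations = (0:5) * pi / 6,
    phases = c(0, pi / 2),
    dog_sigma_pairs = list(c(0.075, 0.125), c(0.125, 0.175),
                           c(0.175, 0.225), c(0.225, 0.275)),
    base_support = base_support
  )
}

#' Build the texture filter bank
#'
#' Assembles the ordered bank used for texture segmentation: all Gabors in a
#' fixed loop order (frequency outermost, then orientation, then phase),
#' followed by the DoGs. The default configuration yields 40 filters:
#' 3 frequencies x 6 orientations x 2 phases = 36 Gabors plus 4 DoGs.
#'
#' @param config list as returned by [default_bank_config()].
#' @return an object of class `filter_bank`: list with `kernels` (list of
#'   `ct_kernel`), `n_filters`, and the `config` used.
#' @examples
#' bank <- filter_bank()
#' bank$n_filters  # 40
#' @export
filter_bank <- function(config = default_bank_config()) {
  check(length(config$frequencies) >= 1, "filter_bank: no frequencies")
  dup <- anyDuplicated(expand.grid(f = config$frequencies,
                                   o = config$orientations,
                                   p = config$phases))
  if (dup > 0)
    warning("filter_bank: duplicate Gabor parameter tuples; duplicates kept")
  sigma_max <- max(vapply(config$dog_sigma_pairs, max, 0)) * config$base_support
  C <- sigma_max * min(config$frequencies)
  kernels <- list()
  for (f in config$frequencies)
    for (th in config$orientations)
      for (ph in config$phases)
        kernels[[length(kernels) + 1L]] <- gabor_kernel(f, th, ph, C / f)
  for (p in config$dog_sigma_pairs)
    kernels[[length(kernels) + 1L]] <-
      dog_kernel(p[1] * config$base_support, p[2] * config$base_support)
  structure(list(kernels = kernels, n_filters = length(kernels),
                 config = config),
            class = "filter_bank")
}

#' @export
print.filter_bank <- function(x, ...) {
  kinds <- vapply(x$kernels, function(k) k$kind, "")
  cat(sprintf("Texture filter bank: %d filters (%d Gabor, %d DoG)\n",
              x$n_filters, sum(kinds == "gabor"), sum(kinds == "dog")))
  sup <- vapply(x$kernels, function(k) nrow(k$values), 0L)
  cat(sprintf("  kernel supports: %d-%d px\n", min(sup), max(sup)))
  invisible(x)
}

#' Export the bank as a tiled kernel gallery
#'
#' Writes one grayscale TIFF tile per kernel arranged on a grid, each kernel
#' rescaled to `[0, 1]` for visual inspection.
#'
#' @param bank a [filter_bank()].
#' @param path output TIFF path.
#' @param ncol tiles per row.
#' @return `path`, invisibly.
#' @export
export_bank_gallery <- function(bank, path, ncol = 8) {
  sup <- max(vapply(bank$kernels, function(k) nrow(k$values), 0L))
  n <- bank$n_filters
  nrow_t <- ceiling(n / ncol)
  canvas <- matrix(0.5, nrow_t * sup, ncol * sup)
  for (i in seq_len(n)) {
    v <- bank$kernels[[i]]$values
    rng <- range(v)
    v <- if (diff(rng) > 0) (v - rng[1]) / diff(rng) else v * 0 + 0.5
    s <- nrow(bank$kernels[[i]]$values)
    off <- (s - 1) %/% 2
    r0 <- ((i - 1) %/% ncol) * sup + sup %/% 2 - off
    c0 <- ((i - 1) %% ncol) * sup + sup %/% 2 - off
    canvas[r0 + seq_len(s), c0 + seq_len(s)] <- v
  }
  tiff::writeTIFF(canvas, path, bits.per.sample = 8L)
  invisible(path)
}
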