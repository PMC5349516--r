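# Texture-based bone segmentation: filter responses in the Fourier domain,
# then two-cluster k-means++ on the per-pixel response vectors. A pixel is
# classified by its textural context rather than its raw intensity, which
# separates closely lying bones that are bridged by intermediate-intensity
# soft tissue (where plain thresholding merges them).

#' Per-pixel filter responses of one slice
#'
#' Convolves the slice with every kernel in the bank. Convolution is done in
#' the Fourier domain after symmetric (mirror) padding by half the largest
#' kernel support, then cropped back, so there are no wrap-around artifacts.
#'
#' @param slice numeric matrix (one grayscale CT slice).
#' @param bank a [filter_bank()].
#' @return numeric array `M x N x n_filters` of responses.
#' @export
filter_responses <- function(slice, bank) {
  check(is.matrix(slice) && is.numeric(slice), "filter_responses: slice must be a numeric matrix")
  check(all(is.finite(slice)), "filter_responses: non-finite pixel values")
  sup <- vapply(bank$kernels, function(k) nrow(k$values), 0L)
  p <- (max(sup) - 1L) %/% 2L
  M <- nrow(slice); N <- ncol(slice)
  check(M >= max(sup) && N >= max(sup),
        "filter_responses: slice (%dx%d) smaller than largest kernel support (%d)",
        M, N, max(sup))
  ix <- c(p:1, 1:M, M:(M - p + 1L))
  iy <- c(p:1, 1:N, N:(N - p + 1L))
  P <- slice[ix, iy]
  MP <- nrow(P); NP <- ncol(P)
  FI <- stats::fft(P)
  out <- array(0, c(M, N, bank$n_filters))
  for (i in seq_len(bank$n_filters)) {
    k <- bank$kernels[[i]]$values
    s <- nrow(k); hk <- (s - 1L) %/% 2L
    K <- matrix(0, MP, NP)
    K[1:s, 1:s] <- k
    # rotate so the kernel center sits at element (1, 1): circular
    # convolution then equals linear convolution on the padded image
    K <- K[c((hk + 1L):MP, seq_len(hk)), c((hk + 1L):NP, seq_len(hk))]
    R <- Re(stats::fft(FI * stats::fft(K), inverse = TRUE)) / (MP * NP)
    out[, , i] <- R[(p + 1L):(p + M), (p + 1L):(p + N)]
  }
  out
}

# k-means++ seeding (Arthur & Vassilvitskii): first center uniform, each
# subsequent center sampled with probability proportional to the squared
# distance to the nearest chosen center.
kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  C <- matrix(0, k, ncol(X))
  C[1, ] <- X[sample.int(n, 1L), ]
  d2 <- rowSums(sweep(X, 2, C[1, ])^2)
  for (j in seq_len(k - 1L) + 1L) {
    if (sum(d2) <= 0) {
      # remaining points coincide with a chosen center; fall back to uniform
      C[j, ] <- X[sample.int(n, 1L), ]
    } else {
      C[j, ] <- X[sample.int(n, 1L, prob = d2), ]
    }
    d2 <- pmin(d2, rowSums(sweep(X, 2, C[j, ])^2))
  }
  C
}

#' Segment one slice by k-means++ clustering of filter responses
#'
#' Partitions all pixels of a slice into two clusters by Euclidean distance
#' in filter-response space (k-means with k-means++ initialization, Lloyd
#' iterations, several restarts keeping the lowest within-cluster sum of
#' squares). The bone label goes to the cluster whose member pixels have the
#' higher mean *original* intensity, since bone is radiodense.
#'
#' @param features `M x N x n_filters` response array from
#'   [filter_responses()].
#' @param intensity the original `M x N` slice (used only to decide which
#'   cluster is bone).
#' @param seed integer RNG seed for the k-means++ restarts.
#' @param restarts number of k-means++ restarts (best inertia kept).
#' @param standardize if `TRUE`, z-score each feature across pixels before
#'   clustering (off by default: raw responses, Euclidean metric).
#' @return logical `M x N` bone mask.
#' @export
kmeans_segment <- function(features, intensity, seed = 0L, restarts = 10L,
                           standardize = FALSE) {
  d <- dim(features)
  check(length(d) == 3L, "kmeans_segment: features must be M x N x n_filters")
  check(all(is.finite(features)), "kmeans_segment: non-finite features")
  X <- matrix(features, d[1] * d[2], d[3])
  if (standardize) {
    s <- apply(X, 2, stats::sd)
    s[s == 0] <- 1
    X <- sweep(sweep(X, 2, colMeans(X)), 2, s, "/")
  }
  if (all(abs(sweep(X, 2, X[1, ])) < 1e-12)) {
    warning("kmeans_segment: all feature vectors identical; returning all-background")
    return(matrix(FALSE, d[1], d[2]))
  }
  best <- NULL
  with_seed(seed, {
    for (r in seq_len(restarts)) {
      C <- kmeanspp_centers(X, 2L)
      if (all(C[1, ] == C[2, ])) next
      km <- suppressWarnings(
        stats::kmeans(X, centers = C, algorithm = "Lloyd", iter.max = 100L))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  if (is.null(best)) {
    warning("kmeans_segment: degenerate clustering; returning all-background")
    return(matrix(FALSE, d[1], d[2]))
  }
  lab <- best$cluster
  m1 <- mean(intensity[lab == 1L])
  m2 <- mean(intensity[lab == 2L])
  bone <- if (m1 >= m2) lab == 1L else lab == 2L
  matrix(bone, d[1], d[2])
}

#' Texture-segment a whole stack
#'
#' Applies [filter_responses()] + [kmeans_segment()] slice by slice. Each
#' slice is clustered independently (the default) with a per-slice seed
#' derived from `seed`, so results are reproducible and slices are
#' parallelizable. With `scope = "stack"` all pixels of the stack are pooled
#' and clustered once.
#'
#' @param stack a [ct_stack()] or numeric 3D array.
#' @param bank a [filter_bank()].
#' @param seed base RNG seed; slice `i` uses `seed + i - 1`.
#' @param restarts k-means++ restarts per clustering.
#' @param scope `"slice"` (default) or `"stack"`.
#' @param standardize passed to [kmeans_segment()].
#' @return logical 3D array, `TRUE` = bone.
#' @export
segment_stack <- function(stack, bank, seed = 0L, restarts = 10L,
                          scope = c("slice", "stack"), standardize = FALSE) {
  scope <- match.arg(scope)
  vol <- if (inherits(stack, "ct_stack")) stack$voxels else stack
  d <- dim(vol)
  check(length(d) == 3L, "segment_stack: stack must be 3D")
  mask <- array(FALSE, d)
  if (scope == "slice") {
    for (z in seq_len(d[3])) {
      sl <- vol[, , z]
      resp <- tryCatch(filter_responses(sl, bank),
                       error = function(e) stop(sprintf("slice %d: %s", z, conditionMessage(e)), call. = FALSE))
      mask[, , z] <- kmeans_segment(resp, sl, seed = seed + z - 1L,
                                    restarts = restarts,
                                    standardize = standardize)
    }
  } else {
    feats <- vector("list", d[3])
    for (z in seq_len(d[3]))
      feats[[z]] <- matrix(filter_responses(vol[, , z], bank),
                           d[1] * d[2], bank$n_filters)
    X <- do.call(rbind, feats)
    big <- array(X, c(d[1], d[2] * d[3], bank$n_filters))
    m <- kmeans_segment(big, matrix(vol, d[1], d[2] * d[3]), seed = seed,
                        restarts = restarts, standardize = standardize)
    mask <- array(m, d)
  }
  mask
}

#' Baseline segmentation: global threshold plus morphological opening
#'
#' The reference scheme texture segmentation is compared against: a global
#' threshold (Otsu's method, or a fixed value) followed by a morphological
#' opening with a disc structuring element.
#'
#' @param slice numeric matrix.
#' @param method `"otsu"` or `"fixed"`.
#' @param threshold threshold value when `method = "fixed"` (same units as
#'   `slice`).
#' @param opening_radius disc radius (pixels) of the opening; `0` disables
#'   it.
#' @return logical bone mask.
#' @export
baseline_threshold_segment <- function(slice, method = c("otsu", "fixed"),
                                       threshold = NULL, opening_radius = 2L) {
  method <- match.arg(method)
  if (method == "otsu") {
    rng <- range(slice)
    if (diff(rng) == 0) return(matrix(FALSE, nrow(slice), ncol(slice)))
    norm <- (slice - rng[1]) / diff(rng)
    thr <- EBImage::otsu(EBImage::Image(norm), range = c(0, 1))
    mask <- norm > thr
  } else {
    check(!is.null(threshold), "baseline_threshold_segment: fixed method needs a threshold")
    mask <- slice > threshold
  }
  if (opening_radius > 0 && any(mask)) {
    brush <- EBImage::makeBrush(2L * as.integer(opening_radius) + 1L, "disc")
    mask <- EBImage::opening(EBImage::Image(mask * 1), brush) > 0.5
  }
  matrix(as.logical(mask), nrow(slice), ncol(slice))
}

#' Dice similarity coefficient of two binary masks
#'
#' `2 |A & B| / (|A| + |B|)`; two empty masks are defined to agree perfectly
#' (Dice 1).
#'
#' @param a,b logical arrays of identical shape.
#' @return a number in `[0, 1]`.
#' @export
dice <- function(a, b) {
  check(identical(dim(a), dim(b)), "dice: masks must have identical shape")
  a <- as.logical(a); b <- as.logical(b)
  s <- sum(a) + sum(b)
  if (s == 0) return(1)
  2 * sum(a & b) / s
}
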