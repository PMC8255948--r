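# Pixel feature maps and the kNN-sparsified radial Gaussian kernel
# matrix K used to represent the attenuation image as mu = K alpha.

#' Raw intensity-patch features
#'
#' Extracts, for every pixel, the intensities of the square patch
#' centred on it (replicate padding at the borders), in raster order
#' (patch row by patch row), one feature row per image pixel in the
#' package's column-wise pixel order.
#'
#' @param x Prior image (matrix), typically the X-ray CT.
#' @param patch_side Odd patch side length (default 3, i.e. 9 channels).
#' @return A `feature_map`: list with `features` (n_pix x C matrix),
#'   `kind = "patch"`, `normalized = FALSE`.
#' @export
extract_patch_features <- function(x, patch_side = 3L) {
  patch_side <- as.integer(patch_side)
  if (patch_side %% 2L == 0L || patch_side < 1L)
    stop("patch_side must be odd and positive")
  nr <- nrow(x); nc <- ncol(x)
  if (patch_side > nr || patch_side > nc)
    stop("patch larger than the image")
  half <- (patch_side - 1L) %/% 2L
  # replicate padding via index clamping
  ri <- pmin(pmax(seq_len(nr + 2 * half) - half, 1L), nr)
  ci <- pmin(pmax(seq_len(nc + 2 * half) - half, 1L), nc)
  xp <- x[ri, ci]
  C <- patch_side^2
  F <- matrix(0, nr * nc, C)
  ch <- 1L
  for (dr in seq_len(patch_side)) {      # raster order: patch row by row
    for (dc in seq_len(patch_side)) {
      F[, ch] <- as.vector(xp[(dr):(dr + nr - 1L), (dc):(dc + nc - 1L)])
      ch <- ch + 1L
    }
  }
  structure(list(features = F, kind = "patch", normalized = FALSE),
            class = "feature_map")
}

#' Standardize feature channels
#'
#' Centres every channel to zero mean and scales to unit standard
#' deviation across pixels; constant channels are mapped to zero. After
#' standardization the Gaussian kernel width sigma = 1 is the natural
#' default. Idempotent.
#'
#' @param F A `feature_map` (or bare matrix).
#' @return The standardized `feature_map` with `normalized = TRUE`.
#' @export
normalize_features <- function(F) {
  fm <- if (inherits(F, "feature_map")) F else {
    list(features = F, kind = "custom", normalized = FALSE)
  }
  M <- fm$features
  mu <- colMeans(M)
  sd <- apply(M, 2, stats::sd)
  Z <- sweep(M, 2, mu, "-")
  keep <- sd > 0
  Z[, keep] <- sweep(Z[, keep, drop = FALSE], 2, sd[keep], "/")
  Z[, !keep] <- 0
  structure(list(features = Z, kind = fm$kind, normalized = TRUE),
            class = "feature_map")
}

#' Build the kNN-sparsified radial Gaussian kernel matrix
#'
#' For every pixel j, the k nearest pixels in Euclidean feature distance
#' are retained (the pixel itself always included; remaining ties broken
#' by lower pixel index), weighted by the radial Gaussian kernel
#' `exp(-||f_j - f_l||^2 / (2 sigma^2))`, and each row is normalized to
#' sum to one, making K row-stochastic.
#'
#' @param F A `feature_map`, normally after [normalize_features()].
#' @param k Number of neighbours per pixel (default 50).
#' @param sigma Kernel width (default 1, appropriate for standardized
#'   features).
#' @param window Optional spatial search window: neighbours are then
#'   restricted to pixels within this Chebyshev radius (in pixels) of
#'   the query pixel. `NULL` (default) searches globally.
#' @param dims Image dimensions `c(n_rows, n_cols)`, required with
#'   `window`.
#' @return A row-stochastic `dgCMatrix` (n_pix x n_pix) with attributes
#'   `k`, `sigma`, `kind`.
#' @export
build_kernel_matrix <- function(F, k = 50L, sigma = 1, window = NULL,
                                dims = NULL) {
  M <- if (inherits(F, "feature_map")) F$features else F
  n <- nrow(M)
  k <- as.integer(k)
  if (k > n) stop("k cannot exceed the number of pixels")
  nn <- if (is.null(window)) knn_search(M, k)
        else .knn_windowed(M, k, as.integer(window), dims)
  w <- exp(-nn$d2 / (2 * sigma^2))
  w <- w / rowSums(w)
  K <- Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(nn$idx),
                            x = as.vector(w), dims = c(n, n))
  attr(K, "k") <- k
  attr(K, "sigma") <- sigma
  attr(K, "kind") <- if (inherits(F, "feature_map")) F$kind else "custom"
  K
}

# spatially windowed kNN: same selection rule (self first, then smallest
# feature distances with ties by lower index) among pixels within a
# Chebyshev radius on the image grid
.knn_windowed <- function(M, k, window, dims) {
  if (is.null(dims) || length(dims) != 2L)
    stop("dims = c(n_rows, n_cols) is required with a search window")
  nr <- dims[1]; nc <- dims[2]
  if (nr * nc != nrow(M)) stop("dims do not match the feature map")
  idx <- matrix(0L, nrow(M), k)
  d2 <- matrix(0, nrow(M), k)
  for (j in seq_len(nrow(M))) {
    r0 <- (j - 1L) %% nr + 1L
    c0 <- (j - 1L) %/% nr + 1L
    rows <- max(1L, r0 - window):min(nr, r0 + window)
    cols <- max(1L, c0 - window):min(nc, c0 + window)
    cand <- as.vector(outer(rows, (cols - 1L) * nr, `+`))
    cand <- cand[cand != j]
    if (length(cand) < k - 1L)
      stop("window too small to supply k neighbours")
    dd <- rowSums((M[cand, , drop = FALSE] -
                     rep(M[j, ], each = length(cand)))^2)
    ord <- order(dd, cand)[seq_len(k - 1L)]
    idx[j, ] <- c(j, cand[ord])
    d2[j, ] <- c(0, dd[ord])
  }
  list(idx = idx, d2 = d2)
}
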