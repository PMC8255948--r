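#' Parallel-beam TOF scanner geometry
#'
#' A generic 2D parallel-beam ring stand-in: `n_angles` views over 180
#' degrees, `n_radial` offsets per view, and an odd number of TOF bins
#' with a Gaussian timing profile. The default spatial TOF FWHM of
#' 8.25 cm corresponds to ~550 ps coincidence timing resolution
#' (c * 550 ps / 2).
#'
#' @param n_angles,n_radial Number of projection angles / radial bins.
#' @param radial_spacing Radial bin spacing in cm.
#' @param n_tof Odd number of TOF bins.
#' @param tof_fwhm Spatial TOF kernel FWHM in cm.
#' @param tof_bin_width TOF bin width in cm; `NULL` defaults to
#'   (field of view) / n_tof when the system is built.
#' @return `scanner_geometry` object.
#' @export
scanner_geometry <- function(n_angles = 180L, n_radial = 200L,
                             radial_spacing = 0.35, n_tof = 11L,
                             tof_fwhm = 8.25, tof_bin_width = NULL) {
  n_tof <- as.integer(n_tof)
  if (n_angles < 1L || n_radial < 1L) stop("geometry must have rays")
  if (n_tof < 1L || n_tof %% 2L == 0L) stop("n_tof must be odd and >= 1")
  if (tof_fwhm <= 0) stop("tof_fwhm must be > 0")
  structure(list(n_angles = as.integer(n_angles),
                 n_radial = as.integer(n_radial),
                 radial_spacing = radial_spacing, n_tof = n_tof,
                 tof_fwhm = tof_fwhm, tof_bin_width = tof_bin_width,
                 n_det = as.integer(n_angles) * as.integer(n_radial)),
            class = "scanner_geometry")
}

#' Build the emission and transmission system matrices
#'
#' Ray-traces the parallel-beam geometry over the grid (Siddon
#' intersection lengths) to form the transmission operator `A`
#' (n_det x n_pix, cm), and modulates each traced segment by a Gaussian
#' TOF profile evaluated at the segment's signed position along the ray
#' to form the TOF emission operators. The per-segment TOF weights are
#' renormalized to sum to one over bins, so the bin-summed emission
#' operator equals `A` exactly. The TOF operators are stored stacked
#' bin-major as one sparse matrix `G` ((n_det * n_tof) x n_pix).
#'
#' @param grid An [image_grid()].
#' @param geom A [scanner_geometry()].
#' @return `system_matrices` list: `A`, `G` (dgCMatrix), `c` (scalar or
#'   vector of multiplicative factors, default 1), `grid`, `geom`.
#' @export
build_system <- function(grid, geom) {
  stopifnot(inherits(grid, "image_grid"), inherits(geom, "scanner_geometry"))
  angles <- (seq_len(geom$n_angles) - 1) * pi / geom$n_angles
  offsets <- (seq_len(geom$n_radial) - (geom$n_radial + 1) / 2) *
    geom$radial_spacing
  tr <- trace_rays(grid$n_rows, grid$n_cols, grid$pixel_size, angles, offsets)

  n_det <- geom$n_det
  A <- Matrix::sparseMatrix(i = tr$ray + 1L, j = tr$pixel + 1L, x = tr$length,
                            dims = c(n_det, grid$n_pix))

  bw <- geom$tof_bin_width
  if (is.null(bw)) bw <- grid$n_cols * grid$pixel_size / geom$n_tof
  geom$tof_bin_width <- bw
  sigma <- geom$tof_fwhm / (2 * sqrt(2 * log(2)))
  te <- tof_expand(tr$ray, tr$pixel, tr$length, tr$s, n_det, geom$n_tof,
                   sigma, bw)
  G <- Matrix::sparseMatrix(i = te$i + 1L, j = te$j + 1L, x = te$v,
                            dims = c(n_det * geom$n_tof, grid$n_pix))

  structure(list(A = A, G = G, c = 1, grid = grid, geom = geom),
            class = "system_matrices")
}

#' TOF sinogram container
#'
#' @param values Nonnegative matrix (n_det x n_tof) of counts or
#'   expected counts.
#' @param geom The [scanner_geometry()] the values refer to.
#' @return `tof_sinogram` object.
#' @export
tof_sinogram <- function(values, geom) {
  if (any(values < 0)) stop("sinogram values must be nonnegative")
  if (nrow(values) != geom$n_det || ncol(values) != geom$n_tof)
    stop("sinogram shape must be n_det x n_tof")
  structure(list(values = values, geom = geom), class = "tof_sinogram")
}

.sino_values <- function(x) if (inherits(x, "tof_sinogram")) x$values else x

#' Attenuation (normalization) factors for a given attenuation image
#'
#' Computes `n[i, m] = c[i, m] * exp(-(A mu)[i])` for every detector
#' pair and TOF bin.
#'
#' @param mu Nonnegative attenuation image (matrix, 1/cm).
#' @param sys A [build_system()] result.
#' @return Matrix (n_det x n_tof) of factors in (0, c].
#' @export
attenuation_factors <- function(mu, sys) {
  if (any(mu < 0)) stop("mu must be nonnegative")
  am <- as.numeric(sys$A %*% as.vector(mu))
  matrix(sys$c * exp(-am), sys$geom$n_det, sys$geom$n_tof)
}

#' Expected TOF counts under the Poisson emission model
#'
#' `ybar_m = n_m(mu) * (G_m lambda) + r_m` per TOF bin.
#'
#' @param lam,mu Nonnegative activity / attenuation images.
#' @param r Background (randoms + scatter) expectation, sinogram-shaped
#'   (matrix or [tof_sinogram()]).
#' @param sys A [build_system()] result.
#' @return Matrix (n_det x n_tof) of expected counts.
#' @export
expected_counts <- function(lam, mu, r, sys) {
  if (any(lam < 0) || any(mu < 0)) stop("lam and mu must be nonnegative")
  r <- .sino_values(r)
  if (!all(dim(r) == c(sys$geom$n_det, sys$geom$n_tof)))
    stop("background shape must be n_det x n_tof")
  nfac <- attenuation_factors(mu, sys)
  gl <- matrix(as.numeric(sys$G %*% as.vector(lam)),
               sys$geom$n_det, sys$geom$n_tof)
  nfac * gl + r
}

#' Poisson log-likelihood of a TOF scan
#'
#' `L = sum(y * log(ybar) - ybar)` with the convention 0*log(0) = 0;
#' bins with `ybar = 0` and `y = 0` contribute zero, and `ybar = 0` with
#' `y > 0` is an impossible datum.
#'
#' @param y Observed counts (matrix or [tof_sinogram()]).
#' @param lam,mu,r,sys As in [expected_counts()].
#' @return Scalar log-likelihood (up to the data-only factorial term).
#' @export
log_likelihood <- function(y, lam, mu, r, sys) {
  y <- .sino_values(y)
  ybar <- expected_counts(lam, mu, r, sys)
  .loglik_from_ybar(y, ybar)
}

.loglik_from_ybar <- function(y, ybar) {
  if (any(ybar == 0 & y > 0))
    stop("expected count is zero where observed count is positive")
  pos <- ybar > 0
  sum(y[pos] * log(ybar[pos])) - sum(ybar)
}

#' Simulate a noisy TOF-PET scan of a phantom
#'
#' Scales the phantom activity so the total expected prompts equal
#' `total_events`, adds a uniform background making up
#' `background_fraction` of the total expectation (emulating randoms and
#' scatter), and draws independent Poisson counts.
#'
#' @param phantom A [make_phantom()] result.
#' @param sys A [build_system()] result on the phantom's grid.
#' @param total_events Total expected prompt events (default 5e6).
#' @param background_fraction Fraction of total expected prompts that is
#'   background (default 0.4); the alternative trues-relative reading is
#'   available via `background_relative_to = "trues"`.
#' @param seed Integer seed; the draw is reproducible.
#' @param background_relative_to `"prompts"` (default) or `"trues"`.
#' @return List: `y` (counts, [tof_sinogram()]), `r` (background
#'   expectation sinogram), `scale` (activity scale factor applied),
#'   `ybar` (noise-free expectation matrix).
#' @export
simulate_scan <- function(phantom, sys, total_events = 5e6,
                          background_fraction = 0.4, seed = 1L,
                          background_relative_to = c("prompts", "trues")) {
  background_relative_to <- match.arg(background_relative_to)
  if (total_events <= 0) stop("total_events must be > 0")
  if (background_fraction < 0 || background_fraction >= 1)
    stop("background_fraction must be in [0, 1)")
  nfac <- attenuation_factors(phantom$mu511, sys)
  gl <- matrix(as.numeric(sys$G %*% as.vector(phantom$activity)),
               sys$geom$n_det, sys$geom$n_tof)
  trues_unscaled <- sum(nfac * gl)
  if (trues_unscaled <= 0) stop("phantom projects to zero trues")

  if (background_relative_to == "prompts") {
    trues_target <- (1 - background_fraction) * total_events
    bg_total <- background_fraction * total_events
  } else {
    trues_target <- total_events / (1 + background_fraction)
    bg_total <- background_fraction * trues_target
  }
  scale <- trues_target / trues_unscaled
  nbin <- sys$geom$n_det * sys$geom$n_tof
  r <- matrix(bg_total / nbin, sys$geom$n_det, sys$geom$n_tof)
  ybar <- nfac * gl * scale + r
  y <- .with_seed(seed, matrix(stats::rpois(nbin, as.vector(ybar)),
                               sys$geom$n_det, sys$geom$n_tof))
  list(y = tof_sinogram(y, sys$geom), r = tof_sinogram(r, sys$geom),
       scale = scale, ybar = ybar)
}
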