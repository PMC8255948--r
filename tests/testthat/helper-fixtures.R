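# Shared small-scale fixtures, built once per test run.

.fix <- new.env(parent = emptyenv())

fix_get <- function(name, builder) {
  if (is.null(.fix[[name]])) .fix[[name]] <- builder()
  .fix[[name]]
}

small_grid <- function() image_grid(12, 12, 0.5)

small_geom <- function() {
  scanner_geometry(n_angles = 10, n_radial = 16, radial_spacing = 0.5,
                   n_tof = 3, tof_fwhm = 4)
}

small_system <- function() {
  fix_get("small_system", function() build_system(small_grid(), small_geom()))
}

# a random joint activity/attenuation instance on the small system with
# Poisson data, for update-step audits
small_instance <- function(seed = 11) {
  fix_get(paste0("inst", seed), function() {
    sys <- small_system()
    set.seed(seed)
    lam <- matrix(runif(144, 0.5, 2), 12, 12)
    mu <- matrix(runif(144, 0, 0.05), 12, 12)
    r <- matrix(0.2, sys$geom$n_det, sys$geom$n_tof)
    ybar <- expected_counts(lam, mu, r, sys)
    y <- matrix(rpois(length(ybar), as.vector(ybar) * 20),
                nrow(ybar), ncol(ybar))
    list(sys = sys, lam = lam * 20, mu = mu, r = r * 20,
         ybar = ybar * 20, y = y)
  })
}

# random sparse row-stochastic kernel matrix over n pixels
random_row_stochastic <- function(n, k = 5, seed = 3) {
  set.seed(seed)
  idx <- t(vapply(seq_len(n), function(j)
    c(j, sample(setdiff(seq_len(n), j), k - 1)), integer(k)))
  w <- matrix(runif(n * k, 0.1, 1), n, k)
  w <- w / rowSums(w)
  Matrix::sparseMatrix(i = rep(seq_len(n), k), j = as.vector(idx),
                       x = as.vector(w), dims = c(n, n))
}

desk_phantom <- function() {
  fix_get("desk_phantom", function() make_phantom(image_grid(64, 64, 0.35),
                                                  seed = 1))
}
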