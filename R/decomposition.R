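# Dual-energy multi-material decomposition: each pixel's
# (X-ray CT at 80 keV, GCT at 511 keV) pair is fit by a three-material
# basis (air, soft tissue/water, bone) under the sum-to-one constraint.

#' Dual-energy basis matrix
#'
#' The 2 x 3 matrix of linear attenuation coefficients (rows: 80 keV,
#' 511 keV; columns: air, soft, bone) taken from the material table.
#'
#' @param table A [make_material_table()] result.
#' @return Numeric 2 x 3 matrix `U`.
#' @export
make_basis_matrix <- function(table = make_material_table()) {
  U <- rbind(e80 = table["e80", ], e511 = table["e511", ])
  V <- U[, 2:3] - U[, 1]
  if (abs(det(crossprod(V))) < 1e-20)
    stop("basis matrix is rank-deficient after the sum constraint")
  U
}

# reduced 2x2 normal equations after eliminating rho_air = 1 - rho_s - rho_b
.decomp_solver <- function(U) {
  V <- U[, 2:3] - U[, 1]
  G <- crossprod(V)
  if (abs(det(G)) < 1e-20)
    stop("basis matrix is rank-deficient after the sum constraint")
  list(V = V, Ginv = solve(G), a = U[, 1])
}

#' Decompose one dual-energy measurement pixel
#'
#' Minimizes `||u - U rho||^2` subject to `sum(rho) = 1`, in closed form
#' by eliminating the air fraction and solving the 2 x 2 normal
#' equations. Only the sum constraint is enforced; fractions may leave
#' [0, 1] under noise unless `clip = TRUE`.
#'
#' @param u Length-2 vector `(x80, mu511)`.
#' @param U Basis matrix from [make_basis_matrix()].
#' @param clip Clip fractions to [0, 1] and renormalize (default FALSE).
#' @return Length-3 vector `(rho_air, rho_soft, rho_bone)` summing to 1.
#' @export
decompose_pixel <- function(u, U, clip = FALSE) {
  as.vector(decompose_image(matrix(u[1]), matrix(u[2]), U, clip = clip)$fractions)
}

#' Decompose a dual-energy image pair into material fractions
#'
#' Pixel-wise application of the constrained least-squares fit of
#' [decompose_pixel()], vectorized over the image.
#'
#' @param xct80 Low-energy (80 keV) attenuation image.
#' @param gct511 High-energy (511 keV) attenuation image, e.g. a
#'   reconstructed GCT.
#' @param U Basis matrix from [make_basis_matrix()].
#' @param clip Clip fractions to [0, 1] and renormalize (default FALSE).
#' @return A `fraction_images` list: `fractions` (n_pix x 3 matrix with
#'   columns air/soft/bone, rows summing to 1), `dim` (image shape).
#' @export
decompose_image <- function(xct80, gct511, U = make_basis_matrix(),
                            clip = FALSE) {
  if (!all(dim(xct80) == dim(gct511)))
    stop("xct80 and gct511 must share the same grid")
  sol <- .decomp_solver(U)
  R <- cbind(as.vector(xct80) - sol$a[1], as.vector(gct511) - sol$a[2])
  sb <- R %*% sol$V %*% sol$Ginv          # n x 2: (rho_soft, rho_bone)
  rho <- cbind(air = 1 - sb[, 1] - sb[, 2], soft = sb[, 1], bone = sb[, 2])
  if (clip) {
    rho <- pmin(pmax(rho, 0), 1)
    rho <- rho / rowSums(rho)
  }
  structure(list(fractions = rho, dim = dim(xct80)),
            class = "fraction_images")
}
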