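#' Image grid description
#'
#' A 2D pixel grid with square pixels, pixel-centre origin convention.
#' Pixels are flattened column-wise (R's native array order), so pixel
#' index `j = row + n_rows * (col - 1)`.
#'
#' @param n_rows,n_cols Number of rows / columns (each at least 8).
#' @param pixel_size Pixel side length in cm.
#' @return An object of class `image_grid` with fields `n_rows`, `n_cols`,
#'   `pixel_size` and the derived pixel count `n_pix`.
#' @export
image_grid <- function(n_rows = 180L, n_cols = 180L, pixel_size = 0.35) {
  n_rows <- as.integer(n_rows); n_cols <- as.integer(n_cols)
  if (n_rows < 8L || n_cols < 8L) stop("grid must be at least 8 x 8")
  if (!is.finite(pixel_size) || pixel_size <= 0) stop("pixel_size must be > 0")
  structure(list(n_rows = n_rows, n_cols = n_cols, pixel_size = pixel_size,
                 n_pix = n_rows * n_cols),
            class = "image_grid")
}

#' Linear attenuation coefficients of the basis materials
#'
#' Air, water (soft tissue surrogate) and ICRU-44 cortical bone at the
#' two energies of the PET-enabled dual-energy pair: 80 keV (X-ray CT)
#' and 511 keV (annihilation photons). Values are NIST XCOM mass
#' attenuation coefficients multiplied by nominal densities
#' (air 1.205e-3, water 1.0, cortical bone 1.92 g/cc).
#'
#' @return A `material_table`: a 2 x 3 numeric matrix (rows `e80`,
#'   `e511`; columns `air`, `soft`, `bone`), in 1/cm.
#' @export
make_material_table <- function() {
  tab <- rbind(
    e80  = c(air = 0.1662 * 1.205e-3, soft = 0.1837 * 1.0, bone = 0.2229 * 1.92),
    e511 = c(air = 0.0870 * 1.205e-3, soft = 0.0960 * 1.0, bone = 0.0895 * 1.92)
  )
  structure(tab, class = c("material_table", class(tab)))
}

# ellipse membership on a normalized [-1, 1]^2 grid of size nr x nc
.ellipse_mask_n <- function(nr, nc, cx, cy, ax, ay) {
  xs <- (seq_len(nc) - (nc + 1) / 2) / (nc / 2)
  ys <- (seq_len(nr) - (nr + 1) / 2) / (nr / 2)
  X <- matrix(xs, nr, nc, byrow = TRUE)
  Y <- matrix(ys, nr, nc)
  ((X - cx) / ax)^2 + ((Y - cy) / ay)^2 <= 1
}

# average ss x ss blocks (supersampled rasterization -> partial volume)
.block_mean <- function(M, ss) {
  nr <- nrow(M) / ss; nc <- ncol(M) / ss
  M <- matrix(colMeans(matrix(M, ss, nr * ss * nc)), nr, ss * nc)
  t(matrix(colMeans(matrix(t(M), ss, nc * nr)), nc, nr))
}

# bilinear upsampling of a coarse field to nr x nc (for lung texture)
.bilinear_up <- function(C, nr, nc) {
  up1 <- function(M, n_out) {
    n_in <- nrow(M)
    src <- pmin(pmax((seq_len(n_out) - 0.5) * n_in / n_out - 0.5, 0), n_in - 1)
    i0 <- floor(src); w <- src - i0; i1 <- pmin(i0 + 1, n_in - 1)
    M[i0 + 1, , drop = FALSE] * (1 - w) + M[i1 + 1, , drop = FALSE] * w
  }
  t(up1(t(up1(C, nr)), nc))
}

.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate the synthetic 2D chest phantom set
#'
#' Builds an ellipse-composed chest slice — body outline with a
#' subcutaneous fat layer, two lungs with textured parenchyma, liver,
#' spine, ribs along the chest wall, and two hot lesions — together with
#' its ground-truth activity image, 511 keV attenuation map, 80 keV
#' X-ray CT image, per-pixel material fractions (air / soft tissue /
#' bone) and liver and spine-bone ROI masks. Anatomy is rasterized on a
#' 4x supersampled grid and block-averaged, so organ boundaries carry
#' realistic partial-volume material mixtures (rib edges facing lung mix
#' all three basis materials). Both attenuation images are computed
#' exactly as `fractions %*% material column` at the respective energy,
#' so the noise-free pair decomposes back to the true fractions.
#'
#' Lesions are hot in the activity image only (soft-tissue attenuation),
#' mirroring a PET-avid lesion invisible to CT. Lung parenchyma is a
#' low-density mixture around 30% soft tissue with smooth seeded
#' texture; spine and ribs are 70% cortical bone / 30% soft tissue; the
#' fat layer is a 92% soft / 8% air mixture (density below water).
#'
#' @param grid An [image_grid()]. The default 180 x 180 grid has 32400
#'   pixels.
#' @param seed Integer seed; regeneration with the same (grid, seed) is
#'   bit-identical. The seed jitters organ placement by a few percent
#'   and draws the lung texture.
#' @param intensities Named list of relative activity levels
#'   (`lung`, `soft`, `liver`, `lesion`, `spine`).
#' @return A `phantom_set` list: `activity`, `mu511`, `xct80` (matrices,
#'   cm^-1 for the attenuation pair), `fractions` (n_pix x 3 matrix),
#'   `roi_liver`, `roi_bone` (logical matrices), `grid`, `table`.
#' @export
make_phantom <- function(grid = image_grid(), seed = 1L,
                         intensities = list(lung = 0.5, soft = 1.0,
                                            liver = 1.5, lesion = 4.0,
                                            spine = 1.0)) {
  stopifnot(inherits(grid, "image_grid"))
  tab <- make_material_table()
  ss <- 4L
  nr <- grid$n_rows; nc <- grid$n_cols
  NR <- nr * ss; NC <- nc * ss

  .with_seed(seed, {
    jit <- function(x, amt = 0.02) x + stats::runif(length(x), -amt, amt)
    body  <- c(jit(0.00), jit(-0.05), 0.92, 0.70)
    llung <- c(jit(-0.42), jit(0.05), jit(0.28, 0.01), jit(0.40, 0.01))
    rlung <- c(jit(0.42), jit(0.08), jit(0.26, 0.01), jit(0.38, 0.01))
    liver <- c(jit(0.30), jit(-0.34), 0.32, 0.21)
    spine <- c(jit(0.00, 0.01), jit(-0.50, 0.01), 0.12, 0.12)
    les1  <- c(jit(0.28), jit(-0.33), 0.055, 0.055)   # in liver
    les2  <- c(llung[1] + jit(0.02), llung[2] + jit(0.05), 0.06, 0.06) # in lung
    tex   <- matrix(stats::runif(144, 0.20, 0.45), 12, 12)  # lung texture
    btex  <- matrix(stats::runif(144, 0.25, 0.42), 12, 12)  # trabecular texture
    rib_y <- list(left = jit(c(0.52, 0.24, -0.04, -0.32), 0.01),
                  right = jit(c(0.55, 0.27, -0.01, -0.29), 0.01))
  })

  em <- function(p) .ellipse_mask_n(NR, NC, p[1], p[2], p[3], p[4])
  m_body <- em(body)
  m_inner <- .ellipse_mask_n(NR, NC, body[1], body[2],
                             body[3] - 0.07, body[4] - 0.07)
  m_fat <- m_body & !m_inner
  m_ll <- em(llung) & m_inner; m_rl <- em(rlung) & m_inner
  m_liver <- em(liver) & m_inner; m_spine <- em(spine) & m_inner
  m_les1 <- em(les1) & m_liver
  m_les2 <- em(les2) & m_ll

  # ribs: small cortical ellipses along the chest wall flanking the lungs
  m_rib <- matrix(FALSE, NR, NC)
  for (side in c(-1, 1)) {
    ys <- if (side < 0) rib_y$left else rib_y$right
    lung <- if (side < 0) llung else rlung
    for (y0 in ys) {
      cx <- side * (lung[1] * side + lung[3] + 0.045)
      m_rib <- m_rib | .ellipse_mask_n(NR, NC, cx, y0, 0.045, 0.075)
    }
  }
  m_rib <- m_rib & m_inner
  m_lung <- (m_ll | m_rl) & !m_liver & !m_spine & !m_rib
  m_liver <- m_liver & !m_spine & !m_rib

  # high-resolution soft-tissue fraction of the lung parenchyma
  lung_soft <- .bilinear_up(tex, NR, NC)
  # trabecular interior of the spine: cortical shell around a
  # bone/marrow mixture (marrow modelled as soft tissue below unit
  # density, giving genuine three-material voxels)
  m_trab <- .ellipse_mask_n(NR, NC, spine[1], spine[2],
                            spine[3] - 0.035, spine[4] - 0.035) & m_inner
  trab_bone <- .bilinear_up(btex, NR, NC)

  # compose per-pixel (air, soft, bone) on the supersampled grid
  A <- matrix(1, NR, NC); S <- matrix(0, NR, NC); B <- matrix(0, NR, NC)
  assign_mat <- function(mask, a, s, b) {
    A[mask] <<- a; S[mask] <<- s; B[mask] <<- b
  }
  assign_mat(m_body, 0, 1, 0)
  assign_mat(m_fat, 0.08, 0.92, 0)
  A[m_lung] <- 1 - lung_soft[m_lung]; S[m_lung] <- lung_soft[m_lung]
  B[m_lung] <- 0
  assign_mat(m_spine | m_rib, 0, 0.3, 0.7)
  A[m_trab] <- 0.12
  B[m_trab] <- trab_bone[m_trab]
  S[m_trab] <- 1 - 0.12 - trab_bone[m_trab]

  act_hi <- matrix(0, NR, NC)
  act_hi[m_body]  <- intensities$soft
  act_hi[m_lung]  <- intensities$lung
  act_hi[m_liver] <- intensities$liver
  act_hi[m_spine | m_rib] <- intensities$spine
  act_hi[m_les1 | m_les2] <- intensities$lesion

  # block-average to the acquisition grid: partial-volume edge mixtures
  a <- .block_mean(A, ss); s <- .block_mean(S, ss); b <- .block_mean(B, ss)
  act <- .block_mean(act_hi, ss)
  frac <- cbind(air = as.vector(a), soft = as.vector(s),
                bone = as.vector(b))

  # ROIs only over pixels fully interior to their organ
  liver_pure <- .block_mean(m_liver + 0, ss) >= 1
  spine_pure <- .block_mean(m_spine + 0, ss) >= 1
  lesion_any <- .block_mean(m_les1 + 0, ss) > 0
  roi_liver <- .ellipse_mask_n(nr, nc, liver[1] + 0.10, liver[2] - 0.02,
                               0.09, 0.07) & liver_pure & !lesion_any
  roi_bone <- .ellipse_mask_n(nr, nc, spine[1], spine[2], 0.06, 0.06) &
    spine_pure

  if (!any(m_lung) || !any(liver_pure) || !any(spine_pure) ||
      !any(roi_liver) || !any(roi_bone) || !any(m_les1) || !any(m_les2))
    stop("grid too small to place the phantom organs and ROIs")

  mu511 <- matrix(frac %*% tab["e511", ], nr, nc)
  xct80 <- matrix(frac %*% tab["e80", ], nr, nc)

  structure(list(activity = act, mu511 = mu511, xct80 = xct80,
                 fractions = frac, roi_liver = roi_liver,
                 roi_bone = roi_bone, grid = grid, table = tab,
                 seed = as.integer(seed)),
            class = "phantom_set")
}

#' Convert an 80 keV X-ray CT image to a 511 keV attenuation map
#'
#' Standard bilinear (piecewise-linear) conversion: values up to the
#' water value at 80 keV are scaled by the water 511/80 ratio; values
#' above are mapped along the water-to-bone segment. Used to initialize
#' the attenuation image in MLAA reconstructions.
#'
#' @param xct80 Nonnegative image (matrix) in 1/cm at 80 keV.
#' @param table A [make_material_table()] result.
#' @return Image of 511 keV attenuation coefficients, same shape.
#' @export
convert_ct_to_511 <- function(xct80, table = make_material_table()) {
  if (any(xct80 < 0)) stop("xct80 must be nonnegative")
  w80 <- table["e80", "soft"]; w511 <- table["e511", "soft"]
  b80 <- table["e80", "bone"]; b511 <- table["e511", "bone"]
  out <- ifelse(xct80 <= w80,
                xct80 * (w511 / w80),
                w511 + (xct80 - w80) * (b511 - w511) / (b80 - w80))
  pmax(out, 0)
}
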