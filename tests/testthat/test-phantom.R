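test_that("material table matches published attenuation coefficients", {
  tab <- make_material_table()
  # air is negligible at both energies
  expect_lt(tab["e80", "air"], 1e-3)
  expect_lt(tab["e511", "air"], 1e-3)
  # water (NIST XCOM x density 1.0)
  expect_equal(unname(tab["e511", "soft"]), 0.096, tolerance = 0.02)
  expect_equal(unname(tab["e80", "soft"]), 0.184, tolerance = 0.02)
  # physical orderings
  expect_gt(tab["e80", "bone"], tab["e80", "soft"])
  expect_gt(tab["e80", "soft"], tab["e80", "air"])
  expect_gt(tab["e80", "soft"], tab["e511", "soft"])
  expect_true(all(tab >= 0))
})

test_that("image grid validates its invariants", {
  g <- image_grid(64, 48, 0.35)
  expect_equal(g$n_pix, 64 * 48)
  expect_error(image_grid(4, 64, 0.35), "at least 8")
  expect_error(image_grid(64, 64, -1), "pixel_size")
})

test_that("phantom fractions are a valid mixture and attenuation is exact", {
  ph <- desk_phantom()
  tab <- ph$table
  expect_true(all(ph$fractions >= 0 & ph$fractions <= 1))
  expect_lt(max(abs(rowSums(ph$fractions) - 1)), 1e-12)
  # attenuation images are exactly the mixture times the basis
  expect_identical(as.vector(ph$mu511),
                   as.vector(ph$fractions %*% tab["e511", ]))
  expect_identical(as.vector(ph$xct80),
                   as.vector(ph$fractions %*% tab["e80", ]))
  # a pure soft-tissue pixel carries exactly the water value
  pure <- which(ph$fractions[, "soft"] == 1)
  expect_gt(length(pure), 0)
  expect_identical(unique(as.vector(ph$mu511)[pure]),
                   unname(tab["e511", "soft"]))
})

test_that("default phantom grid has 32400 pixels and valid ROIs", {
  ph <- fix_get("default_phantom", function() make_phantom(seed = 1))
  expect_equal(ph$grid$n_pix, 32400)
  expect_gt(sum(ph$roi_liver), 0)
  expect_gt(sum(ph$roi_bone), 0)
  # liver ROI is pure soft tissue, bone ROI has substantial bone content
  expect_true(all(ph$fractions[as.vector(ph$roi_liver), "soft"] == 1))
  expect_true(all(ph$fractions[as.vector(ph$roi_bone), "bone"] > 0.2))
  expect_true(all(ph$activity >= 0))
})

test_that("phantom regeneration with the same seed is bit-identical", {
  g <- image_grid(48, 48, 0.35)
  expect_identical(make_phantom(g, seed = 7), make_phantom(g, seed = 7))
  expect_false(identical(make_phantom(g, seed = 7)$xct80,
                         make_phantom(g, seed = 8)$xct80))
})

test_that("a grid too small for the organs is rejected", {
  expect_error(make_phantom(image_grid(8, 8, 0.5), seed = 1), "too small")
})

test_that("CT-to-511 conversion maps the breakpoints exactly", {
  tab <- make_material_table()
  x <- matrix(c(0, tab["e80", "soft"], tab["e80", "bone"]), 1, 3)
  out <- convert_ct_to_511(x, tab)
  expect_identical(out[1], 0)
  expect_equal(out[2], unname(tab["e511", "soft"]))
  expect_equal(out[3], unname(tab["e511", "bone"]))
  # piecewise linearity on each segment
  mid1 <- convert_ct_to_511(matrix(tab["e80", "soft"] / 2), tab)
  expect_equal(mid1[1], unname(tab["e511", "soft"]) / 2)
  mid2 <- convert_ct_to_511(
    matrix((tab["e80", "soft"] + tab["e80", "bone"]) / 2), tab)
  expect_equal(mid2[1],
               unname(tab["e511", "soft"] + tab["e511", "bone"]) / 2)
  expect_error(convert_ct_to_511(matrix(-0.1), tab), "nonnegative")
})

test_that("noise-free phantom pair decomposes back to the true fractions", {
  ph <- desk_phantom()
  fr <- decompose_image(ph$xct80, ph$mu511, make_basis_matrix(ph$table))
  expect_lt(max(abs(fr$fractions - ph$fractions)), 1e-10)
})

test_that("phantom round-trips through NIfTI files", {
  ph <- make_phantom(image_grid(48, 48, 0.35), seed = 2)
  dir <- tempfile("ph")
  write_phantom(ph, dir)
  ph2 <- read_phantom(dir)
  expect_equal(ph2$mu511, ph$mu511, tolerance = 1e-6)
  expect_equal(ph2$xct80, ph$xct80, tolerance = 1e-6)
  expect_equal(which(ph2$roi_liver), which(ph$roi_liver))
  unlink(dir, recursive = TRUE)
})
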