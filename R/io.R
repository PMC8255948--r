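# NIfTI persistence for phantom components and reconstructions, with a
# JSON sidecar carrying grid and material metadata.

#' Write a 2D image as a NIfTI file
#'
#' @param img Matrix.
#' @param path Output `.nii` path.
#' @param pixel_size Pixel size in cm (stored in mm in the header).
#' @return The path, invisibly.
#' @export
write_image <- function(img, path, pixel_size = 0.35) {
  nii <- RNifti::asNifti(array(img, c(nrow(img), ncol(img), 1L)))
  RNifti::pixdim(nii) <- c(pixel_size * 10, pixel_size * 10, 1)
  RNifti::writeNifti(nii, path)
  invisible(path)
}

#' Read a 2D image from a NIfTI file
#'
#' @param path `.nii` path.
#' @return Matrix.
#' @export
read_image <- function(path) {
  arr <- as.array(RNifti::readNifti(path))
  d <- dim(arr)
  if (length(d) == 2) matrix(arr, d[1], d[2]) else matrix(arr[, , 1], d[1], d[2])
}

#' Write a phantom set to a directory
#'
#' One NIfTI per component (`activity`, `mu511`, `xct80`, per-material
#' fraction images, integer-labelled ROI mask) plus a JSON sidecar with
#' the grid, seed and material table.
#'
#' @param phantom A [make_phantom()] result.
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  stopifnot(inherits(phantom, "phantom_set"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  ps <- phantom$grid$pixel_size
  write_image(phantom$activity, file.path(dir, "activity.nii"), ps)
  write_image(phantom$mu511, file.path(dir, "mu511.nii"), ps)
  write_image(phantom$xct80, file.path(dir, "xct80.nii"), ps)
  nr <- phantom$grid$n_rows; nc <- phantom$grid$n_cols
  for (m in colnames(phantom$fractions))
    write_image(matrix(phantom$fractions[, m], nr, nc),
                file.path(dir, paste0("frac_", m, ".nii")), ps)
  rois <- matrix(0L, nr, nc)
  rois[phantom$roi_liver] <- 1L
  rois[phantom$roi_bone] <- 2L
  write_image(rois, file.path(dir, "rois.nii"), ps)
  meta <- list(n_rows = nr, n_cols = nc, pixel_size = ps,
               seed = phantom$seed,
               material_table = as.data.frame(unclass(phantom$table)),
               roi_labels = list(liver = 1L, bone = 2L))
  jsonlite::write_json(meta, file.path(dir, "phantom.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Read a phantom set written by [write_phantom()]
#'
#' @param dir Directory containing the NIfTI components and sidecar.
#' @return A `phantom_set`.
#' @export
read_phantom <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "phantom.json"),
                              simplifyVector = TRUE)
  grid <- image_grid(meta$n_rows, meta$n_cols, meta$pixel_size)
  frac <- sapply(c("air", "soft", "bone"), function(m)
    as.vector(read_image(file.path(dir, paste0("frac_", m, ".nii")))))
  rois <- read_image(file.path(dir, "rois.nii"))
  tab <- as.matrix(meta$material_table)
  rownames(tab) <- c("e80", "e511")
  structure(list(activity = read_image(file.path(dir, "activity.nii")),
                 mu511 = read_image(file.path(dir, "mu511.nii")),
                 xct80 = read_image(file.path(dir, "xct80.nii")),
                 fractions = frac,
                 roi_liver = rois == 1, roi_bone = rois == 2,
                 grid = grid,
                 table = structure(tab, class = c("material_table",
                                                  class(tab))),
                 seed = meta$seed),
            class = "phantom_set")
}
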