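# Image and table I/O. Intensities are reals in [0, 1] in memory; 8-bit
# files are scaled on read/write.

#' Read an image file
#'
#' Reads PNG (via the png package) or TIFF (via the tiff package, if
#' installed) into a `[0, 1]` matrix or H x W x C array; an alpha channel is
#' dropped.
#'
#' @param path File path; format chosen by extension.
#' @return Numeric matrix or 3-d array in `[0, 1]`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
                png = png::readPNG(path),
                tif = ,
                tiff = {
                  if (!requireNamespace("tiff", quietly = TRUE)) {
                    stop("reading TIFF requires the 'tiff' package")
                  }
                  tiff::readTIFF(path)
                },
                stop("unsupported image format: .", ext,
                     " (PNG and TIFF are supported)"))
  if (length(dim(img)) == 3 && dim(img)[3] == 4) img <- img[, , 1:3]
  if (length(dim(img)) == 3 && dim(img)[3] == 2) img <- img[, , 1]
  img
}

#' Write a grayscale image as 8-bit PNG
#'
#' @param img Matrix in `[0, 1]` (clamped on write).
#' @param path Output path.
#' @export
write_gray_png <- function(img, path) {
  png::writePNG(clamp01(img), path)
  invisible(path)
}

#' Write a binary mask as a 0/255 PNG
#'
#' @param mask Logical or 0/1 matrix.
#' @param path Output path.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG((mask > 0) * 1, path)
  invisible(path)
}

#' Write phantom image, masks, and ground-truth summary to a directory
#'
#' Produces `image.png`, `lesion_mask.png`, `vessel_mask.png`,
#' `field_mask.png`, and `lesions.csv` (center_row, center_col, radius).
#'
#' @param phantom Result of [generate_phantom()].
#' @param dir Output directory (created if missing).
#' @return The directory, invisibly.
#' @export
write_phantom <- function(phantom, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_gray_png(phantom$image, file.path(dir, "image.png"))
  write_mask_png(phantom$truth$lesion_mask, file.path(dir, "lesion_mask.png"))
  write_mask_png(phantom$truth$vessel_mask, file.path(dir, "vessel_mask.png"))
  write_mask_png(phantom$truth$field_mask, file.path(dir, "field_mask.png"))
  utils::write.csv(phantom$truth$lesion_centers,
                   file.path(dir, "lesions.csv"), row.names = FALSE)
  invisible(dir)
}

#' Write a classified candidate table as CSV
#'
#' @param candidates Data frame from [classify_candidates()].
#' @param path Output path.
#' @export
write_candidates_csv <- function(candidates, path) {
  utils::write.csv(candidates, path, row.names = FALSE)
  invisible(path)
}
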