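# Grayscale PNG/TIFF reading and writing.

#' Read a grayscale image
#'
#' Reads an 8- or 16-bit grayscale PNG or TIFF and returns luminance in
#' \[0, 1\] (8-bit value v maps to v/255, 16-bit to v/65535; no gamma
#' correction).  Color images are rejected.
#'
#' @param path file path; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`).
#' @return numeric matrix in \[0, 1\].
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    "png" = png::readPNG(path),
    "tif" = ,
    "tiff" = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '.%s' (PNG or TIFF expected)", ext),
         call. = FALSE))
  if (length(dim(x)) == 3L) {
    if (dim(x)[3] == 1L) {
      x <- x[, , 1L]
    } else {
      stop(sprintf("color image with %d channels rejected; grayscale required",
                   dim(x)[3]), call. = FALSE)
    }
  }
  as_image_grid(x)
}

#' Write a grayscale image
#'
#' @param grid numeric matrix; values are clipped to \[0, 1\] and quantised
#'   to the requested bit depth.
#' @param path output path (`.png`, `.tif`, `.tiff`).
#' @param bits 8 or 16 (PNG output is 8-bit; use TIFF for 16-bit).
#' @return `path`, invisibly.
#' @export
write_image <- function(grid, path, bits = 8) {
  grid <- clip01(as_image_grid(grid))
  if (!bits %in% c(8, 16)) stop("`bits` must be 8 or 16", call. = FALSE)
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    "png" = {
      if (bits != 8) stop("PNG output is written at 8 bits; use TIFF for 16-bit",
                          call. = FALSE)
      png::writePNG(grid, path)
    },
    "tif" = ,
    "tiff" = tiff::writeTIFF(grid, path, bits.per.sample = bits),
    stop(sprintf("unsupported image format '.%s' (PNG or TIFF expected)", ext),
         call. = FALSE))
  invisible(path)
}
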