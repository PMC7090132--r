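#' Read a multi-page TIFF stack
#'
#' Reads a grayscale 8/12/16-bit multi-page TIFF into an [image_stack()]
#' (pages become z-planes; integer intensities are preserved).
#'
#' @param path TIFF file path.
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @return an [image_stack()].
#' @export
read_stack <- function(path, voxel_size = c(1, 1, 1)) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p <- p[, , 1] # drop extra channels
    p
  })
  d <- dim(pages[[1]])
  vox <- array(0L, c(length(pages), d[1], d[2]))
  for (z in seq_along(pages)) vox[z, , ] <- as.integer(pages[[z]])
  image_stack(vox, voxel_size)
}

#' Write a segmentation mask as a multi-page TIFF
#'
#' True voxels are written as 255, background as 0 (8-bit grayscale).
#'
#' @param mask logical 3D array or `smrg_mask`.
#' @param path output TIFF path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  if (inherits(mask, "smrg_mask")) mask <- mask$mask
  pages <- lapply(seq_len(dim(mask)[1]), function(z)
    matrix(as.numeric(mask[z, , ]), dim(mask)[2], dim(mask)[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' Write an intensity stack as a multi-page TIFF
#'
#' @param stack an [image_stack()].
#' @param path output TIFF path.
#' @param bits bits per sample (8 or 16).
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, bits = 16L) {
  maxval <- 2^bits - 1
  if (max(stack$voxels) > maxval)
    stop("intensities exceed the ", bits, "-bit range")
  pages <- lapply(seq_len(dim(stack$voxels)[1]), function(z)
    matrix(stack$voxels[z, , ] / maxval,
           dim(stack$voxels)[2], dim(stack$voxels)[3]))
  tiff::writeTIFF(pages, path, bits.per.sample = as.integer(bits))
  invisible(path)
}
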