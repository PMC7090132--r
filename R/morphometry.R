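#' Segmented volume
#'
#' True-voxel count times the voxel volume.
#'
#' @param mask logical 3D array or `smrg_mask`.
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @return volume in cubic micrometres.
#' @export
mask_volume <- function(mask, voxel_size = c(1, 1, 1)) {
  if (inherits(mask, "smrg_mask")) {
    voxel_size <- mask$voxel_size
    mask <- mask$mask
  }
  if (!any(mask)) stop("empty mask")
  sum(mask) * prod(voxel_size)
}

#' Surface area of a segmentation mask
#'
#' `voxel_face`: sum of the areas of voxel faces adjoining a background
#' voxel or the stack boundary.  `mesh`: area of the 0.5 iso-surface of the
#' Gaussian-smoothed (sigma = 1 voxel) indicator field, triangulated by
#' marching tetrahedra; the smoothing removes voxelization steps so curved
#' surfaces are measured close to their true area.
#'
#' @param mask logical 3D array or `smrg_mask`.
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @param method `"voxel_face"` or `"mesh"`.
#' @return area in square micrometres.
#' @export
surface_area <- function(mask, voxel_size = c(1, 1, 1),
                         method = c("voxel_face", "mesh")) {
  method <- match.arg(method)
  if (inherits(mask, "smrg_mask")) {
    voxel_size <- mask$voxel_size
    mask <- mask$mask
  }
  if (!any(mask)) stop("empty mask")
  dims <- dim(mask)
  dz <- voxel_size[1]; dy <- voxel_size[2]; dx <- voxel_size[3]
  if (method == "voxel_face") {
    exposed_along <- function(ax) {
      n <- dims[ax]
      pad_shift <- function(sh) {
        src <- seq_len(n) + sh
        out <- array(FALSE, dims)
        ok <- src >= 1 & src <= n
        if (any(ok)) {
          idx <- which(ok)
          out <- switch(ax,
            { a <- array(FALSE, dims); a[idx, , ] <- mask[src[ok], , , drop = FALSE]; a },
            { a <- array(FALSE, dims); a[, idx, ] <- mask[, src[ok], , drop = FALSE]; a },
            { a <- array(FALSE, dims); a[, , idx] <- mask[, , src[ok], drop = FALSE]; a })
        }
        out
      }
      sum(mask & !pad_shift(1L)) + sum(mask & !pad_shift(-1L))
    }
    face_area <- c(dy * dx, dz * dx, dz * dy) # faces normal to z, y, x
    return(exposed_along(1) * face_area[1] + exposed_along(2) * face_area[2] +
             exposed_along(3) * face_area[3])
  }
  # mesh: pad so surfaces at the stack border are closed, smooth, triangulate
  pad <- 4L
  big <- array(0, dims + 2L * pad)
  big[pad + seq_len(dims[1]), pad + seq_len(dims[2]), pad + seq_len(dims[3])] <-
    as.numeric(mask)
  sm <- .gauss_smooth(big, c(1, 1, 1))
  mt_area_cpp(as.vector(sm), dim(sm), voxel_size, 0.5)
}

#' Sholl intersection profile
#'
#' Counts, for each radius `k * step`, the number of 26-connected components
#' of the segmented voxels whose physical distance to the centre falls in
#' the spherical shell of half-width `h` (half the voxel diagonal) around
#' that radius — the number of processes crossing the Sholl sphere.
#'
#' @param mask logical 3D array or `smrg_mask`.
#' @param center integer `(z, y, x)` voxel (1-based), typically the soma
#'   centre.
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @param step shell spacing in micrometres.
#' @return object of class `sholl_profile`: data.frame with columns
#'   `radius` (micrometres) and `count`.
#' @export
sholl <- function(mask, center, voxel_size = c(1, 1, 1), step = 10) {
  if (inherits(mask, "smrg_mask")) {
    voxel_size <- mask$voxel_size
    mask <- mask$mask
  }
  if (step <= 0) stop("step must be positive")
  dims <- dim(mask)
  center <- as.numeric(center)
  w <- which(mask, arr.ind = TRUE)
  if (nrow(w) == 0) stop("empty mask")
  dist <- sqrt(((w[, 1] - center[1]) * voxel_size[1])^2 +
                 ((w[, 2] - center[2]) * voxel_size[2])^2 +
                 ((w[, 3] - center[3]) * voxel_size[3])^2)
  h <- 0.5 * sqrt(sum(voxel_size^2))
  kmax <- max(1L, floor((max(dist) + h) / step))
  lin <- .lin_index(w, dims)
  counts <- integer(kmax)
  for (k in seq_len(kmax)) {
    sel <- abs(dist - k * step) <= h
    if (!any(sel)) { counts[k] <- 0L; next }
    shell <- array(FALSE, dims)
    shell[lin[sel]] <- TRUE
    lab <- label_cc_cpp(as.vector(shell), dims, 26L)
    counts[k] <- attr(lab, "n_components")
  }
  structure(data.frame(radius = seq_len(kmax) * step, count = counts),
            class = c("sholl_profile", "data.frame"))
}

#' Area under a Sholl profile
#'
#' Trapezoidal integral of intersection counts over radius, summarising a
#' profile as a single number.
#'
#' @param profile a [sholl()] result, or any data.frame/list with `radius`
#'   and `count`.
#' @return the AUC (micrometres times counts).
#' @export
sholl_auc <- function(profile) {
  r <- profile$radius
  cnt <- profile$count
  if (length(r) < 2) stop("need at least 2 radii for the trapezoidal rule")
  if (any(diff(r) <= 0)) stop("radii must be strictly increasing")
  sum((cnt[-1] + cnt[-length(cnt)]) / 2 * diff(r))
}

#' Morphometric feature table
#'
#' One-row summary (volume, surface areas, Sholl AUC) of a segmentation,
#' as written by the command-line `morphometry` and `segment` commands.
#'
#' @param mask logical 3D array or `smrg_mask`.
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @param center Sholl centre `(z, y, x)`; default is the mask centroid.
#' @param step Sholl shell spacing (micrometres).
#' @return data.frame with columns `volume_um3`, `area_voxel_um2`,
#'   `area_mesh_um2`, `sholl_auc`.
#' @export
morphometry_table <- function(mask, voxel_size = c(1, 1, 1), center = NULL,
                              step = 10) {
  if (inherits(mask, "smrg_mask")) {
    voxel_size <- mask$voxel_size
    mask <- mask$mask
  }
  if (is.null(center)) {
    w <- which(mask, arr.ind = TRUE)
    center <- round(colMeans(w))
  }
  prof <- sholl(mask, center, voxel_size, step)
  auc <- if (nrow(prof) >= 2) sholl_auc(prof) else 0
  data.frame(volume_um3 = mask_volume(mask, voxel_size),
             area_voxel_um2 = surface_area(mask, voxel_size, "voxel_face"),
             area_mesh_um2 = surface_area(mask, voxel_size, "mesh"),
             sholl_auc = auc)
}
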