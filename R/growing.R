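#' 3D image stack
#'
#' Wrap a 3D array of non-negative integer intensities indexed `(z, y, x)`
#' together with its physical voxel size `(dz, dy, dx)` in micrometres.
#' Growth and connectivity operate in voxel space; the voxel size enters
#' only in morphometry and SWC export.
#'
#' @param voxels 3D numeric array of non-negative integers, dim `(Z, Y, X)`.
#' @param voxel_size numeric length-3 `(dz, dy, dx)` in micrometres/voxel.
#' @return object of class `image_stack`.
#' @export
image_stack <- function(voxels, voxel_size = c(1, 1, 1)) {
  if (!is.array(voxels) || length(dim(voxels)) != 3L)
    stop("voxels must be a 3D array indexed (z, y, x)")
  if (any(voxels < 0)) stop("intensities must be non-negative")
  if (length(voxel_size) != 3L || any(voxel_size <= 0))
    stop("voxel_size must be 3 positive numbers (dz, dy, dx)")
  structure(list(voxels = voxels, voxel_size = as.numeric(voxel_size)),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf("image_stack: %d x %d x %d (Z x Y x X), voxel %s um\n",
              d[1], d[2], d[3], paste(signif(x$voxel_size, 4), collapse = " x ")))
  invisible(x)
}

#' Region-growing configuration
#'
#' @param posterior_threshold signal-posterior admission threshold `tau`
#'   (default 0.999: neighbours whose probability of belonging to the signal
#'   exceeds 99.9\% are admitted).
#' @param crop_fraction on-plane divisor of the crop window (the local
#'   window is `M/crop_fraction x N/crop_fraction x crop_depth` for an
#'   `M x N` plane).
#' @param crop_min minimum on-plane crop edge (the crop is never smaller
#'   than `crop_min x crop_min x crop_depth`).
#' @param crop_depth crop depth in planes (odd).
#' @param dip_alpha significance level of the dip test gating mixture vs
#'   Otsu thresholding.
#' @param dip_B bootstrap resamples for the dip-test p-value.
#' @param connectivity voxel connectivity for region membership (26, 18 or 6).
#' @return object of class `grow_config`.
#' @export
grow_config <- function(posterior_threshold = 0.999, crop_fraction = 8,
                        crop_min = 32, crop_depth = 3, dip_alpha = 0.01,
                        dip_B = 2000L, connectivity = 26) {
  if (posterior_threshold <= 0 || posterior_threshold >= 1)
    stop("posterior_threshold must lie in (0, 1)")
  if (crop_min < 32) stop("crop_min must be at least 32")
  if (crop_depth %% 2 != 1) stop("crop_depth must be odd")
  if (!connectivity %in% c(6, 18, 26)) stop("connectivity must be 6, 18 or 26")
  structure(list(posterior_threshold = posterior_threshold,
                 crop_fraction = crop_fraction, crop_min = crop_min,
                 crop_depth = as.integer(crop_depth), dip_alpha = dip_alpha,
                 dip_B = as.integer(dip_B),
                 connectivity = as.integer(connectivity)),
            class = "grow_config")
}

.check_seed <- function(seed, dims) {
  seed <- as.integer(round(seed))
  if (length(seed) != 3L) stop("a seed is a (z, y, x) triple")
  if (any(seed < 1L) || any(seed > dims)) stop("seed out of bounds")
  seed
}

# window of length w along an axis of size n, centred at s (1-based);
# clip = truncate at the borders, expand = shift inward to keep length w
.axis_window <- function(s, w, n, expand) {
  if (w >= n) return(c(1L, n))
  a <- s - (w - 1L) %/% 2L
  b <- a + w - 1L
  if (expand) {
    if (a < 1L) { a <- 1L; b <- w }
    if (b > n) { b <- n; a <- n - w + 1L }
  } else {
    a <- max(a, 1L); b <- min(b, n)
  }
  c(as.integer(a), as.integer(b))
}

#' Extract the local crop around a seed
#'
#' Returns the `M/8 x N/8 x 3` window (on-plane fraction and depth from the
#' configuration, raised to the `crop_min` floor) centred on the seed.  At
#' stack borders the window is clipped by default; with `expand = TRUE` it
#' is shifted toward the interior so the crop keeps its full size whenever
#' the stack allows, which guarantees enough pixels for the mixture fit.
#'
#' @param stack an [image_stack()].
#' @param seed integer `(z, y, x)` voxel, 1-based.
#' @param config a [grow_config()].
#' @param expand shift the window inward instead of clipping.
#' @return list with `crop` (3D array) and `offset` (integer `(z, y, x)`
#'   such that `crop[c] == stack$voxels[c + offset]`).
#' @export
extract_crop <- function(stack, seed, config = grow_config(), expand = FALSE) {
  dims <- dim(stack$voxels)
  seed <- .check_seed(seed, dims)
  wy <- max(dims[2] %/% config$crop_fraction, config$crop_min)
  wx <- max(dims[3] %/% config$crop_fraction, config$crop_min)
  rz <- .axis_window(seed[1], config$crop_depth, dims[1], expand)
  ry <- .axis_window(seed[2], wy, dims[2], expand)
  rx <- .axis_window(seed[3], wx, dims[3], expand)
  crop <- stack$voxels[rz[1]:rz[2], ry[1]:ry[2], rx[1]:rx[2], drop = FALSE]
  list(crop = crop, offset = c(rz[1], ry[1], rx[1]) - 1L)
}

#' Segment one crop around a local seed
#'
#' The crop's intensity distribution is tested for unimodality with the dip
#' test.  Multimodal crops are thresholded with Otsu's method; unimodal
#' crops get the mixture model fitted by EM and voxels are admitted when
#' their signal posterior exceeds `posterior_threshold`.  In both branches
#' only voxels 26-connected (within the crop) to the seed are kept.  If the
#' EM fit does not converge the crop falls back to the Otsu branch with a
#' warning.
#'
#' @param crop 3D intensity array (a crop).
#' @param seed_local integer `(z, y, x)` of the seed within the crop, 1-based.
#' @param config a [grow_config()].
#' @return list with `mask` (logical array; empty if the seed fails the
#'   admission rule), `decision` (the [dip_test()] result) and `fit` (the
#'   [fit_em()] report or NULL on the Otsu branch).
#' @export
segment_crop <- function(crop, seed_local, config = grow_config()) {
  dims <- dim(crop)
  seed_local <- .check_seed(seed_local, dims)
  pix <- as.vector(crop)
  dec <- dip_test(pix, B = config$dip_B, alpha = config$dip_alpha)
  fit <- NULL
  admitted <- NULL
  use_otsu <- dec$multimodal
  if (!use_otsu) {
    fit <- fit_em(pix)
    if (!fit$converged) {
      warning("EM fit did not converge; falling back to Otsu thresholding")
      use_otsu <- TRUE
    } else {
      post <- signal_posterior(pix, fit$params)
      admitted <- post > config$posterior_threshold
    }
  }
  if (use_otsu) {
    admitted <- tryCatch(pix > otsu_threshold(pix),
                         error = function(e) rep(FALSE, length(pix)))
  }
  adm <- array(admitted, dim = dims)
  mask <- array(flood_cpp(adm, dims, seed_local - 1L, config$connectivity),
                dim = dims)
  list(mask = mask, decision = dec, fit = fit)
}

#' New seeds from the distance transform of a segmented crop
#'
#' For each plane of the local mask, the regional maxima of the 2D Euclidean
#' distance transform of the segmented foreground are taken as the next
#' generation of seeds (plateau-aware: a connected plateau of maximal
#' distance contributes its centroid voxel).
#'
#' @param local_mask logical 3D array (a segmented crop).
#' @param offset integer `(z, y, x)` crop offset from [extract_crop()].
#' @return integer matrix with columns `z, y, x` (stack coordinates,
#'   1-based); zero rows if the mask is empty.
#' @export
next_seeds <- function(local_mask, offset = c(0L, 0L, 0L)) {
  dims <- dim(local_mask)
  out <- NULL
  for (z in seq_len(dims[1])) {
    plane <- local_mask[z, , , drop = TRUE]
    if (!any(plane)) next
    pdim <- c(1L, dims[2], dims[3])
    sq <- edt_sq_cpp(as.vector(plane), pdim, c(1, 1, 1))
    lab <- regmax_cpp(sq, as.vector(plane), pdim, 26L)
    if (all(lab == 0L)) next
    labm <- matrix(lab, dims[2], dims[3])
    for (l in unique(lab[lab > 0L])) {
      w <- which(labm == l, arr.ind = TRUE)
      cen <- colMeans(w)
      # snap the plateau centroid to the nearest plateau voxel
      i <- which.min((w[, 1] - cen[1])^2 + (w[, 2] - cen[2])^2)
      out <- rbind(out, c(z, w[i, 1], w[i, 2]))
    }
  }
  if (is.null(out)) return(matrix(integer(0), 0, 3,
                                  dimnames = list(NULL, c("z", "y", "x"))))
  out <- out + rep(offset, each = nrow(out))
  out <- unique(out)
  colnames(out) <- c("z", "y", "x")
  out
}

#' Smart region growing over a seed queue
#'
#' Breadth-first main loop: pop a seed, extract the local crop, segment it
#' ([segment_crop()]), OR the local mask into the global one, and enqueue
#' the regional-maxima seeds of the new local mask ([next_seeds()]).  Each
#' voxel is used as a seed at most once, so the procedure terminates when
#' no unvisited seeds remain.  The global mask grows monotonically and every
#' admitted voxel is connected to an initial seed through admitted voxels.
#'
#' @param stack an [image_stack()].
#' @param seeds integer matrix with columns `(z, y, x)` (or a single length-3
#'   vector), 1-based voxel coordinates.
#' @param config a [grow_config()].
#' @param verbose print per-crop progress.
#' @return object of class `smrg_mask`: list with `mask` (logical 3D array),
#'   `seed_history` (matrix of processed seeds), `voxel_size`, `n_crops`.
#' @export
grow <- function(stack, seeds, config = grow_config(), verbose = FALSE) {
  dims <- dim(stack$voxels)
  if (any(dims < c(3, 32, 32)))
    stop("stack must be at least 3 x 32 x 32 (Z x Y x X) for segmentation")
  if (is.null(dim(seeds))) seeds <- matrix(seeds, nrow = 1)
  if (nrow(seeds) < 1) stop("at least one seed is required")
  for (i in seq_len(nrow(seeds))) .check_seed(seeds[i, ], dims)
  mode(seeds) <- "integer"

  nvox <- prod(dims)
  gmask <- array(FALSE, dims)
  tried <- array(FALSE, dims) # voxels ever enqueued as seeds
  queue <- matrix(0L, nrow = 256L, ncol = 3L)
  qhead <- 0L; qtail <- 0L
  push <- function(s) {
    if (qtail == nrow(queue)) queue <<- rbind(queue, matrix(0L, nrow(queue), 3L))
    qtail <<- qtail + 1L
    queue[qtail, ] <<- s
  }
  for (i in seq_len(nrow(seeds))) {
    s <- seeds[i, ]
    if (!tried[s[1], s[2], s[3]]) {
      tried[s[1], s[2], s[3]] <- TRUE
      push(s)
    }
  }

  history <- NULL
  n_crops <- 0L
  while (qhead < qtail && n_crops <= nvox) {
    qhead <- qhead + 1L
    s <- queue[qhead, ]
    cr <- extract_crop(stack, s, config, expand = TRUE)
    seg <- segment_crop(cr$crop, s - cr$offset, config)
    n_crops <- n_crops + 1L
    history <- rbind(history, s)
    if (!any(seg$mask)) next
    # OR into the global mask
    w <- which(seg$mask, arr.ind = TRUE)
    w <- w + rep(cr$offset, each = nrow(w))
    gmask[w] <- TRUE
    ns <- next_seeds(seg$mask, cr$offset)
    if (nrow(ns) > 0) {
      for (j in seq_len(nrow(ns))) {
        p <- ns[j, ]
        if (!tried[p[1], p[2], p[3]]) {
          tried[p[1], p[2], p[3]] <- TRUE
          push(p)
        }
      }
    }
    if (verbose)
      message(sprintf("crop %d: seed (%d,%d,%d) -> %d voxels, queue %d",
                      n_crops, s[1], s[2], s[3], sum(gmask), qtail - qhead))
  }
  if (!any(gmask))
    warning("no voxel passed the admission rule: empty segmentation")
  if (!is.null(history)) colnames(history) <- c("z", "y", "x")
  structure(list(mask = gmask, seed_history = history,
                 voxel_size = stack$voxel_size, n_crops = n_crops),
            class = "smrg_mask")
}

#' @export
print.smrg_mask <- function(x, ...) {
  cat(sprintf("smrg_mask: %s voxels segmented in %d crops (stack %s)\n",
              format(sum(x$mask), big.mark = ","), x$n_crops,
              paste(dim(x$mask), collapse = " x ")))
  invisible(x)
}

# separable gaussian smoothing of a 3D array (sigma in voxels per axis)
.gauss_smooth <- function(arr, sigma = c(1, 1, 1)) {
  dims <- dim(arr)
  out <- arr
  for (ax in 1:3) {
    s <- sigma[ax]
    if (s <= 0) next
    r <- max(1L, ceiling(3 * s))
    k <- exp(-((-r):r)^2 / (2 * s^2))
    k <- k / sum(k)
    out <- .conv_axis(out, k, ax)
  }
  out
}

# convolve along one axis with edge replication
.conv_axis <- function(arr, k, ax) {
  dims <- dim(arr)
  r <- (length(k) - 1L) %/% 2L
  n <- dims[ax]
  idx <- function(i) pmin(pmax(i, 1L), n)
  out <- array(0, dims)
  for (j in seq_along(k)) {
    sh <- j - r - 1L
    src <- idx(seq_len(n) + sh)
    out <- out + k[j] * switch(ax,
      arr[src, , , drop = FALSE],
      arr[, src, , drop = FALSE],
      arr[, , src, drop = FALSE])
  }
  out
}

#' Automatic soma detection by spherical Hough transform
#'
#' Searches the stack for spherical objects (somata) and proposes their
#' centres as seeds.  Surface voxels of the Otsu foreground vote along the
#' local intensity-gradient direction at every radius in the range; peaks in
#' the smoothed accumulator are the detected sphere centres, sorted by
#' accumulator score.
#'
#' @param stack an [image_stack()].
#' @param radius_range numeric `(rmin, rmax)` sphere radii in voxels.
#' @param min_score keep peaks scoring at least this fraction of the best
#'   peak.
#' @return integer matrix with columns `z, y, x` (1-based voxel centres),
#'   one row per detected soma; zero rows if nothing is found.
#' @export
detect_somata <- function(stack, radius_range = c(5, 15), min_score = 0.5) {
  if (any(radius_range <= 0) || radius_range[2] < radius_range[1])
    stop("radius_range must be positive and increasing")
  vox <- stack$voxels
  dims <- dim(vox)
  thr <- tryCatch(otsu_threshold(as.vector(vox)), error = function(e) NULL)
  if (is.null(thr)) return(matrix(integer(0), 0, 3,
                                  dimnames = list(NULL, c("z", "y", "x"))))
  fg <- vox > thr
  if (!any(fg)) return(matrix(integer(0), 0, 3,
                              dimnames = list(NULL, c("z", "y", "x"))))
  # boundary voxels of the foreground (some 6-neighbour is background)
  sq <- array(edt_sq_cpp(as.vector(fg), dims, c(1, 1, 1)), dims)
  boundary <- which(fg & sq <= 1, arr.ind = TRUE)
  # inward normals from the smoothed intensity gradient
  sm <- .gauss_smooth(vox, c(1.5, 1.5, 1.5))
  grad <- function(ax) {
    n <- dims[ax]
    hi <- pmin(seq_len(n) + 1L, n); lo <- pmax(seq_len(n) - 1L, 1L)
    switch(ax,
      (sm[hi, , , drop = FALSE] - sm[lo, , , drop = FALSE]) / 2,
      (sm[, hi, , drop = FALSE] - sm[, lo, , drop = FALSE]) / 2,
      (sm[, , hi, drop = FALSE] - sm[, , lo, drop = FALSE]) / 2)
  }
  gz <- grad(1); gy <- grad(2); gx <- grad(3)
  bz <- gz[boundary]; by <- gy[boundary]; bx <- gx[boundary]
  nrm <- sqrt(bz^2 + by^2 + bx^2)
  ok <- nrm > 1e-9
  boundary <- boundary[ok, , drop = FALSE]
  bz <- bz[ok] / nrm[ok]; by <- by[ok] / nrm[ok]; bx <- bx[ok] / nrm[ok]

  acc <- array(0, dims)
  for (r in seq(radius_range[1], radius_range[2], by = 1)) {
    cz <- round(boundary[, 1] + r * bz)
    cy <- round(boundary[, 2] + r * by)
    cx <- round(boundary[, 3] + r * bx)
    inb <- cz >= 1 & cz <= dims[1] & cy >= 1 & cy <= dims[2] &
      cx >= 1 & cx <= dims[3]
    if (!any(inb)) next
    ind <- cbind(cz[inb], cy[inb], cx[inb])
    lin <- (ind[, 3] - 1) * dims[1] * dims[2] + (ind[, 2] - 1) * dims[1] +
      ind[, 1]
    tab <- table(lin)
    acc[as.numeric(names(tab))] <- acc[as.numeric(names(tab))] + as.numeric(tab)
  }
  acc <- .gauss_smooth(acc, c(1, 1, 1))
  if (max(acc) <= 0) return(matrix(integer(0), 0, 3,
                                   dimnames = list(NULL, c("z", "y", "x"))))
  # greedy peak picking with non-maximum suppression at rmin spacing
  ord <- order(acc, decreasing = TRUE)
  peaks <- NULL; scores <- NULL
  cutoff <- min_score * max(acc)
  for (i in ord) {
    if (acc[i] < cutoff) break
    p <- arrayInd(i, dims)
    if (!is.null(peaks)) {
      d2 <- rowSums((peaks - rep(p, each = nrow(peaks)))^2)
      if (any(d2 < radius_range[1]^2)) next
    }
    peaks <- rbind(peaks, p)
    scores <- c(scores, acc[i])
    if (nrow(peaks) >= 64) break
  }
  if (is.null(peaks)) return(matrix(integer(0), 0, 3,
                                    dimnames = list(NULL, c("z", "y", "x"))))
  colnames(peaks) <- c("z", "y", "x")
  mode(peaks) <- "integer"
  peaks[order(scores, decreasing = TRUE), , drop = FALSE]
}
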