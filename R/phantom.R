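#' Specify a synthetic neuron phantom
#'
#' A phantom is a branching set of tapered tubes (capsules) plus an optional
#' spherical soma, rasterized into a voxel mask and rendered with the
#' background/signal noise model of confocal counts: background voxels are
#' `K0 + round(N(0, vB))` (clipped at 0), foreground voxels are
#' `K0 + NB(r, p)` with `(p, r)` derived from the requested signal mean and
#' variance.
#'
#' @param segments data.frame with one row per branch segment and columns
#'   `z0, y0, x0, z1, y1, x1` (start/end points, micrometres),
#'   `r0, r1` (start/end radii, micrometres) and `parent` (row index of the
#'   parent segment, 0 for segments attached to the soma/root).
#' @param soma optional list `(center = c(z, y, x), radius)` in micrometres.
#' @param stack_shape integer `(Z, Y, X)` voxel dimensions.
#' @param voxel_size `(dz, dy, dx)` micrometres/voxel.
#' @param noise list with `K0`, `vB`, `muS`, `vS` describing the rendering
#'   model.
#' @param rng_seed integer seed making the rendering reproducible.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(segments = NULL, soma = NULL, stack_shape,
                         voxel_size = c(1, 1, 1),
                         noise = list(K0 = 100, vB = 25, muS = 50, vS = 150),
                         rng_seed = 1L) {
  if (!is.null(segments)) {
    need <- c("z0", "y0", "x0", "z1", "y1", "x1", "r0", "r1", "parent")
    if (!all(need %in% names(segments)))
      stop("segments needs columns: ", paste(need, collapse = ", "))
    if (any(segments$r0 <= 0) || any(segments$r1 <= 0))
      stop("segment radii must be positive")
  }
  if (!is.null(soma) && soma$radius <= 0) stop("soma radius must be positive")
  if (noise$vS <= noise$muS)
    stop("signal must be overdispersed (vS > muS) for a negative binomial")
  structure(list(segments = segments, soma = soma,
                 stack_shape = as.integer(stack_shape),
                 voxel_size = as.numeric(voxel_size), noise = noise,
                 rng_seed = as.integer(rng_seed)),
            class = "phantom_spec")
}

# chessboard-step voxel trace of a segment (voxel coordinates, 1-based rows)
.trace_voxels <- function(a, b) {
  n <- max(abs(round(b) - round(a)), 1)
  t <- seq(0, 1, length.out = n + 1)
  pts <- round(outer(1 - t, a) + outer(t, b))
  pts[!duplicated(pts), , drop = FALSE]
}

#' Rasterize a phantom into ground truth
#'
#' Produces the ground-truth voxel mask (union of tapered capsules and the
#' soma sphere, voxel-centre-in-solid test) and the ground-truth centerline
#' as an SWC tree: each segment axis is traced at one-voxel lattice steps
#' and attached to the nearest node of its parent (or the soma centre).
#'
#' @param spec a [phantom_spec()].
#' @return object of class `phantom_truth`: list with `mask` (logical 3D
#'   array), `centerline` (an [swc()] in micrometres), `centerline_vox`
#'   (matrix of 1-based `(z, y, x)` voxel coordinates of the nodes) and
#'   `spec`.
#' @export
rasterize_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$stack_shape
  vs <- spec$voxel_size
  mask <- array(FALSE, dims)

  # voxel centres in physical coordinates along each axis
  zc <- (seq_len(dims[1]) - 1) * vs[1]
  yc <- (seq_len(dims[2]) - 1) * vs[2]
  xc <- (seq_len(dims[3]) - 1) * vs[3]

  paint_capsule <- function(a, b, r0, r1) {
    rmax <- max(r0, r1)
    lo <- pmin(a, b) - rmax; hi <- pmax(a, b) + rmax
    iz <- which(zc >= lo[1] & zc <= hi[1])
    iy <- which(yc >= lo[2] & yc <= hi[2])
    ix <- which(xc >= lo[3] & xc <= hi[3])
    if (!length(iz) || !length(iy) || !length(ix)) {
      if (any(lo < -rmax) || any(hi > c(max(zc), max(yc), max(xc)) + rmax))
        stop("segment outside the stack")
      return(invisible())
    }
    g <- expand.grid(z = zc[iz], y = yc[iy], x = xc[ix])
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      d2 <- (g$z - a[1])^2 + (g$y - a[2])^2 + (g$x - a[3])^2
      inside <- d2 <= r0^2
    } else {
      t <- ((g$z - a[1]) * ab[1] + (g$y - a[2]) * ab[2] +
              (g$x - a[3]) * ab[3]) / len2
      t <- pmin(pmax(t, 0), 1)
      d2 <- (g$z - (a[1] + t * ab[1]))^2 + (g$y - (a[2] + t * ab[2]))^2 +
        (g$x - (a[3] + t * ab[3]))^2
      inside <- d2 <= (r0 + t * (r1 - r0))^2
    }
    if (any(inside)) {
      idx <- as.matrix(expand.grid(z = iz, y = iy, x = ix))[inside, ,
                                                            drop = FALSE]
      mask[idx] <<- TRUE
    }
    invisible()
  }

  segs <- spec$segments
  if (!is.null(segs)) {
    for (i in seq_len(nrow(segs))) {
      a <- c(segs$z0[i], segs$y0[i], segs$x0[i])
      b <- c(segs$z1[i], segs$y1[i], segs$x1[i])
      if (any(a < 0) || any(b < 0) ||
          any(a > (dims - 1) * vs) || any(b > (dims - 1) * vs))
        stop("segment endpoint outside the stack")
      paint_capsule(a, b, segs$r0[i], segs$r1[i])
    }
  }
  if (!is.null(spec$soma))
    paint_capsule(spec$soma$center, spec$soma$center,
                  spec$soma$radius, spec$soma$radius)

  # ---- centerline tree ----
  nodes_vox <- NULL   # (z, y, x) voxel coords, 1-based
  parent <- integer(0)
  radius <- numeric(0)
  seg_nodes <- vector("list", if (is.null(segs)) 0 else nrow(segs))
  add_node <- function(v, par, r) {
    nodes_vox <<- rbind(nodes_vox, v)
    parent <<- c(parent, par)
    radius <<- c(radius, r)
    nrow(nodes_vox)
  }
  if (!is.null(spec$soma))
    add_node(round(spec$soma$center / vs) + 1, -1L, spec$soma$radius)
  if (!is.null(segs)) {
    for (i in seq_len(nrow(segs))) {
      a_vox <- c(segs$z0[i], segs$y0[i], segs$x0[i]) / vs + 1
      b_vox <- c(segs$z1[i], segs$y1[i], segs$x1[i]) / vs + 1
      tr <- .trace_voxels(a_vox, b_vox)
      rr <- seq(segs$r0[i], segs$r1[i], length.out = nrow(tr))
      # attachment: nearest node of the parent segment (or soma / none)
      att <- 0L
      cand <- if (segs$parent[i] > 0) seg_nodes[[segs$parent[i]]]
              else if (!is.null(spec$soma)) 1L else integer(0)
      if (length(cand)) {
        d2 <- rowSums((nodes_vox[cand, , drop = FALSE] -
                         rep(tr[1, ], each = length(cand)))^2)
        att <- cand[which.min(d2)]
      }
      ids <- integer(nrow(tr))
      prev <- if (att > 0) att else -1L
      for (k in seq_len(nrow(tr))) {
        # skip a first node identical to its attachment point
        if (prev > 0 && all(tr[k, ] == nodes_vox[prev, ])) {
          ids[k] <- prev
          next
        }
        prev <- add_node(tr[k, ], if (prev > 0) prev else -1L, rr[k])
        ids[k] <- prev
      }
      seg_nodes[[i]] <- unique(ids)
    }
  }
  if (is.null(nodes_vox)) {
    centerline <- NULL
    centerline_vox <- matrix(numeric(0), 0, 3)
  } else {
    centerline_vox <- unname(nodes_vox)
    centerline <- swc(data.frame(
      id = seq_len(nrow(nodes_vox)),
      type = ifelse(parent == -1L, 1L, 3L),
      x = (nodes_vox[, 3] - 1) * vs[3],
      y = (nodes_vox[, 2] - 1) * vs[2],
      z = (nodes_vox[, 1] - 1) * vs[1],
      radius = radius,
      parent = parent))
  }
  structure(list(mask = mask, centerline = centerline,
                 centerline_vox = centerline_vox, spec = spec),
            class = "phantom_truth")
}

#' Render a phantom into a noisy image stack
#'
#' Background voxels get discrete-normal counts around the offset `K0`;
#' mask voxels get `K0` plus negative-binomial counts with the spec's
#' signal mean and variance.  Rendering is a pure function of the spec
#' (same `rng_seed`, same stack).
#'
#' @param truth a [rasterize_phantom()] result.
#' @return an [image_stack()].
#' @export
render_phantom <- function(truth) {
  stopifnot(inherits(truth, "phantom_truth"))
  spec <- truth$spec
  nz <- spec$noise
  nb <- moments_to_nb(nz$muS, nz$vS)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(spec$rng_seed)
  n <- length(truth$mask)
  nfg <- sum(truth$mask)
  vox <- integer(n)
  vox[!truth$mask] <- pmax(nz$K0 + as.integer(round(rnorm(n - nfg, 0,
                                                          sqrt(nz$vB)))), 0L)
  vox[truth$mask] <- nz$K0 + rnbinom(nfg, size = nb$r, prob = nb$p)
  image_stack(array(vox, dim(truth$mask)), spec$voxel_size)
}

# contrast tiers: signal mean over background standard deviation ~ 10, 5, 2.5
.tier_noise <- function(tier) {
  muS <- switch(tier, high = 50, medium = 25, low = 12.5,
                stop("unknown tier: ", tier))
  list(K0 = 100, vB = 25, muS = muS, vS = 3 * muS)
}

#' Standard phantom suite
#'
#' Fixed, named phantoms at three contrast tiers (`muS/sqrt(vB)` of about
#' 10, 5 and 2.5), used throughout the tests and the acceptance runs:
#' a straight tube, a Y-branched tube, a multi-branch soma-bearing
#' ("Purkinje-like") tree, and two touching somata.  Seeds are fixed per
#' phantom and tier so the rendered stacks are reproducible.
#'
#' @param name one of `"tube"`, `"ybranch"`, `"purkinje"`, `"twosomata"`.
#' @param tier contrast tier: `"high"`, `"medium"` or `"low"`.
#' @param seed optional RNG seed overriding the fixed default.
#' @return list with `stack` (an [image_stack()]) and `truth` (a
#'   [rasterize_phantom()] result).
#' @export
phantom_suite <- function(name = c("tube", "ybranch", "purkinje",
                                   "twosomata"),
                          tier = c("high", "medium", "low"), seed = NULL) {
  name <- match.arg(name)
  tier <- match.arg(tier)
  noise <- .tier_noise(tier)
  base_seed <- c(tube = 101L, ybranch = 202L, purkinje = 303L,
                 twosomata = 404L)[name]
  tier_off <- c(high = 0L, medium = 1L, low = 2L)[tier]
  if (is.null(seed)) seed <- base_seed + tier_off

  seg <- function(a, b, r0, r1, parent = 0L)
    data.frame(z0 = a[1], y0 = a[2], x0 = a[3], z1 = b[1], y1 = b[2],
               x1 = b[3], r0 = r0, r1 = r1, parent = parent)
  spec <- switch(name,
    tube = phantom_spec(
      segments = seg(c(4, 23, 9), c(4, 23, 85), 3, 3),
      stack_shape = c(9, 48, 96), noise = noise, rng_seed = seed),
    ybranch = phantom_spec(
      segments = rbind(
        seg(c(10, 16, 64), c(12, 60, 64), 3.5, 3),
        seg(c(12, 60, 64), c(14, 100, 30), 3, 2.2, parent = 1L),
        seg(c(12, 60, 64), c(14, 100, 98), 3, 2.2, parent = 1L)),
      stack_shape = c(25, 128, 128), noise = noise, rng_seed = seed),
    purkinje = phantom_spec(
      segments = rbind(
        seg(c(12, 26, 48), c(12, 44, 48), 3.5, 3),
        seg(c(12, 44, 48), c(10, 70, 28), 3, 2, parent = 1L),
        seg(c(12, 44, 48), c(14, 72, 66), 3, 2, parent = 1L),
        seg(c(10, 70, 28), c(10, 86, 40), 2, 1.6, parent = 2L),
        seg(c(14, 72, 66), c(14, 86, 56), 2, 1.6, parent = 3L)),
      soma = list(center = c(12, 18, 48), radius = 8),
      stack_shape = c(25, 96, 96), noise = noise, rng_seed = seed),
    twosomata = phantom_spec(
      soma = list(center = c(12, 32, 24), radius = 8),
      segments = seg(c(12, 32, 24), c(12, 32, 39), 8, 8),
      stack_shape = c(25, 64, 64), noise = noise, rng_seed = seed))
  if (name == "twosomata") {
    # two touching spheres, expressed as soma + a second sphere via capsule
    spec$segments <- NULL
    spec$soma <- NULL
    spec <- phantom_spec(
      segments = rbind(
        seg(c(12, 32, 24), c(12, 32, 24), 8, 8),
        seg(c(12, 32, 39), c(12, 32, 39), 8, 8)),
      stack_shape = c(25, 64, 64), noise = noise, rng_seed = seed)
  }
  truth <- rasterize_phantom(spec)
  list(stack = render_phantom(truth), truth = truth)
}
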