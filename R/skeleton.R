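#' Skeletonize a segmentation mask
#'
#' Reduces the volumetric mask to a one-voxel-thick medial curve by
#' topology-preserving thinning: simple points (whose removal changes
#' neither the number of foreground components, background components nor
#' tunnels, by the standard local 26/6-connectivity characterization) are
#' deleted in order of increasing distance to the boundary until only the
#' centred medial curve remains; curve endpoints are preserved.  The
#' skeleton is a subset of the mask and has the same number of 26-connected
#' components.
#'
#' Short side branches ("spurs") produced by bumps of the segmentation
#' boundary are pruned: an endpoint chain attached to a junction is removed
#' when it is shorter than the local object radius at the junction (never
#' shorter than `min_spur`), and the result is re-thinned.  Pruning never
#' removes a whole component.
#'
#' Isolated internal cavities (background voxels not reachable from the
#' stack border, e.g. single sub-threshold voxels inside a neurite) are
#' filled first: the thinning is topology-preserving, so unfilled cavities
#' would force medial surfaces instead of curves.
#'
#' @param mask logical 3D array or an `smrg_mask`.
#' @param prune remove boundary-noise spurs (default TRUE).
#' @param min_spur minimum spur length (voxels) always considered noise.
#' @param fill_holes fill internal background cavities before thinning.
#' @return logical 3D array (the skeleton voxels).
#' @export
skeletonize <- function(mask, prune = TRUE, min_spur = 4, fill_holes = TRUE) {
  if (inherits(mask, "smrg_mask")) mask <- mask$mask
  stopifnot(is.array(mask), length(dim(mask)) == 3L)
  dims <- dim(mask)
  if (!any(mask)) return(array(FALSE, dims))
  if (fill_holes) mask <- .fill_holes(mask)
  pri <- edt_sq_cpp(as.vector(mask), dims, c(1, 1, 1))
  skel <- array(thin3d_cpp(as.vector(mask), dims, pri), dims)
  if (prune) {
    for (pass in 1:3) {
      pruned <- .prune_spurs(skel, sqrt(pri), min_spur)
      if (identical(pruned, skel)) break
      # re-thin: pruning can leave corner voxels that are now simple
      skel <- array(thin3d_cpp(as.vector(pruned), dims, pri), dims)
    }
  }
  skel
}

# remove endpoint chains shorter than max(min_spur, local radius at the
# junction they attach to); `radius` is the mask distance transform
.prune_spurs <- function(skel, radius, min_spur) {
  dims <- dim(skel)
  vox <- which(skel, arr.ind = TRUE)
  n <- nrow(vox)
  if (n < 3) return(skel)
  id_of <- array(0L, dims)
  id_of[vox] <- seq_len(n)
  nb <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  neighbors <- function(i) {
    q <- rep(vox[i, ], each = 26) + nb
    ok <- q[, 1] >= 1 & q[, 1] <= dims[1] & q[, 2] >= 1 & q[, 2] <= dims[2] &
      q[, 3] >= 1 & q[, 3] <= dims[3]
    ids <- id_of[q[ok, , drop = FALSE]]
    ids[ids > 0L]
  }
  adj <- lapply(seq_len(n), neighbors)
  deg <- lengths(adj)
  lin <- .lin_index(vox, dims)
  drop <- logical(n)
  for (e in which(deg == 1)) {
    chain <- e
    prev <- 0L
    cur <- e
    repeat {
      nxt <- setdiff(adj[[cur]], c(prev, chain))
      if (length(nxt) == 0) { chain <- NULL; break }      # isolated path
      if (deg[nxt[1]] >= 3) {                             # reached a junction
        thr <- max(min_spur, radius[lin[nxt[1]]])
        if (length(chain) >= thr) chain <- NULL
        break
      }
      if (length(nxt) > 1) { chain <- NULL; break }
      prev <- cur
      cur <- nxt[1]
      chain <- c(chain, cur)
      if (length(chain) > max(min_spur, max(radius[lin]), 64)) {
        chain <- NULL; break
      }
    }
    if (!is.null(chain)) drop[chain] <- TRUE
  }
  if (!any(drop)) return(skel)
  out <- skel
  out[vox[drop, , drop = FALSE]] <- FALSE
  out
}

# fill background components not 6-connected to the stack border
.fill_holes <- function(mask) {
  dims <- dim(mask)
  comp <- array(label_cc_cpp(as.vector(!mask), dims, 6L), dims)
  outside <- unique(c(comp[1, , ], comp[dims[1], , ], comp[, 1, ],
                      comp[, dims[2], ], comp[, , 1], comp[, , dims[3]]))
  mask | !(comp %in% c(0L, outside))
}

# linear (z,y,x) index helpers for voxel sets
.lin_index <- function(w, dims) {
  (w[, 3] - 1) * dims[1] * dims[2] + (w[, 2] - 1) * dims[1] + w[, 1]
}

#' Convert a skeleton to an SWC reconstruction
#'
#' Builds a spanning tree over 26-adjacent skeleton voxels rooted at the
#' skeleton voxel nearest the given root seed (breadth-first order, which
#' also breaks any cycles left by thinning), assigns each node the local
#' mask radius (Euclidean distance transform of the mask at the skeleton
#' voxel, scaled by the mean on-plane voxel size), and scales coordinates to
#' micrometres.  Additional skeleton components are rooted at their own
#' voxel nearest the seed.
#'
#' @param skeleton logical 3D array from [skeletonize()].
#' @param mask the segmentation mask the skeleton came from.
#' @param voxel_size `(dz, dy, dx)` in micrometres.
#' @param root integer `(z, y, x)` seed, 1-based; must be within 10 voxels
#'   of the skeleton.
#' @return object of class `swc`: data.frame with columns
#'   `id, type, x, y, z, radius, parent` (root type 1, others 3; coordinates
#'   and radii in micrometres; `parent = -1` for roots).
#' @export
skeleton_to_swc <- function(skeleton, mask, voxel_size = c(1, 1, 1), root) {
  if (inherits(mask, "smrg_mask")) mask <- mask$mask
  dims <- dim(skeleton)
  stopifnot(all(dim(mask) == dims))
  vox <- which(skeleton, arr.ind = TRUE)
  if (nrow(vox) == 0) stop("empty skeleton")
  root <- as.integer(round(root))
  d2root <- (vox[, 1] - root[1])^2 + (vox[, 2] - root[2])^2 +
    (vox[, 3] - root[3])^2
  if (min(d2root) > 100) stop("root seed is more than 10 voxels from skeleton")

  # voxel id lookup
  id_of <- array(0L, dims)
  id_of[vox] <- seq_len(nrow(vox))
  radii_vox <- sqrt(edt_sq_cpp(as.vector(mask), dims, c(1, 1, 1)))[
    .lin_index(vox, dims)]
  radii_vox[!is.finite(radii_vox)] <- max(dims) # mask with no background
  radius_um <- radii_vox * mean(voxel_size[2:3])

  n <- nrow(vox)
  visited <- logical(n)
  order_out <- integer(n)
  parent_out <- integer(n)
  k <- 0L
  nb <- as.matrix(expand.grid(dz = -1:1, dy = -1:1, dx = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  remaining <- order(d2root)
  for (start in remaining) {
    if (visited[start]) next
    # BFS from this component's voxel nearest the root
    queue <- integer(64); queue[1] <- start
    qh <- 0L; qt <- 1L
    visited[start] <- TRUE
    k <- k + 1L; order_out[k] <- start; parent_out[start] <- 0L
    while (qh < qt) {
      qh <- qh + 1L
      v <- queue[qh]
      p <- vox[v, ]
      for (j in seq_len(nrow(nb))) {
        q <- p + nb[j, ]
        if (any(q < 1L) || any(q > dims)) next
        w <- id_of[q[1], q[2], q[3]]
        if (w > 0L && !visited[w]) {
          visited[w] <- TRUE
          parent_out[w] <- v
          k <- k + 1L; order_out[k] <- w
          if (qt == length(queue)) queue <- c(queue, integer(length(queue)))
          qt <- qt + 1L; queue[qt] <- w
        }
      }
    }
  }
  # renumber in traversal order so parents precede children
  newid <- integer(n)
  newid[order_out] <- seq_len(n)
  v <- vox[order_out, , drop = FALSE]
  par <- parent_out[order_out]
  par_id <- ifelse(par == 0L, -1L, newid[pmax(par, 1L)])
  swc(data.frame(
    id = seq_len(n),
    type = ifelse(par_id == -1L, 1L, 3L),
    x = (v[, 3] - 1) * voxel_size[3],
    y = (v[, 2] - 1) * voxel_size[2],
    z = (v[, 1] - 1) * voxel_size[1],
    radius = radius_um[order_out],
    parent = par_id))
}

#' SWC reconstruction object
#'
#' Validates and classes a node table in the standard SWC layout: integer
#' `id` (contiguous from 1), structure `type`, physical coordinates
#' `x, y, z` (micrometres), node `radius` and `parent` id (`-1` for roots;
#' every parent must appear before its children).
#'
#' @param nodes data.frame with columns `id, type, x, y, z, radius, parent`.
#' @return the validated data.frame with class `swc`.
#' @export
swc <- function(nodes) {
  need <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!all(need %in% names(nodes))) stop("SWC table needs columns: ",
                                         paste(need, collapse = ", "))
  nodes <- nodes[, need]
  n <- nrow(nodes)
  if (n == 0) stop("empty reconstruction")
  if (!identical(as.integer(nodes$id), seq_len(n)))
    stop("node ids must be contiguous from 1")
  bad <- which(nodes$parent != -1 &
                 (nodes$parent < 1 | nodes$parent >= nodes$id))
  if (length(bad))
    stop("node ", nodes$id[bad[1]],
         ": parent must be a previously listed id (or -1)")
  class(nodes) <- c("swc", "data.frame")
  nodes
}

#' Read an SWC reconstruction file
#'
#' Whitespace-delimited 7-column SWC with `#` comment lines.  Node ids must
#' be contiguous from 1 with parents preceding children; malformed lines are
#' reported with their line number.
#'
#' @param path file path.
#' @return an [swc()] object.
#' @export
read_swc <- function(path) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  if (!any(keep)) stop("no SWC records in ", path)
  rows <- which(keep)
  parts <- strsplit(trimws(lines[keep]), "\\s+")
  bad <- which(vapply(parts, length, 1L) != 7L)
  if (length(bad))
    stop("malformed SWC line ", rows[bad[1]], " in ", path)
  m <- matrix(as.numeric(unlist(parts)), ncol = 7, byrow = TRUE)
  if (anyNA(m)) {
    r <- rows[which(rowSums(is.na(m)) > 0)[1]]
    stop("non-numeric field on SWC line ", r, " in ", path)
  }
  df <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                   x = m[, 3], y = m[, 4], z = m[, 5], radius = m[, 6],
                   parent = as.integer(m[, 7]))
  if (anyDuplicated(df$id))
    stop("duplicate node id ", df$id[anyDuplicated(df$id)], " in ", path)
  swc(df)
}

#' Write an SWC reconstruction file
#'
#' @param recon an [swc()] object.
#' @param path output path.
#' @param comment optional extra header lines (without the leading `#`).
#' @return `path`, invisibly.
#' @export
write_swc <- function(recon, path, comment = NULL) {
  recon <- swc(as.data.frame(recon))
  hdr <- c("# SWC reconstruction (id type x y z radius parent)",
           if (!is.null(comment)) paste("#", comment))
  body <- sprintf("%d %d %.4f %.4f %.4f %.4f %d",
                  recon$id, recon$type, recon$x, recon$y, recon$z,
                  recon$radius, recon$parent)
  writeLines(c(hdr, body), path)
  invisible(path)
}
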