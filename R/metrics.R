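# coerce an SWC object / data.frame / matrix to an n x 3 coordinate matrix
.node_coords <- function(a) {
  if (inherits(a, "swc") || (is.data.frame(a) && all(c("x", "y", "z") %in%
                                                     names(a))))
    return(as.matrix(a[, c("x", "y", "z")]))
  m <- as.matrix(a)
  if (ncol(m) != 3) stop("node sets must be n x 3 coordinate matrices or SWC")
  m
}

#' Nearest-neighbour distances between two node sets
#'
#' For each node of `A`, the minimum Euclidean distance to any node of `B`.
#'
#' @param A,B SWC reconstructions or `n x 3` coordinate matrices (units are
#'   whatever the inputs use: voxels for phantom work, micrometres for
#'   physical reconstructions).
#' @return numeric vector of length `nrow(A)`.
#' @export
nearest_distances <- function(A, B) {
  A <- .node_coords(A); B <- .node_coords(B)
  if (nrow(A) == 0 || nrow(B) == 0) stop("empty node set")
  tB <- t(B)
  vapply(seq_len(nrow(A)), function(i)
    sqrt(min(colSums((tB - A[i, ])^2))), numeric(1))
}

#' Spatial distance between two reconstructions
#'
#' Mean bidirectional nearest-node distance:
#' `SD = sum(d_AB)/(2|A|) + sum(d_BA)/(2|B|)`.
#'
#' @inheritParams nearest_distances
#' @return the spatial distance (same units as the inputs).
#' @export
spatial_distance <- function(A, B) {
  dab <- nearest_distances(A, B)
  dba <- nearest_distances(B, A)
  sum(dab) / (2 * length(dab)) + sum(dba) / (2 * length(dba))
}

#' Substantial spatial distance and its node percentage
#'
#' Restricts the bidirectional nearest-node distances to those exceeding the
#' tolerance `S`: `SSD` is the average of the two directional means over
#' those "substantially distant" nodes (an empty direction contributes 0),
#' and `ssd_pct` is the percentage of all nodes that contribute.
#'
#' @inheritParams nearest_distances
#' @param S tolerance threshold (same units as the node coordinates;
#'   2 voxels is the conventional choice).
#' @return list with `ssd` and `ssd_pct`.
#' @export
substantial_spatial_distance <- function(A, B, S = 2) {
  if (S < 0) stop("S must be non-negative")
  dab <- nearest_distances(A, B)
  dba <- nearest_distances(B, A)
  Dab <- dab[dab > S]
  Dba <- dba[dba > S]
  m <- function(v) if (length(v)) mean(v) else 0
  list(ssd = (m(Dab) + m(Dba)) / 2,
       ssd_pct = 100 * (length(Dab) + length(Dba)) /
         (length(dab) + length(dba)))
}

#' Precision, recall and F-score of a reconstruction
#'
#' Greedy one-to-one matching of test nodes `A` against reference nodes `B`
#' in ascending distance order; pairs within the tolerance `S` are true
#' positives.  `precision = TP/|A|`, `recall = TP/|B|`, `f_score` their
#' harmonic mean.  One-to-one matching prevents a dense reconstruction from
#' inflating precision.
#'
#' @inheritParams nearest_distances
#' @param S matching tolerance (same units as the node coordinates).
#' @return list of class `prf_result` with `precision`, `recall`, `f_score`,
#'   `threshold_S`, `n_matched`.
#' @export
precision_recall_f <- function(A, B, S) {
  if (S <= 0) stop("S must be positive")
  A <- .node_coords(A); B <- .node_coords(B)
  if (nrow(A) == 0 || nrow(B) == 0) stop("empty node set")
  tB <- t(B)
  d2 <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A))) d2[i, ] <- colSums((tB - A[i, ])^2)
  cand <- which(d2 <= S^2, arr.ind = TRUE)
  tp <- 0L
  if (nrow(cand) > 0) {
    ordc <- order(d2[cand])
    usedA <- logical(nrow(A)); usedB <- logical(nrow(B))
    for (k in ordc) {
      i <- cand[k, 1]; j <- cand[k, 2]
      if (!usedA[i] && !usedB[j]) {
        usedA[i] <- TRUE; usedB[j] <- TRUE
        tp <- tp + 1L
      }
    }
  }
  P <- tp / nrow(A); R <- tp / nrow(B)
  f <- if (P + R > 0) 2 * P * R / (P + R) else 0
  structure(list(precision = P, recall = R, f_score = f, threshold_S = S,
                 n_matched = tp), class = "prf_result")
}

#' Full reconstruction comparison
#'
#' Spatial distance, substantial spatial distance (+ percentage) and
#' precision/recall/F at the tolerance `S`.
#'
#' @inheritParams substantial_spatial_distance
#' @return list of class `comparison_result` with `sd`, `ssd`, `ssd_pct`,
#'   `precision`, `recall`, `f_score`, `threshold_S`, `n_A`, `n_B`.
#' @export
compare_reconstructions <- function(A, B, S = 2) {
  Am <- .node_coords(A); Bm <- .node_coords(B)
  ss <- substantial_spatial_distance(Am, Bm, S)
  prf <- precision_recall_f(Am, Bm, S)
  structure(list(sd = spatial_distance(Am, Bm), ssd = ss$ssd,
                 ssd_pct = ss$ssd_pct, precision = prf$precision,
                 recall = prf$recall, f_score = prf$f_score,
                 threshold_S = S, n_A = nrow(Am), n_B = nrow(Bm)),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf(
    "comparison (S=%g): SD=%.3f SSD=%.3f SSD%%=%.1f P=%.3f R=%.3f F=%.3f\n",
    x$threshold_S, x$sd, x$ssd, x$ssd_pct, x$precision, x$recall, x$f_score))
  invisible(x)
}
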