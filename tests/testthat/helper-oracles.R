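# Independent brute-force oracles used to validate the implementation.

# ---- dip statistic oracle -------------------------------------------------
# The dip is the smallest t for which a unimodal CDF G exists with
# sup|Fn - G| <= t.  At each data point x_i the value and left limit of G
# are boxed: i/n - t <= G(x_i) <= (i-1)/n + t (G may jump only at the mode).
# Feasibility for a fixed t is checked by a greatest-convex-minorant-style
# dynamic program over a value grid: for the convex (pre-mode) run the
# minimal admissible chord slope into each grid value is propagated node by
# node; the concave (post-mode) run is the same DP on the reflected sample.
# Modes at a data point (with an atom) and inside a gap are enumerated.
# Bisection on t then brackets the dip to grid accuracy.
oracle_dip <- function(x, G = 2001L, iters = 50L) {
  x <- sort(as.numeric(x))
  n <- length(x)
  stopifnot(n >= 2, !anyDuplicated(x))
  gs <- seq(0, 1, length.out = G)
  eps <- 1e-12

  # one DP step: from min-slope vector `prev` at the previous node, distance
  # dx, to the new node with value box [Lb, Ub]; returns min-slope vector
  step <- function(prev, dx, Lb, Ub) {
    h <- gs + dx * prev # minimal reachable g' from each previous g
    ordh <- order(h)
    hs <- h[ordh]
    cmg <- cummax(gs[ordh])
    pos <- findInterval(gs + eps, hs)
    cur <- rep(Inf, G)
    ok <- pos >= 1L & gs >= Lb - eps & gs <= Ub + eps
    cur[ok] <- (gs[ok] - cmg[pos[ok]]) / dx
    cur
  }
  box_only <- function(Lb, Ub) ifelse(gs >= Lb - eps & gs <= Ub + eps, 0, Inf)

  run_dp <- function(xs, Lv, Uv) {
    k <- length(xs)
    res <- vector("list", k)
    res[[1]] <- box_only(Lv[1], Uv[1])
    if (k >= 2) for (i in 2:k)
      res[[i]] <- step(res[[i - 1]], xs[i] - xs[i - 1], Lv[i], Uv[i])
    res
  }

  feasible <- function(t) {
    L <- (1:n) / n - t
    U <- (0:(n - 1)) / n + t
    left <- run_dp(x, L, U)
    xr <- rev(-x)
    right <- run_dp(xr, rev(1 - U), rev(1 - L)) # reflected problem
    fin <- function(v) any(is.finite(v))

    for (m in 1:n) { # mode at data point m (atom allowed at the mode)
      Lrel <- (m - 1) / n - t
      Urel <- (m - 1) / n + t
      lm <- if (m == 1) box_only(max(0, Lrel), Urel)
            else step(left[[m - 1]], x[m] - x[m - 1], Lrel, Urel)
      if (!fin(lm)) next
      k <- n + 1 - m # reversed index of node m
      Rrel_lo <- 1 - (m / n + t)
      Rrel_hi <- 1 - (m / n - t)
      rm <- if (k == 1) box_only(Rrel_lo, min(1, Rrel_hi))
            else step(right[[k - 1]], xr[k] - xr[k - 1], Rrel_lo, Rrel_hi)
      if (!fin(rm)) next
      minL <- min(gs[is.finite(lm)])
      maxG <- 1 - min(gs[is.finite(rm)])
      if (minL <= maxG + eps) return(TRUE)
    }
    for (m in 1:(n - 1)) { # mode inside the gap (x_m, x_{m+1}), no atom
      lm <- left[[m]]
      k <- n - m # reversed index of node m+1
      rm <- right[[k]]
      if (!fin(lm) || !fin(rm)) next
      dx <- x[m + 1] - x[m]
      gpL <- gs[is.finite(lm)] + dx * lm[is.finite(lm)]
      gR_max <- 1 - min(gs[is.finite(rm)])
      if (min(gpL) <= gR_max + eps) return(TRUE) # rise dominated by left slope
      gpR <- (1 - gs[is.finite(rm)]) - dx * rm[is.finite(rm)]
      gL_min <- min(gs[is.finite(lm)])
      if (max(gpR) >= gL_min - eps) return(TRUE) # rise dominated by right slope
    }
    FALSE
  }

  lo <- 0
  hi <- 0.5
  for (i in seq_len(iters)) {
    mid <- (lo + hi) / 2
    if (feasible(mid)) hi <- mid else lo <- mid
  }
  hi
}

# ---- reconstruction metric oracles (naive double loops) -------------------
oracle_nearest <- function(A, B) {
  vapply(seq_len(nrow(A)), function(i)
    min(sqrt(colSums((t(B) - A[i, ])^2))), numeric(1))
}

oracle_sd <- function(A, B) {
  dab <- oracle_nearest(A, B)
  dba <- oracle_nearest(B, A)
  sum(dab) / (2 * nrow(A)) + sum(dba) / (2 * nrow(B))
}

oracle_ssd <- function(A, B, S) {
  dab <- oracle_nearest(A, B)
  dba <- oracle_nearest(B, A)
  Dab <- dab[dab > S]
  Dba <- dba[dba > S]
  m <- function(v) if (length(v)) mean(v) else 0
  list(ssd = (m(Dab) + m(Dba)) / 2,
       ssd_pct = 100 * (length(Dab) + length(Dba)) / (nrow(A) + nrow(B)))
}

oracle_prf <- function(A, B, S) {
  d <- matrix(0, nrow(A), nrow(B))
  for (i in seq_len(nrow(A)))
    d[i, ] <- sqrt(colSums((t(B) - A[i, ])^2))
  pairs <- which(d <= S, arr.ind = TRUE)
  tp <- 0L
  if (nrow(pairs)) {
    usedA <- logical(nrow(A)); usedB <- logical(nrow(B))
    for (k in order(d[pairs])) {
      i <- pairs[k, 1]; j <- pairs[k, 2]
      if (!usedA[i] && !usedB[j]) {
        usedA[i] <- TRUE; usedB[j] <- TRUE; tp <- tp + 1L
      }
    }
  }
  P <- tp / nrow(A); R <- tp / nrow(B)
  list(precision = P, recall = R,
       f_score = if (P + R > 0) 2 * P * R / (P + R) else 0)
}

# ---- component pmf oracle (direct special-function formulas) --------------
oracle_mixture_pmf <- function(y, K0, vB, alpha, r, p) {
  k <- y - K0
  W <- ceiling(6 * sqrt(vB))
  Z <- sum(exp(-((-W):W)^2 / (2 * vB)))
  bg <- exp(-k^2 / (2 * vB)) / Z
  sg <- ifelse(k >= 0,
               exp(lgamma(k + r) - lgamma(k + 1) - lgamma(r) +
                     r * log(p) + k * log(1 - p)),
               0)
  alpha * bg + (1 - alpha) * sg
}

# ---- Otsu oracle (exhaustive double loop over cut points) -----------------
oracle_otsu <- function(y) {
  lv <- sort(unique(y))
  best <- -Inf; best_t <- lv[1]
  for (t in lv[-length(lv)]) {
    g0 <- y[y <= t]; g1 <- y[y > t]
    w0 <- length(g0) / length(y); w1 <- 1 - w0
    v <- w0 * w1 * (mean(g0) - mean(g1))^2
    if (v > best) { best <- v; best_t <- t }
  }
  best_t
}

# ---- misc helpers ---------------------------------------------------------
dice <- function(a, b) 2 * sum(a & b) / (sum(a) + sum(b))

# solid axis-aligned cylinder along x, radius r, centred in a (2r+3)^2 plane
make_cylinder <- function(r = 3, len = 60, pad = 3) {
  side <- 2 * (r + pad) + 1
  c0 <- r + pad + 1
  dims <- c(side, side, len + 2 * pad)
  arr <- array(FALSE, dims)
  for (z in seq_len(side)) for (y in seq_len(side))
    if ((z - c0)^2 + (y - c0)^2 <= r^2)
      arr[z, y, (pad + 1):(pad + len)] <- TRUE
  list(mask = arr, center = c(c0, c0), x_range = c(pad + 1, pad + len))
}
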