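#' Hartigan's dip statistic
#'
#' Maximum distance between the empirical CDF of the sample and the closest
#' unimodal CDF, computed with the iterative greatest-convex-minorant /
#' least-concave-majorant algorithm.  Lies in `[1/(2n), 1/4]`.
#'
#' @param x numeric sample (need not be sorted; ties allowed).
#' @return the dip statistic.
#' @examples
#' dip_stat(c(0, 1))          # 0.25, the two-point maximum
#' dip_stat(c(0, 1, 9, 10))   # 2/9, a strongly bimodal four-point sample
#' @export
dip_stat <- function(x) {
  x <- as.numeric(x)
  if (length(x) == 0) stop("empty sample")
  dip_stat_cpp(x)
}

# deterministic uniform(-1/2, 1/2) jitter used to de-quantize integer data
.fixed_jitter <- function(n, seed = 9397L) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  runif(n, -0.5, 0.5)
}

# memoised bootstrap null table of the dip under the uniform distribution;
# a fixed internal seed makes the decision deterministic while leaving the
# caller's RNG stream untouched
.dip_null_table <- function(n, B = 2000L, seed = 4242L) {
  key <- paste0("dipnull_", n, "_", B)
  if (!is.null(.smrg_cache[[key]])) return(.smrg_cache[[key]])
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  tab <- sort(dip_null_cpp(n, B))
  .smrg_cache[[key]] <- tab
  tab
}

#' Dip test for unimodality
#'
#' Tests the pixel intensity distribution of a crop for unimodality against
#' multimodality.  The p-value is obtained by bootstrap against the uniform
#' null (Hartigan's calibration recipe): `B` uniform samples of the same size
#' are drawn with a fixed internal seed and the p-value is the fraction of
#' null dips at least as large as the observed one.  Crops with fewer than 8
#' distinct values are declared unimodal by convention.  The decision drives
#' the thresholding branch of the growing loop: multimodal crops are
#' thresholded with Otsu's method, unimodal crops with the mixture model.
#'
#' Integer-quantized samples are dithered with deterministic uniform
#' (-1/2, 1/2) jitter before the test: quantization concentrates ties on
#' adjacent levels and would otherwise register as spurious multimodality
#' against the continuous null, while genuinely separated modes survive the
#' jitter unchanged.  Constant samples (or fewer than 4 values) are
#' unimodal by convention.
#'
#' @param pixels numeric intensity sample.
#' @param B number of bootstrap resamples.
#' @param alpha significance level for the multimodality call.
#' @param dither jitter integer samples before testing (default TRUE).
#' @return list of class `crop_decision` with elements `multimodal`,
#'   `dip_stat`, `p_value` and `method` (`"otsu"` or `"mixture"`).
#' @export
dip_test <- function(pixels, B = 2000L, alpha = 0.01, dither = TRUE) {
  x <- as.numeric(pixels)
  if (length(x) == 0) stop("empty sample")
  if (length(x) < 4L || length(unique(x)) < 2L) {
    return(structure(list(multimodal = FALSE, dip_stat = dip_stat_cpp(x),
                          p_value = 1, method = "mixture"),
                     class = "crop_decision"))
  }
  if (dither && all(x == round(x))) x <- x + .fixed_jitter(length(x))
  d <- dip_stat_cpp(x)
  tab <- .dip_null_table(length(x), B)
  p <- (1 + sum(tab >= d)) / (length(tab) + 1)
  multimodal <- p < alpha
  structure(list(multimodal = multimodal, dip_stat = d, p_value = p,
                 method = if (multimodal) "otsu" else "mixture"),
            class = "crop_decision")
}

#' @export
print.crop_decision <- function(x, ...) {
  cat(sprintf("crop_decision: dip=%.5f p=%.4f -> %s\n",
              x$dip_stat, x$p_value, x$method))
  invisible(x)
}

#' Otsu's threshold on an integer intensity sample
#'
#' Exhaustive maximisation of the between-class variance over the observed
#' intensity histogram.  Foreground is defined as strictly greater than the
#' returned threshold.
#'
#' @param pixels integer intensity sample with at least 2 distinct values.
#' @return the threshold intensity (a value such that `pixels > threshold`
#'   is the foreground class).
#' @export
otsu_threshold <- function(pixels) {
  y <- as.numeric(pixels)
  if (length(y) == 0) stop("empty sample")
  lo <- min(y); hi <- max(y)
  if (lo == hi) stop("constant input: Otsu threshold undefined")
  counts <- tabulate(y - lo + 1L, nbins = hi - lo + 1L)
  levels <- lo:hi
  n <- length(y)
  w0 <- cumsum(counts) / n
  m0 <- cumsum(counts * levels) / n
  mT <- m0[length(m0)]
  # between-class variance for cut after each level (foreground strictly >)
  valid <- w0 > 0 & w0 < 1
  sigma_b <- rep(-Inf, length(levels))
  sigma_b[valid] <- (mT * w0[valid] - m0[valid])^2 /
    (w0[valid] * (1 - w0[valid]))
  levels[which.max(sigma_b)]
}
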