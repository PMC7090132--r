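#' Background/signal mixture parameters
#'
#' Bundle the five parameters of the local intensity model used by the smart
#' region-growing predicate: photon counts `y` are background with
#' probability `alpha`, in which case `y - K0` follows a discrete normal
#' distribution with variance `vB` centred at zero, and signal otherwise, in
#' which case `y - K0` follows a negative binomial with size `r` and success
#' probability `p`.  `K0` is the integer detector offset shared by both
#' components.
#'
#' The negative-binomial component has mean `muS = r(1-p)/p` and variance
#' `vS = muS/p`, so `p <= 1` enforces the overdispersion (`vS >= muS`)
#' characteristic of fluorescence signal.
#'
#' @param K0 integer detector offset (counts).
#' @param vB background variance (counts^2), positive.
#' @param alpha background mixing weight in `[0, 1]`.
#' @param r negative-binomial size parameter, positive.
#' @param p negative-binomial success probability in `(0, 1]`.
#' @return An object of class `mixture_params`.
#' @examples
#' pars <- mixture_params(K0 = 100, vB = 25, alpha = 0.7, r = 20, p = 1/3)
#' nb_moments(pars) # signal mean 40, variance 120
#' @export
mixture_params <- function(K0, vB, alpha, r, p) {
  if (!is.numeric(K0) || length(K0) != 1L || K0 != round(K0))
    stop("K0 must be a single integer")
  if (!is.numeric(vB) || length(vB) != 1L || vB <= 0)
    stop("vB must be a single positive number")
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]")
  if (!is.numeric(r) || length(r) != 1L || r <= 0)
    stop("r must be positive")
  if (!is.numeric(p) || length(p) != 1L || p <= 0 || p > 1)
    stop("p must lie in (0, 1]")
  structure(list(K0 = as.integer(K0), vB = as.numeric(vB),
                 alpha = as.numeric(alpha), r = as.numeric(r),
                 p = as.numeric(p)),
            class = "mixture_params")
}

#' @export
print.mixture_params <- function(x, ...) {
  m <- nb_moments(x)
  cat(sprintf(
    "mixture_params: K0=%d vB=%.3f alpha=%.4f r=%.3f p=%.4f (muS=%.2f vS=%.2f)\n",
    x$K0, x$vB, x$alpha, x$r, x$p, m$muS, m$vS))
  invisible(x)
}

#' Signal mean and variance of the negative-binomial component
#'
#' @param params a [mixture_params()] object.
#' @return list with elements `muS` (signal mean above the offset) and `vS`
#'   (signal variance).
#' @export
nb_moments <- function(params) {
  stopifnot(inherits(params, "mixture_params"))
  muS <- params$r * (1 - params$p) / params$p
  list(muS = muS, vS = muS / params$p)
}

#' Method-of-moments inversion for the negative binomial
#'
#' Maps a signal mean/variance pair to the `(p, r)` parameterisation:
#' `p = muS/vS`, `r = muS^2/(vS - muS)`.
#'
#' @param muS signal mean (counts above the offset), positive.
#' @param vS signal variance (counts^2), must exceed `muS`.
#' @return list with elements `p` and `r`.
#' @examples
#' moments_to_nb(10, 20) # p = 0.5, r = 10
#' @export
moments_to_nb <- function(muS, vS) {
  if (!is.numeric(muS) || !is.numeric(vS) || muS <= 0)
    stop("muS must be positive")
  if (vS <= muS)
    stop("underdispersion: vS must exceed muS for a negative binomial")
  list(p = muS / vS, r = muS^2 / (vS - muS))
}

# normalising constant of the discrete normal: sum of exp(-k^2/(2 vB)) over
# the integer window [-W, W], W = ceiling(6 sqrt(vB))
.dnorm_discrete_Z <- function(vB) {
  W <- ceiling(6 * sqrt(vB))
  k <- (-W):W
  sum(exp(-k^2 / (2 * vB)))
}

# component pmfs at integer deviations k = y - K0 (vectorised over k)
.psi_B <- function(k, vB, logZ = log(.dnorm_discrete_Z(vB))) {
  exp(-k^2 / (2 * vB) - logZ)
}

.psi_S <- function(k, r, p) {
  out <- numeric(length(k))
  pos <- k >= 0
  out[pos] <- dnbinom(k[pos], size = r, prob = p)
  out
}

#' Mixture probability mass function
#'
#' Probability of observing intensity `y` under the background/signal
#' mixture: `alpha * psiB(y - K0) + (1 - alpha) * psiS(y - K0)`, where
#' `psiB` is the discrete normal background and `psiS` the negative-binomial
#' signal.  The signal component has support `y >= K0`.
#'
#' @param y integer intensity value(s).
#' @param params a [mixture_params()] object.
#' @return probability mass at each `y`.
#' @export
mixture_pdf <- function(y, params) {
  stopifnot(inherits(params, "mixture_params"))
  if (any(y != round(y))) stop("intensities must be integers")
  k <- y - params$K0
  params$alpha * .psi_B(k, params$vB) +
    (1 - params$alpha) * .psi_S(k, params$r, params$p)
}

# background responsibility alpha_y for each pixel
.bg_responsibility <- function(y, params) {
  k <- y - params$K0
  b <- params$alpha * .psi_B(k, params$vB)
  s <- (1 - params$alpha) * .psi_S(k, params$r, params$p)
  tot <- b + s
  out <- ifelse(tot > 0, b / tot, 1) # below-support outliers -> background
  out
}

#' Posterior probability of belonging to the signal
#'
#' One minus the background responsibility of each pixel under a fitted
#' mixture; this is the homogeneity predicate of the region-growing loop
#' (a voxel is admitted when its posterior exceeds the configured
#' threshold, 0.999 by default).
#'
#' @param pixels integer intensity vector.
#' @param params fitted [mixture_params()].
#' @return numeric vector of posteriors in `[0, 1]`.
#' @export
signal_posterior <- function(pixels, params) {
  stopifnot(inherits(params, "mixture_params"))
  1 - .bg_responsibility(pixels, params)
}

# observed-data log-likelihood (sum over pixels), guarded against underflow
.mixture_loglik <- function(y, params) {
  sum(log(pmax(mixture_pdf(y, params), 1e-300)))
}

# deterministic data-driven initialisation: offset at the histogram mode,
# background spread from the sub-mode pixels, signal moments from the rest
.em_init <- function(y) {
  tab <- tabulate(y + 1L)
  mode <- which.max(tab) - 1L
  bg <- y[y <= mode]
  vB <- max(var(c(bg, mode)), 0.25)
  if (is.na(vB)) vB <- 0.25
  cut <- mode + 2 * sqrt(vB)
  alpha <- min(max(mean(y <= cut), 1e-3), 1 - 1e-3)
  sig <- y[y > cut]
  if (length(sig) >= 2) {
    muS <- max(mean(sig) - mode, 1)
    vS <- max(var(sig), muS * 1.5)
  } else {
    muS <- max(max(y) - mode, 1)
    vS <- muS * 1.5
  }
  nb <- moments_to_nb(muS, vS)
  mixture_params(K0 = mode, vB = vB, alpha = alpha, r = nb$r, p = nb$p)
}

#' Fit the background/signal mixture by expectation-maximisation
#'
#' E-step: per-pixel background responsibilities under the current
#' parameters.  M-step: `alpha` is the mean responsibility; `K0` is found by
#' integer grid search around the histogram mode maximising the
#' responsibility-weighted background log-likelihood (with `vB` at its
#' conditional weighted-variance estimate); `(p, r)` come from
#' responsibility-weighted method of moments on `y - K0`.  Because the
#' moment update is not an exact likelihood maximiser, a step that would
#' decrease the log-likelihood is rejected and the previous parameters are
#' kept, so the reported trace is non-decreasing.
#'
#' @param pixels integer intensity vector (a local crop), at least 256 values.
#' @param init optional starting [mixture_params()]; by default a
#'   deterministic histogram-based initialisation is used so that fits are
#'   reproducible.
#' @param tol convergence tolerance on the relative log-likelihood change.
#' @param max_iter maximum number of EM iterations.
#' @return An object of class `smrg_fit`: list with elements `params`
#'   ([mixture_params()]), `loglik_trace`, `n_iter`, `converged`, `n_pixels`.
#' @examples
#' set.seed(1)
#' y <- c(100 + round(rnorm(2000, 0, 5)), 100 + rnbinom(1000, size = 20, prob = 1/3))
#' fit <- fit_em(y)
#' fit$params$alpha
#' @export
fit_em <- function(pixels, init = NULL, tol = 1e-6, max_iter = 200L) {
  y <- as.integer(pixels)
  if (length(y) < 256L) stop("need at least 256 pixels to fit the mixture")
  if (any(y < 0L)) stop("intensities must be non-negative")

  if (length(unique(y)) == 1L) {
    pars <- mixture_params(K0 = y[1], vB = 0.25, alpha = 1, r = 1, p = 0.5)
    return(structure(list(params = pars, loglik_trace = numeric(0),
                          n_iter = 0L, converged = FALSE,
                          n_pixels = length(y)),
                     class = "smrg_fit"))
  }

  pars <- if (is.null(init)) .em_init(y) else init
  tab <- tabulate(y + 1L)
  mode <- which.max(tab) - 1L
  K0_grid <- max(0L, mode - 10L):(mode + 10L)

  ll <- .mixture_loglik(y, pars)
  trace <- ll
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    ay <- .bg_responsibility(y, pars)

    alpha_new <- mean(ay)
    # K0, vB: maximise the responsibility-weighted background log-likelihood
    # over the integer offset grid (conditional vB = weighted variance)
    sw <- sum(ay)
    best <- NULL
    for (K0c in K0_grid) {
      d <- y - K0c
      vBc <- max(sum(ay * d^2) / max(sw, 1e-12), 0.25)
      obj <- sum(ay * (-d^2 / (2 * vBc))) - sw * log(.dnorm_discrete_Z(vBc))
      if (is.null(best) || obj > best$obj)
        best <- list(K0 = K0c, vB = vBc, obj = obj)
    }
    # (p, r): responsibility-weighted method of moments on y - K0
    w <- 1 - ay
    swS <- sum(w)
    dS <- y - best$K0
    degenerate <- FALSE
    if (swS < 1e-8) {
      degenerate <- TRUE
    } else {
      muS <- sum(w * dS) / swS
      if (muS <= 0) {
        degenerate <- TRUE
      } else {
        vS <- sum(w * (dS - muS)^2) / swS
        if (vS <= muS) { # underdispersion guard
          p_new <- 0.99
          r_new <- muS * p_new / (1 - p_new)
        } else {
          nb <- moments_to_nb(muS, vS)
          p_new <- nb$p
          r_new <- nb$r
        }
      }
    }
    if (degenerate) {
      pars <- mixture_params(best$K0, best$vB, 1, pars$r, pars$p)
      return(structure(list(params = pars, loglik_trace = trace,
                            n_iter = it, converged = FALSE,
                            n_pixels = length(y)),
                       class = "smrg_fit"))
    }
    cand <- mixture_params(best$K0, best$vB, alpha_new, r_new, p_new)
    ll_new <- .mixture_loglik(y, cand)
    if (ll_new < ll) { # inexact M-step went downhill: keep previous params
      converged <- TRUE
      break
    }
    pars <- cand
    trace <- c(trace, ll_new)
    if (abs(ll_new - ll) <= tol * (abs(ll) + 1e-12)) {
      ll <- ll_new
      converged <- TRUE
      break
    }
    ll <- ll_new
  }
  structure(list(params = pars, loglik_trace = trace, n_iter = it,
                 converged = converged, n_pixels = length(y)),
            class = "smrg_fit")
}

#' @export
print.smrg_fit <- function(x, ...) {
  cat(sprintf("smrg_fit: n=%d iter=%d converged=%s\n",
              x$n_pixels, x$n_iter, x$converged))
  print(x$params)
  invisible(x)
}

#' Serialise a fit report to JSON
#'
#' @param fit an object returned by [fit_em()].
#' @return a JSON string.
#' @export
fit_report_json <- function(fit) {
  stopifnot(inherits(fit, "smrg_fit"))
  jsonlite::toJSON(list(
    params = unclass(fit$params), loglik_trace = fit$loglik_trace,
    n_iter = fit$n_iter, converged = fit$converged,
    n_pixels = fit$n_pixels), auto_unbox = TRUE, digits = NA)
}
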