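test_that("mixture pmf reduces to its components and sums to one", {
  # pure background: symmetric peak at K0, unit total mass
  bg <- mixture_params(K0 = 100, vB = 25, alpha = 1, r = 1, p = 0.5)
  expect_equal(sum(mixture_pdf(0:300, bg)), 1, tolerance = 1e-6)
  pk <- mixture_pdf(95:105, bg)
  expect_equal(which.max(pk), 6L)
  expect_equal(mixture_pdf(95, bg), mixture_pdf(105, bg), tolerance = 1e-12)

  # pure signal: exactly the negative-binomial pmf, mean r(1-p)/p
  sg <- mixture_params(K0 = 0, vB = 1, alpha = 0, r = 10, p = 0.5)
  y <- 0:200
  expect_equal(mixture_pdf(y, sg), dnbinom(y, size = 10, prob = 0.5))
  expect_equal(sum(y * mixture_pdf(y, sg)), 10, tolerance = 1e-8)

  # general mixture against an independently coded pmf
  pars <- mixture_params(K0 = 50, vB = 16, alpha = 0.6, r = 20, p = 1 / 3)
  for (yy in c(50, 60, 110))
    expect_equal(mixture_pdf(yy, pars),
                 oracle_mixture_pmf(yy, 50, 16, 0.6, 20, 1 / 3),
                 tolerance = 1e-12)
  expect_equal(sum(mixture_pdf(0:2000, pars)), 1, tolerance = 1e-6)
  # no signal mass below the offset
  expect_equal(mixture_pdf(49, pars),
               0.6 * oracle_mixture_pmf(49, 50, 16, 1, 20, 1 / 3))
})

test_that("pmf normalisation holds across random valid parameters", {
  set.seed(42)
  for (i in 1:20) {
    pars <- mixture_params(K0 = sample(0:200, 1), vB = runif(1, 0.5, 100),
                           alpha = runif(1), r = runif(1, 0.5, 50),
                           p = runif(1, 0.05, 1))
    lo <- pars$K0 - ceiling(6 * sqrt(pars$vB)) - 2 # support may dip below 0
    hi <- pars$K0 + ceiling(6 * sqrt(pars$vB)) +
      ceiling(nb_moments(pars)$muS + 40 * sqrt(nb_moments(pars)$vS)) + 10
    expect_equal(sum(mixture_pdf(lo:hi, pars)), 1, tolerance = 1e-6)
  }
})

test_that("parameter validation rejects out-of-domain values", {
  expect_error(mixture_params(100.5, 25, 0.5, 10, 0.5), "integer")
  expect_error(mixture_params(100, -1, 0.5, 10, 0.5), "positive")
  expect_error(mixture_params(100, 25, 1.2, 10, 0.5), "alpha")
  expect_error(mixture_params(100, 25, 0.5, -1, 0.5), "r must")
  expect_error(mixture_params(100, 25, 0.5, 10, 1.5), "p must")
})

test_that("method of moments inverts the negative binomial", {
  expect_equal(moments_to_nb(10, 20), list(p = 0.5, r = 10))
  expect_equal(moments_to_nb(40, 120), list(p = 1 / 3, r = 20))
  # roundtrip through the nb mean/variance formulas
  set.seed(3)
  for (i in 1:10) {
    muS <- runif(1, 1, 100)
    vS <- muS * runif(1, 1.01, 5)
    nb <- moments_to_nb(muS, vS)
    expect_equal(nb$r * (1 - nb$p) / nb$p, muS, tolerance = 1e-12)
    expect_equal(nb$r * (1 - nb$p) / nb$p^2, vS, tolerance = 1e-12)
  }
  expect_error(moments_to_nb(10, 10), "underdispersion")
  expect_error(moments_to_nb(10, 5), "underdispersion")
})

test_that("EM recovers generating parameters from simulated crops", {
  # pure background: alpha should be driven to ~1
  set.seed(10)
  bg <- pmax(100 + round(rnorm(3072, 0, 5)), 0)
  fit <- fit_em(bg)
  expect_gte(fit$params$alpha, 0.95)
  expect_lte(abs(fit$params$K0 - 100), 2)

  # full mixture, a handful of replicates (the 50-replicate protocol runs
  # in the acceptance suite)
  ok_alpha <- ok_K0 <- ok_mu <- logical(10)
  for (i in 1:10) {
    set.seed(100 + i)
    n_bg <- rbinom(1, 3072, 0.7)
    y <- c(pmax(100 + round(rnorm(n_bg, 0, 5)), 0),
           100 + rnbinom(3072 - n_bg, size = 20, prob = 1 / 3))
    f <- fit_em(y)
    expect_true(all(diff(f$loglik_trace) >= -1e-8))
    ok_alpha[i] <- abs(f$params$alpha - 0.7) <= 0.05
    ok_K0[i] <- abs(f$params$K0 - 100) <= 2
    ok_mu[i] <- abs(nb_moments(f$params)$muS - 40) <= 4
  }
  expect_gte(mean(ok_alpha), 0.9)
  expect_gte(mean(ok_K0), 0.9)
  expect_gte(mean(ok_mu), 0.9)
})

test_that("degenerate single-valued crops give a non-converged background fit", {
  fit <- fit_em(rep(7L, 500))
  expect_false(fit$converged)
  expect_equal(fit$params$alpha, 1)
  expect_error(fit_em(1:100), "at least 256")
  expect_error(fit_em(rep(-1L, 300)), "non-negative")
})

test_that("signal posterior behaves like a classifier boundary", {
  pars <- mixture_params(K0 = 100, vB = 25, alpha = 0.95, r = 20, p = 1 / 3)
  # background peak -> posterior near 0; far tail -> posterior -> 1
  expect_lt(signal_posterior(100, pars), 0.05)
  expect_gt(signal_posterior(250, pars), 0.999)
  y <- 0:400
  post <- signal_posterior(y, pars)
  expect_true(all(post >= 0 & post <= 1))
  # complementarity with the background responsibility is exact
  expect_equal(post + smrg:::.bg_responsibility(y, pars), rep(1, length(y)))
  # monotone in intensity once the signal tail dominates (y >= K0 here)
  up <- post[y >= 100]
  expect_true(all(diff(up) >= -1e-12))
})

test_that("fit reports serialise to JSON", {
  set.seed(5)
  y <- c(100 + round(rnorm(2000, 0, 5)), 100 + rnbinom(1000, 20, prob = 1 / 3))
  fit <- fit_em(y)
  js <- jsonlite::fromJSON(fit_report_json(fit))
  expect_equal(js$params$K0, fit$params$K0)
  expect_equal(js$n_pixels, 3000)
  expect_true(js$converged)
})
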