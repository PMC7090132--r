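rand_nodes <- function(n, spread = 20) {
  cbind(x = runif(n, 0, spread), y = runif(n, 0, spread),
        z = runif(n, 0, spread))
}

test_that("nearest distances match simple geometry and the brute force", {
  A <- matrix(c(0, 0, 0), 1)
  B <- matrix(c(3, 4, 0), 1)
  expect_equal(nearest_distances(A, B), 5)
  expect_equal(nearest_distances(B, B), 0)

  set.seed(12)
  for (i in 1:5) {
    A <- rand_nodes(50); B <- rand_nodes(40)
    expect_equal(nearest_distances(A, B), oracle_nearest(A, B),
                 tolerance = 1e-12)
  }
  expect_error(nearest_distances(A, matrix(numeric(0), 0, 3)), "empty")
})

test_that("spatial distance averages both directions and is symmetric", {
  A <- rand_nodes(30); B <- rand_nodes(25)
  expect_equal(spatial_distance(A, A), 0)
  # one node each at distance d -> SD = d
  expect_equal(spatial_distance(matrix(c(0, 0, 0), 1),
                                matrix(c(0, 0, 7), 1)), 7)
  expect_equal(spatial_distance(A, B), oracle_sd(A, B), tolerance = 1e-12)
  expect_equal(spatial_distance(A, B), spatial_distance(B, A),
               tolerance = 1e-12)
})

test_that("substantial spatial distance thresholds node pairs", {
  A <- rand_nodes(30)
  same <- substantial_spatial_distance(A, A, S = 1)
  expect_equal(same$ssd, 0)
  expect_equal(same$ssd_pct, 0)

  # one node each at distance 5 with S = 2: both directions exceed S
  r <- substantial_spatial_distance(matrix(c(0, 0, 0), 1),
                                    matrix(c(0, 0, 5), 1), S = 2)
  expect_equal(r$ssd, 5)
  expect_equal(r$ssd_pct, 100)

  set.seed(13)
  for (i in 1:5) {
    A <- rand_nodes(60); B <- rand_nodes(45)
    got <- substantial_spatial_distance(A, B, S = 2)
    want <- oracle_ssd(A, B, S = 2)
    expect_equal(got$ssd, want$ssd, tolerance = 1e-12)
    expect_equal(got$ssd_pct, want$ssd_pct, tolerance = 1e-12)
    # every contributing distance exceeds S
    if (got$ssd_pct > 0) expect_gte(got$ssd, 2)
  }
})

test_that("precision/recall/F behave as a one-to-one matching score", {
  A <- rand_nodes(40)
  perfect <- precision_recall_f(A, A, S = 0.5)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)
  expect_equal(perfect$f_score, 1)

  B <- A + 100 # disjoint by far more than S
  zero <- precision_recall_f(A, B, S = 5)
  expect_equal(zero$f_score, 0)

  set.seed(14)
  for (i in 1:5) {
    A <- rand_nodes(50); B <- rand_nodes(60)
    got <- precision_recall_f(A, B, S = 2)
    want <- oracle_prf(A, B, S = 2)
    expect_equal(got$precision, want$precision, tolerance = 1e-12)
    expect_equal(got$recall, want$recall, tolerance = 1e-12)
    expect_equal(got$f_score, want$f_score, tolerance = 1e-12)
  }

  # monotone non-decreasing in the tolerance S
  A <- rand_nodes(80); B <- rand_nodes(70)
  sweep <- t(vapply(seq(0.5, 5, by = 0.5), function(s) {
    r <- precision_recall_f(A, B, s)
    c(r$precision, r$recall, r$f_score)
  }, numeric(3)))
  expect_true(all(diff(sweep[, 1]) >= 0))
  expect_true(all(diff(sweep[, 2]) >= 0))
  expect_true(all(diff(sweep[, 3]) >= 0))

  # f-score is the harmonic mean whenever P + R > 0
  r <- precision_recall_f(A, B, 3)
  expect_equal(r$f_score,
               2 * r$precision * r$recall / (r$precision + r$recall))
})

test_that("compare_reconstructions accepts SWC objects", {
  rec <- swc(data.frame(id = 1:3, type = c(1L, 3L, 3L), x = c(0, 1, 2),
                        y = 0, z = 0, radius = 1, parent = c(-1L, 1L, 2L)))
  cmp <- compare_reconstructions(rec, rec, S = 2)
  expect_equal(cmp$sd, 0)
  expect_equal(cmp$f_score, 1)
  expect_equal(cmp$n_A, 3)
})
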