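test_that("volume counts voxels and scales with voxel size", {
  cube <- array(FALSE, c(12, 34, 34))
  cube[2:11, 2:11, 2:11] <- TRUE
  expect_equal(mask_volume(cube, c(1, 1, 1)), 1000)
  expect_equal(mask_volume(cube, c(2, 1, 1)), 2000)
  expect_equal(mask_volume(cube, c(1.24, 0.62, 0.62)), 1000 * 1.24 * 0.62^2)

  # rasterized tube volume close to pi r^2 L
  spec <- phantom_spec(
    segments = data.frame(z0 = 12, y0 = 12, x0 = 5, z1 = 12, y1 = 12,
                          x1 = 105, r0 = 5, r1 = 5, parent = 0L),
    stack_shape = c(25, 25, 111))
  truth <- rasterize_phantom(spec)
  analytic <- pi * 25 * 100 + 4 / 3 * pi * 125 # capsule = tube + end caps
  expect_lt(abs(mask_volume(truth$mask, c(1, 1, 1)) - analytic) / analytic,
            0.05)
  expect_error(mask_volume(array(FALSE, c(2, 2, 2))), "empty")
})

test_that("surface area: exposed faces exactly, mesh approximately", {
  cube <- array(FALSE, c(12, 34, 34))
  cube[2:11, 2:11, 2:11] <- TRUE
  expect_equal(surface_area(cube, c(1, 1, 1), "voxel_face"), 600)

  one <- array(FALSE, c(3, 32, 32)); one[2, 16, 16] <- TRUE
  expect_equal(surface_area(one, c(1, 1, 1), "voxel_face"), 6)

  # anisotropic faces: cuboid 1 voxel with dz=2: 2 faces of dy*dx=1,
  # 4 faces of 2*1
  expect_equal(surface_area(one, c(2, 1, 1), "voxel_face"), 2 + 8)

  # sphere r=10: triangulated iso-surface area within 10% of 4 pi r^2
  sp <- array(FALSE, c(25, 25, 25))
  for (z in 1:25) for (y in 1:25)
    sp[z, y, ] <- (z - 13)^2 + (y - 13)^2 + ((1:25) - 13)^2 <= 100
  am <- surface_area(sp, c(1, 1, 1), "mesh")
  expect_lt(abs(am - 4 * pi * 100) / (4 * pi * 100), 0.1)

  expect_error(surface_area(cube, c(1, 1, 1), "nope"))
})

test_that("Sholl profiles count shell crossings", {
  # single radial filament: one crossing per shell over its length
  m <- array(FALSE, c(9, 61, 61))
  m[5, 31, 31:61] <- TRUE # 30 um long in +x (plus centre voxel)
  pr <- sholl(m, c(5, 31, 31), c(1, 1, 1), step = 10)
  expect_s3_class(pr, "sholl_profile")
  expect_equal(pr$count[pr$radius <= 30], rep(1L, 3))
  expect_true(all(pr$count[pr$radius > 31] == 0L))

  # Y-branch: 1 crossing before the bifurcation, 2 after
  ph <- phantom_suite("ybranch", "high")
  ctr <- ph$truth$centerline_vox[1, ]
  pr2 <- sholl(ph$truth$mask, ctr, c(1, 1, 1), step = 10)
  # bifurcation at ~44 um from the trunk start
  expect_true(all(pr2$count[pr2$radius <= 40] == 1))
  expect_true(any(pr2$count[pr2$radius >= 60 & pr2$radius <= 80] == 2))

  expect_error(sholl(m, c(5, 31, 31), c(1, 1, 1), step = 0), "step")
})

test_that("Sholl counts are invariant to 90-degree rotation", {
  ph <- phantom_suite("ybranch", "high")
  m <- ph$truth$mask
  ctr <- ph$truth$centerline_vox[1, ]
  pr <- sholl(m, ctr, c(1, 1, 1), step = 10)
  # rotate 90 degrees in the (y, x) plane: (z, y, x) -> (z, x, Y+1-y)
  dims <- dim(m)
  mr <- aperm(m, c(1, 3, 2))[, , rev(seq_len(dims[2]))]
  ctr_r <- c(ctr[1], ctr[3], dims[2] + 1 - ctr[2])
  pr_r <- sholl(mr, ctr_r, c(1, 1, 1), step = 10)
  expect_equal(pr$count, pr_r$count)
})

test_that("Sholl AUC is the trapezoidal integral", {
  expect_equal(sholl_auc(list(radius = c(1, 3), count = c(2, 4))), 6)
  # constant count over a span integrates to count x span
  expect_equal(sholl_auc(list(radius = seq(5, 45, 10),
                              count = rep(3, 5))), 3 * 40)
  # matches a fine Riemann sum of the linear interpolant
  set.seed(8)
  r <- sort(runif(12, 1, 90))
  cnt <- sample(0:6, 12, replace = TRUE)
  fine <- seq(min(r), max(r), length.out = 2e5)
  riemann <- sum(approx(r, cnt, xout = fine)$y) * diff(fine)[1]
  expect_equal(sholl_auc(list(radius = r, count = cnt)), riemann,
               tolerance = 1e-4)
  expect_error(sholl_auc(list(radius = 1, count = 2)), "at least 2")
})
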