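test_that("crop windows follow the on-plane fraction with a 32-voxel floor", {
  cfg <- grow_config()
  # 512 x 512 planes -> 512/8 = 64 on-plane crop
  big <- image_stack(array(0L, c(3, 512, 512)))
  cr <- extract_crop(big, c(2, 256, 256), cfg)
  expect_equal(dim(cr$crop), c(3, 64, 64))
  # 128 x 128 planes -> 128/8 = 16 raised to the 32 floor
  small <- image_stack(array(0L, c(3, 128, 128)))
  cr2 <- extract_crop(small, c(2, 64, 64), cfg)
  expect_equal(dim(cr2$crop), c(3, 32, 32))

  # corner seed: clipped crop, offset maps crop into stack coordinates
  vox <- array(sample.int(100, 3 * 128 * 128, replace = TRUE) - 1L,
               c(3, 128, 128))
  st <- image_stack(vox)
  cr3 <- extract_crop(st, c(1, 1, 1), cfg)
  expect_lt(prod(dim(cr3$crop)), 32 * 32 * 3)
  for (idx in list(c(1, 1, 1), dim(cr3$crop))) {
    expect_equal(cr3$crop[idx[1], idx[2], idx[3]],
                 vox[idx[1] + cr3$offset[1], idx[2] + cr3$offset[2],
                     idx[3] + cr3$offset[3]])
  }
  # expand mode keeps the full window by shifting inward
  cr4 <- extract_crop(st, c(1, 1, 1), cfg, expand = TRUE)
  expect_equal(dim(cr4$crop), c(3, 32, 32))
  expect_equal(cr4$offset, c(0L, 0L, 0L))
  expect_error(extract_crop(st, c(5, 1, 1), cfg), "out of bounds")
})

test_that("segment_crop admits signal connected to the seed and rejects noise", {
  # pure background crop: nothing passes the 0.999 posterior rule
  set.seed(21)
  bg <- array(pmax(100L + as.integer(round(rnorm(32 * 32 * 3, 0, 5))), 0L),
              c(3, 32, 32))
  seg <- segment_crop(bg, c(2, 16, 16))
  expect_lte(sum(seg$mask), 1)
  expect_identical(seg$decision$method, "mixture")

  # bright tube through the crop: recovered near-perfectly
  spec <- phantom_spec(
    segments = data.frame(z0 = 1, y0 = 15, x0 = 0, z1 = 1, y1 = 15, x1 = 31,
                          r0 = 3, r1 = 3, parent = 0L),
    stack_shape = c(3, 32, 32), rng_seed = 5)
  truth <- rasterize_phantom(spec)
  crop <- render_phantom(truth)$voxels
  seg2 <- segment_crop(crop, c(2, 16, 16))
  expect_gte(dice(seg2$mask, truth$mask), 0.9)

  # two bright blobs: only the one 26-connected to the seed is kept
  two <- bg
  two[, 5:8, 5:8] <- 220L
  two[, 25:28, 25:28] <- 220L
  seg3 <- segment_crop(two, c(2, 6, 6))
  expect_true(seg3$mask[2, 6, 6])
  expect_true(all(!seg3$mask[, 25:28, 25:28]))
})

test_that("next seeds are distance-transform maxima of each plane", {
  # a filled disk yields a single seed at its centre
  m <- array(FALSE, c(1, 33, 33))
  for (y in 1:33) m[1, y, ] <- (y - 17)^2 + ((1:33) - 17)^2 <= 100
  s <- next_seeds(m)
  expect_equal(nrow(s), 1L)
  expect_equal(unname(s[1, ]), c(1, 17, 17))

  # offsets map back to stack coordinates
  s_off <- next_seeds(m, offset = c(4L, 10L, 20L))
  expect_equal(unname(s_off[1, ]), c(5, 27, 37))

  # two disjoint disks -> one maximum each
  m2 <- array(FALSE, c(1, 21, 45))
  for (y in 1:21) {
    m2[1, y, ] <- (y - 11)^2 + ((1:45) - 11)^2 <= 49
    m2[1, y, ] <- m2[1, y, ] | (y - 11)^2 + ((1:45) - 34)^2 <= 49
  }
  s2 <- next_seeds(m2)
  expect_gte(nrow(s2), 2L)

  # seeds of a straight rasterized tube lie within one voxel of its axis
  cyl <- make_cylinder(r = 3, len = 40)
  s3 <- next_seeds(cyl$mask)
  expect_true(all(abs(s3[, 2] - cyl$center[1]) <= 1 |
                    abs(s3[, 1] - cyl$center[2]) <= 1))
  axis_dev <- sqrt((s3[, 1] - cyl$center[1])^2 + (s3[, 2] - cyl$center[2])^2)
  # per-plane maxima on the central planes sit on the axis
  expect_true(any(axis_dev <= 1))

  expect_equal(nrow(next_seeds(array(FALSE, c(1, 5, 5)))), 0L)
})

test_that("grow terminates on background and is deterministic on phantoms", {
  set.seed(31)
  bg <- image_stack(array(pmax(100L + as.integer(round(rnorm(3 * 48 * 48, 0, 5))),
                               0L), c(3, 48, 48)))
  expect_warning(res <- grow(bg, c(2, 24, 24)), "empty")
  expect_lte(sum(res$mask), 1)
  expect_lte(res$n_crops, 3)

  ph <- phantom_suite("tube", "high")
  seed <- ph$truth$centerline_vox[10, ]
  r1 <- grow(ph$stack, seed)
  r2 <- grow(ph$stack, seed)
  expect_identical(r1$mask, r2$mask)
  expect_gte(dice(r1$mask, ph$truth$mask), 0.9)

  # duplicate seeds are processed once (idempotent skip rule)
  r3 <- grow(ph$stack, rbind(seed, seed))
  expect_identical(r3$mask, r1$mask)

  # every admitted voxel is 26-connected to the initial seed
  dims <- dim(r1$mask)
  conn <- array(smrg:::flood_cpp(as.vector(r1$mask), dims, seed - 1L, 26L),
                dims)
  expect_identical(conn, r1$mask)
})

test_that("growing spans crop boundaries through reseeding", {
  ph <- phantom_suite("ybranch", "high")
  seed <- ph$truth$centerline_vox[3, ]
  res <- grow(ph$stack, seed)
  expect_gte(dice(res$mask, ph$truth$mask), 0.9)
  # both branch tips reached (far from the first crop)
  tips <- ph$truth$centerline_vox[c(which.max(ph$truth$centerline_vox[, 3]),
                                    which.min(ph$truth$centerline_vox[, 3])), ]
  for (i in 1:2)
    expect_true(any(res$mask[tips[i, 1] + (-2:2), tips[i, 2] + (-2:2),
                             tips[i, 3] + (-2:2)]))
})

test_that("spherical Hough transform finds somata", {
  ph <- phantom_suite("purkinje", "high")
  s <- detect_somata(ph$stack, c(5, 12))
  expect_gte(nrow(s), 1L)
  truth_center <- round(ph$truth$spec$soma$center / ph$truth$spec$voxel_size) + 1
  expect_lte(sqrt(sum((s[1, ] - truth_center)^2)), 2)

  # two well-separated spheres -> two detections
  ph2 <- phantom_suite("twosomata", "high")
  s2 <- detect_somata(ph2$stack, c(5, 12))
  expect_equal(nrow(s2), 2L)

  # featureless stack -> nothing
  empty <- image_stack(array(10L, c(5, 40, 40)))
  expect_equal(nrow(detect_somata(empty, c(3, 6))), 0L)
})
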