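test_that("thinning reduces tubes to their medial axis", {
  # single voxel is already thin
  one <- array(FALSE, c(5, 33, 33)); one[3, 16, 16] <- TRUE
  expect_identical(skeletonize(one), one)

  # straight cylinder r=3, length 60: skeleton within Hausdorff distance 1
  # of the true axis
  cyl <- make_cylinder(r = 3, len = 60)
  sk <- skeletonize(cyl$mask)
  v <- which(sk, arr.ind = TRUE)
  expect_gt(nrow(v), 40)
  # every skeleton voxel within one lattice step (chessboard distance 1)
  # of the axis line
  expect_lte(max(pmax(abs(v[, 1] - cyl$center[1]),
                      abs(v[, 2] - cyl$center[2]))), 1)
  # every axis voxel (away from the eroded tips) within one step of skeleton
  ax <- cbind(cyl$center[1], cyl$center[2],
              (cyl$x_range[1] + 3):(cyl$x_range[2] - 3))
  d_ax <- vapply(seq_len(nrow(ax)), function(i)
    min(apply(abs(t(v) - ax[i, ]), 2, max)), numeric(1))
  expect_lte(max(d_ax), 1)

  # one-voxel-wide 3D line is returned unchanged
  line <- array(FALSE, c(20, 20, 20))
  for (i in 1:15) line[i + 2, i + 2, i + 2] <- TRUE
  expect_identical(skeletonize(line), line)

  # skeleton is a subset of the mask, preserves component count, is thin
  two <- array(FALSE, c(9, 40, 40))
  two[3:7, 4:10, 4:30] <- TRUE
  two[3:7, 25:31, 4:30] <- TRUE
  sk2 <- skeletonize(two)
  expect_true(all(two[sk2]))
  lab_m <- attr(smrg:::label_cc_cpp(as.vector(two), dim(two), 26L),
                "n_components")
  lab_s <- attr(smrg:::label_cc_cpp(as.vector(sk2), dim(sk2), 26L),
                "n_components")
  expect_equal(lab_s, lab_m)
  # no fully occupied 2x2x2 block
  blocks <- sk2[-1, -1, -1] & sk2[-1, -1, -40] & sk2[-1, -40, -1] &
    sk2[-1, -40, -40] & sk2[-9, -1, -1] & sk2[-9, -1, -40] &
    sk2[-9, -40, -1] & sk2[-9, -40, -40]
  expect_false(any(blocks))

  # empty mask -> empty skeleton
  expect_false(any(skeletonize(array(FALSE, c(3, 32, 32)))))
})

test_that("skeletons convert to rooted SWC trees", {
  # 5-voxel straight line -> a 5-node chain rooted at the seed end
  line <- array(FALSE, c(3, 34, 34))
  line[2, 17, 10:14] <- TRUE
  rec <- skeleton_to_swc(line, line, c(1, 1, 1), root = c(2, 17, 10))
  expect_equal(nrow(rec), 5L)
  expect_equal(rec$parent, c(-1L, 1:4))
  expect_equal(rec$type, c(1L, rep(3L, 4)))
  expect_equal(sort(rec$x), as.numeric(9:13))
  expect_equal(unique(rec$y), 16)

  # Y-shaped skeleton: one branch node with two children, two leaves
  yy <- array(FALSE, c(3, 40, 40))
  yy[2, 10:20, 20] <- TRUE
  yy[2, 21, 19] <- TRUE; yy[2, 21, 21] <- TRUE
  yy[2, 22:28, 18] <- TRUE; yy[2, 22:28, 22] <- TRUE
  # make the arms diagonal-connected properly
  rec2 <- skeleton_to_swc(yy, yy, c(1, 1, 1), root = c(2, 10, 20))
  kids <- table(rec2$parent[rec2$parent > 0])
  expect_equal(sum(kids == 2), 1L) # exactly one branch point
  leaves <- setdiff(rec2$id, rec2$parent)
  expect_equal(length(leaves), 2L)

  # cylinder radius estimate: within one voxel of the true radius
  cyl <- make_cylinder(r = 3, len = 40)
  sk <- skeletonize(cyl$mask)
  rec3 <- skeleton_to_swc(sk, cyl$mask, c(1, 1, 1),
                          root = c(cyl$center[1], cyl$center[2],
                                   cyl$x_range[1]))
  expect_lte(abs(median(rec3$radius) - 3), 1)

  # root must be close to the skeleton
  expect_error(skeleton_to_swc(line, line, c(1, 1, 1), root = c(2, 2, 30)),
               "10 voxels")
})

test_that("SWC files roundtrip and malformed files are rejected", {
  rec <- swc(data.frame(id = 1:4, type = c(1L, 3L, 3L, 3L),
                        x = c(0, 1.25, 2.5, 3.125),
                        y = c(0, 0.1, 0.2, 0.3), z = c(5, 5, 5, 5),
                        radius = c(2, 1, 1, 0.5), parent = c(-1L, 1L, 2L, 3L)))
  f <- tempfile(fileext = ".swc")
  write_swc(rec, f)
  back <- read_swc(f)
  expect_equal(as.data.frame(back), as.data.frame(rec))
  # byte-stable after the first normalization
  f2 <- tempfile(fileext = ".swc")
  write_swc(back, f2)
  expect_identical(readLines(f), readLines(f2))

  # parent referencing a later id
  bad <- tempfile(fileext = ".swc")
  writeLines(c("1 1 0 0 0 1 2", "2 3 1 0 0 1 1"), bad)
  expect_error(read_swc(bad), "parent")
  # comment-only file
  writeLines(c("# header only"), bad)
  expect_error(read_swc(bad), "no SWC records")
  # malformed line (6 columns) is reported with its number
  writeLines(c("1 1 0 0 0 1 -1", "2 3 1 0 0 1"), bad)
  expect_error(read_swc(bad), "line 2")
  # duplicate ids
  writeLines(c("1 1 0 0 0 1 -1", "1 3 1 0 0 1 1"), bad)
  expect_error(read_swc(bad), "contiguous|duplicate")
})
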