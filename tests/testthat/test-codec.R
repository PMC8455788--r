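# Edge-core encoding: per-instance opening, the dilation (initial) codec and
# the erosion (final) codec, checked against brute-force morphology oracles.

test_that("opening matches the brute-force oracle and is anti-extensive and idempotent", {
  arr <- make_sphere(c(11, 11, 11), c(5.5, 5.5, 5.5), 3.2)
  lab <- instance_map3d(arr * 1L)
  op <- open_instances(lab)
  expect_identical(op$data == 1L, bf_open6(arr))
  # a well-resolved sphere survives as one slightly smoothed object
  expect_true(all(arr[op$data == 1L]))            # opening(A) subset of A
  expect_gt(sum(op$data == 1L), 0.8 * sum(arr))   # staircase extremes only
  expect_identical(max(bf_components6(op$data == 1L)), 1L)
  expect_identical(open_instances(op)$data, op$data)
})

test_that("opening removes instances whose erosion is empty", {
  arr <- array(0L, c(9, 9, 9))
  arr[2, 2, 2] <- 1L                      # isolated voxel
  arr[5:7, 5:7, 5:7] <- 2L                # 3-cube survives
  op <- open_instances(instance_map3d(arr))
  expect_identical(sort(unique(as.vector(op$data))), c(0L, 2L))
  expect_identical(op$data == 2L, bf_open6(arr == 2L))
})

test_that("dilation codec geometry matches hand enumeration", {
  sem <- encode_dilation(instance_map3d(array(0L, c(4, 4, 4))))
  expect_true(all(sem$data == 0L))

  m <- array(0L, c(5, 5, 5))
  m[3, 3, 3] <- 1L
  sem <- encode_dilation(instance_map3d(m))
  expect_identical(sum(sem$data == 2L), 1L)
  expect_identical(sum(sem$data == 1L), 6L)
})

test_that("dilation codec overlap semantics: sequential loses cores, core-precedence keeps them", {
  m <- array(0L, c(7, 7, 7))
  m[3, 4, 4] <- 1L
  m[4, 4, 4] <- 2L
  core_wins <- encode_dilation(instance_map3d(m), overlap = "core")
  # both instance voxels stay core; shells overlap the cores and lose there
  expect_identical(sum(core_wins$data == 2L), 2L)
  expect_identical(sum(core_wins$data == 1L), 10L)
  seq_ <- encode_dilation(instance_map3d(m), overlap = "sequential")
  # instance 2's shell overwrites instance 1's core
  expect_identical(sum(seq_$data == 2L), 1L)
  expect_identical(sum(seq_$data == 1L), 11L)
  expect_identical(seq_$data[4, 4, 4], 2L)
})

test_that("sequential dilation round trip loses volume on touching cysts only", {
  d <- c(24L, 24L, 12L)
  touching <- array(0L, d)
  touching[make_sphere(d, c(8, 12, 6), 3.4)] <- 1L
  touching[make_sphere(d, c(14, 12, 6), 3.4) & touching == 0L] <- 2L
  expect_true(labels_touch6(touching))
  dec <- decode_initial(encode_dilation(instance_map3d(touching)))
  expect_lt(sum(dec$data > 0L), sum(touching > 0L))

  apart <- array(0L, d)
  apart[make_sphere(d, c(6, 6, 6), 2.4)] <- 1L
  apart[make_sphere(d, c(17, 17, 6), 2.4)] <- 2L
  dec2 <- decode_initial(encode_dilation(instance_map3d(apart)))
  expect_identical(sum(dec2$data > 0L), sum(apart > 0L))
  expect_identical(length(instance_labels(dec2)), 2L)
})

test_that("erosion codec of a 3-cube matches exhaustive enumeration", {
  mc <- array(0L, c(9, 9, 9))
  mc[4:6, 4:6, 4:6] <- 1L
  sem <- encode_erosion(instance_map3d(mc))
  cube <- mc == 1L
  core_oracle <- bf_erode(cube)
  inner_oracle <- cube & !core_oracle
  outer_oracle <- bf_dilate(cube, offsets4_list) & !cube
  expect_identical(sem$data == 2L, core_oracle)
  expect_identical(sem$data == 1L, inner_oracle | outer_oracle)
  expect_identical(sum(sem$data == 2L), 1L)      # cube center
  expect_identical(sum(inner_oracle), 26L)
  expect_identical(sum(outer_oracle), 36L)       # 12-voxel 4-ring per plane
})

test_that("erosion codec refuses un-opened inputs and empty maps pass through", {
  expect_true(all(encode_erosion(instance_map3d(array(0L, c(4, 4, 4))))$data == 0L))
  one <- array(0L, c(5, 5, 5))
  one[3, 3, 3] <- 1L
  expect_error(encode_erosion(instance_map3d(one)), "open_instances")
})

test_that("cores of distinct instances are never 6-adjacent after erosion encoding", {
  ph <- small_phantom(seed = 9, cluster_fraction = 1)
  up <- upsample_exam(ph$volume, ph$truth, inplane_target = dim(ph$truth$data)[1],
                      z_factor = 3L)
  op <- open_instances(up$labels)
  sem <- encode_erosion(op)
  # label the cores by their instance and scan all face-neighbor pairs
  core_lab <- op$data
  core_lab[sem$data != 2L] <- 0L
  expect_false(labels_touch6(core_lab))
  # classes partition the grid and each instance sits inside core + inner edge
  expect_true(all(sem$data %in% 0:2))
  expect_true(all(sem$data[op$data > 0L] %in% 1:2))
  expect_true(all(op$data[sem$data == 2L] > 0L))
})
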