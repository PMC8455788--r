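test_that("up-sampling reaches the working grid and preserves physical extent", {
  set.seed(2)
  ph <- small_phantom(seed = 2, shape = c(32L, 32L, 10L))
  up <- upsample_exam(ph$volume, ph$truth, inplane_target = 64L, z_factor = 3L)
  expect_identical(dim(up$volume$data), c(64L, 64L, 30L))
  expect_equal(up$volume$spacing, ph$volume$spacing / c(2, 2, 3))
  expect_equal(dim(up$volume$data) * up$volume$spacing,
               dim(ph$volume$data) * ph$volume$spacing)

  # in-plane already at target: unchanged in plane, slices tripled
  same <- upsample_exam(ph$volume, ph$truth, inplane_target = 32L, z_factor = 3L)
  expect_identical(dim(same$labels$data), c(32L, 32L, 30L))
  expect_equal(same$labels$spacing[1:2], ph$truth$spacing[1:2])
})

test_that("up-sampled label sets never gain labels and masks stay binary", {
  ph <- small_phantom(seed = 5, shape = c(32L, 32L, 10L))
  up <- upsample_exam(ph$volume, ph$truth, inplane_target = 64L, z_factor = 3L)
  expect_true(all(instance_labels(up$labels) %in% instance_labels(ph$truth)))
  upm <- upsample_exam(ph$volume, ph$kidney, inplane_target = 64L, z_factor = 3L)
  expect_s3_class(upm$labels, "binary_mask3d")
  expect_error(upsample_exam(
    volume3d(array(0, c(8, 10, 4))),
    instance_map3d(array(0L, c(8, 10, 4)))), "square")
})

test_that("a single-slice cyst spans at least three planes after up-sampling", {
  d <- c(24L, 24L, 8L)
  arr <- array(0L, d)
  arr[10:14, 10:14, 4] <- 1L  # present on exactly one slice
  mri <- volume3d(array(0.5, d), spacing = c(1.5, 1.5, 4.5))
  up <- upsample_exam(mri, instance_map3d(arr, spacing = c(1.5, 1.5, 4.5)),
                      inplane_target = 48L, z_factor = 3L)
  planes <- which(apply(up$labels$data == 1L, 3, any))
  expect_gte(length(planes), 3L)
})

test_that("block-aligned label maps down-sample to exactly the original voxels", {
  orig <- array(0L, c(8L, 8L, 4L))
  orig[3:5, 2:4, 2:3] <- 7L
  fine <- orig[rep(1:8, each = 3), rep(1:8, each = 3), rep(1:4, each = 3)]
  down <- downsample_labels(instance_map3d(fine, spacing = c(0.5, 0.5, 1.5)),
                            c(8L, 8L, 4L))
  expect_identical(down$data, orig)
  expect_equal(down$spacing, c(1.5, 1.5, 4.5))

  empty <- downsample_labels(instance_map3d(array(0L, c(6, 6, 6))), c(3L, 3L, 3L))
  expect_identical(max(empty$data), 0L)
  expect_error(downsample_labels(instance_map3d(array(0L, c(7, 7, 7))),
                                 c(3L, 3L, 3L)), "integer multiple")
})

test_that("up-then-down round trip preserves per-label voxel counts within 5%", {
  ph <- small_phantom(seed = 19)
  shape <- dim(ph$truth$data)
  up <- upsample_exam(ph$volume, ph$truth, inplane_target = shape[1] * 2L,
                      z_factor = 3L)
  down <- downsample_labels(up$labels, shape)
  before <- phantom_cyst_table(ph$truth)
  after <- phantom_cyst_table(down)
  # all phantom cysts have radius >= 2 in-plane voxels by construction
  expect_identical(after$label, before$label)
  expect_true(all(abs(after$voxels - before$voxels) / before$voxels <= 0.05))
})
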