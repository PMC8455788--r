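# Decoding: connected components (initial), EDT watershed with seed
# recovery, instance dilation, the minimum-size filter, and the composed
# final decoder.

test_that("initial decoding labels 6-connected core components only", {
  empty <- semantic_map3d(array(0L, c(6, 6, 6)))
  expect_identical(max(decode_initial(empty)$data), 0L)

  sem <- array(0L, c(9, 5, 5))
  sem[2:3, 3, 3] <- 2L
  sem[4, 3, 3] <- 1L       # single edge voxel between two cores
  sem[5:6, 3, 3] <- 2L
  dec <- decode_initial(semantic_map3d(sem))
  expect_identical(length(instance_labels(dec)), 2L)
  expect_identical(dec$data, bf_components6(sem == 2L))

  diag_ <- array(0L, c(6, 6, 6))
  diag_[2, 2, 2] <- 2L
  diag_[3, 3, 2] <- 2L     # 18-adjacent, not 6-adjacent
  dec2 <- decode_initial(semantic_map3d(diag_))
  expect_identical(length(instance_labels(dec2)), 2L)
})

test_that("watershed splits a dumbbell at the neck and nowhere else", {
  dims <- c(26L, 26L, 20L)
  s1 <- make_sphere(dims, c(9.5, 9.5, 9.5), 4)
  s2 <- make_sphere(dims, c(15.5, 9.5, 9.5), 4)
  dumbbell <- binary_mask3d((s1 | s2) * 1L)
  ws <- split_cores(dumbbell)
  labs <- instance_labels(ws)
  expect_identical(length(labs), 2L)
  # per-voxel nearest-center assignment oracle away from the midline
  ctr1 <- ws$data[10, 10, 10]
  ctr2 <- ws$data[16, 10, 10]
  expect_true(ctr1 > 0L && ctr2 > 0L && ctr1 != ctr2)
  for (v in which(ws$data > 0L)) {
    ai <- arrayInd(v, dims)
    d1 <- sum((ai - c(10, 10, 10))^2)
    d2 <- sum((ai - c(16, 10, 10))^2)
    if (d1 < d2) expect_identical(ws$data[v], ctr1)
    if (d2 < d1) expect_identical(ws$data[v], ctr2)
  }

  one <- split_cores(binary_mask3d(make_sphere(dims, c(13, 13, 10), 4) * 1L))
  expect_identical(length(instance_labels(one)), 1L)
  expect_identical(sum(one$data > 0L), sum(make_sphere(dims, c(13, 13, 10), 4)))

  none <- split_cores(binary_mask3d(array(0L, c(8, 8, 8))))
  expect_identical(max(none$data), 0L)
})

test_that("recovery labels every unclaimed core voxel starting after the last label", {
  dims <- c(26L, 26L, 20L)
  s1 <- make_sphere(dims, c(9.5, 9.5, 9.5), 4)
  s2 <- make_sphere(dims, c(15.5, 9.5, 9.5), 4)
  core <- binary_mask3d((s1 | s2) * 1L)
  ws <- split_cores(core)
  expect_gt(sum(core$data == 1L & ws$data == 0L), 0L)  # ridge voxels exist
  full <- recover_lost_cores(core, ws)
  expect_identical(sum(full$data > 0L), sum(core$data == 1L))  # conservation
  expect_true(all(full$data[core$data == 0L] == 0L))

  # an isolated fragment missed by the watershed becomes max(ws) + 1
  frag_core <- core
  frag_core$data[2, 2, 2] <- 1L
  frag_core$data[3, 2, 2] <- 1L
  ws2 <- ws  # watershed output that never saw the fragment
  rec <- recover_lost_cores(frag_core, ws2)
  expect_identical(rec$data[2, 2, 2], max(ws$data) + 1L)
  expect_identical(rec$data[3, 2, 2], rec$data[2, 2, 2])

  # already complete labelings pass through unchanged
  done <- instance_map3d((core$data == 1L) * 1L, core$spacing)
  expect_identical(recover_lost_cores(core, done)$data, done$data)

  bad <- instance_map3d(array(1L, dim(core$data)), core$spacing)
  expect_error(recover_lost_cores(core, bad), "contained")
})

test_that("instance dilation is one 6-connected round and label-permutation equivariant", {
  one <- array(0L, c(5, 5, 5))
  one[3, 3, 3] <- 1L
  dil <- dilate_instances(instance_map3d(one))
  expect_identical(sum(dil$data > 0L), 7L)
  expect_identical(dil$data == 1L, bf_dilate(one == 1L))

  ph <- small_phantom(seed = 13)
  labs <- instance_labels(ph$truth)
  perm <- rev(labs)  # relabel k -> K+1-k
  permuted <- ph$truth
  permuted$data <- array(c(0L, perm)[ph$truth$data + 1L], dim(ph$truth$data))
  a <- dilate_instances(ph$truth)
  b <- dilate_instances(permuted)
  expect_identical(array(c(0L, perm)[a$data + 1L], dim(a$data)), b$data)
})

test_that("dilating the eroded core of an opened sphere restores it exactly", {
  arr <- make_sphere(c(13, 13, 13), c(6.5, 6.5, 6.5), 4.2)
  opened <- open_instances(instance_map3d(arr * 1L))
  sem <- encode_erosion(opened)
  core <- instance_map3d((sem$data == 2L) * 1L)
  expect_identical(dilate_instances(core)$data > 0L, opened$data > 0L)
})

test_that("the minimum-size filter drops small instances and relabels in order", {
  arr <- array(0L, c(12, 6, 4))
  arr[1:3, 1, 1] <- 2L    # 3 voxels -> removed
  arr[5:9, 2, 2] <- 5L    # 10 voxels across two runs
  arr[5:9, 3, 2] <- 5L
  arr[11:12, 5, 3] <- 9L  # 4 voxels
  arr[11:12, 6, 3] <- 9L
  filt <- filter_small(instance_map3d(arr), 4L)
  tab <- phantom_cyst_table(filt)
  expect_identical(tab$label, c(1L, 2L))
  expect_identical(tab$voxels, c(10L, 4L))
  expect_error(filter_small(instance_map3d(arr), 0L), "at least 1")
})

test_that("final decoding reproduces opened non-touching instances voxel for voxel", {
  ph <- small_phantom(seed = 17, cluster_fraction = 0, n_cysts = 6L)
  shape <- dim(ph$truth$data)
  up <- upsample_exam(ph$volume, ph$truth, inplane_target = shape[1],
                      z_factor = 3L)
  op <- open_instances(up$labels)
  sem <- encode_erosion(op)
  core <- binary_mask3d((sem$data == 2L) * 1L, sem$spacing)
  ws <- split_cores(core)
  full <- recover_lost_cores(core, ws)
  dil <- dilate_instances(full, edt = attr(full, "edt"))
  # identical instance partition up to label ids
  expect_identical(dil$data > 0L, op$data > 0L)
  for (lab in instance_labels(dil)) {
    covered <- unique(op$data[dil$data == lab])
    expect_identical(length(covered), 1L)
  }
  # every decoded final label is 6-connected and at least 4 voxels
  dec <- decode_final(sem, shape)
  for (lab in instance_labels(dec)) {
    m <- dec$data == lab
    expect_gte(sum(m), 4L)
    expect_identical(max(bf_components6(m)), 1L)
  }
  expect_identical(max(decode_final(semantic_map3d(array(0L, c(12, 12, 12))),
                                    c(4L, 4L, 4L))$data), 0L)
})
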