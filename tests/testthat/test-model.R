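# The slice predictor contract: stacking, the Jaccard objective, the
# from-scratch inception U-Net (including an analytic-vs-numeric gradient
# check), reduced-scale training, voting and exam-level prediction.

test_that("slice stacks order channels and zero-pad at the volume ends", {
  d <- c(12L, 12L, 5L)
  set.seed(3)
  mri <- volume3d(array(runif(prod(d)), d))
  kid <- binary_mask3d(array(1L, d))
  s1 <- stack_slices(mri, kid, 1, normalize = FALSE)
  expect_true(all(s1[, , 1] == 0))
  expect_equal(s1[, , 2], mri$data[, , 1])
  expect_equal(s1[, , 3], mri$data[, , 2])
  expect_equal(s1[, , 4], matrix(1, 12, 12))
  sz <- stack_slices(mri, kid, 5, normalize = FALSE)
  expect_true(all(sz[, , 3] == 0))
  expect_error(stack_slices(mri, kid, 0), "range")
  expect_error(stack_slices(mri, kid, 6), "range")

  flat <- volume3d(array(0.7, d))
  sf <- stack_slices(flat, kid, 3)
  expect_equal(sf[, , 1], sf[, , 2])
  expect_equal(sf[, , 2], sf[, , 3])
})

test_that("the Jaccard index evaluates the overlap formula", {
  d <- c(6L, 6L, 2L)
  r <- array(0, d); r[1:4, 1:2, 1] <- 1
  p <- array(0, d); p[1:4, 1, 1] <- 1  # |p| = 4 inside |r| = 8
  expect_equal(jaccard_index(p, r), 0.5)
  expect_equal(jaccard_index(r, r), 1)
  q <- array(0, d); q[1:2, 5, 2] <- 1
  expect_equal(jaccard_index(q, r), 0)
  expect_equal(jaccard_index(array(0, d), array(0, d)), 1)  # empty-empty
  expect_equal(jaccard_index(p, r), jaccard_index(r, p))
  expect_error(jaccard_index(array(2, d), r), "\\[0, 1\\]")
  expect_error(jaccard_index(array(0, c(2, 2, 2)), r), "shape")
})

test_that("dice and jaccard obey D = 2J / (1 + J) on random pairs", {
  set.seed(42)
  for (i in 1:5) {
    a <- instance_map3d(array(rbinom(648, 1, 0.4), c(9, 9, 8)))
    b <- instance_map3d(array(rbinom(648, 1, 0.4), c(9, 9, 8)))
    s <- similarity(a, b)
    expect_equal(s$dice, 2 * s$jaccard / (1 + s$jaccard))
  }
})

test_that("untrained nets are valid deterministic probability predictors", {
  net <- build_inception_unet(seed = 5)
  x <- array(runif(16 * 16 * 4), c(16, 16, 4))
  p <- predict_slice(net, x)
  expect_identical(dim(p), c(16L, 16L, 3L))
  expect_true(all(p >= 0))
  expect_lt(max(abs(apply(p, c(1, 2), sum) - 1)), 1e-8)
  expect_identical(predict_slice(build_inception_unet(seed = 5), x), p)
  expect_false(identical(predict_slice(build_inception_unet(seed = 6), x), p))
  expect_error(build_inception_unet(depth = 1), "depth")
})

test_that("backpropagated gradients match central finite differences", {
  net <- build_inception_unet(seed = 3)
  set.seed(9)
  xs <- array(runif(8 * 8 * 4), c(8, 8, 4))
  tg <- array(0, c(8, 8, 3))
  cls <- sample(0:2, 64, TRUE)
  for (i in 1:64) tg[((i - 1) %% 8) + 1, ((i - 1) %/% 8) + 1, cls[i] + 1] <- 1
  fw <- edgecore:::unet_forward(net, xs, train = FALSE)
  bw <- edgecore:::unet_backward(net, fw$cache, tg)
  lossfn <- function(n) {
    f <- edgecore:::unet_forward(n, xs, train = FALSE)
    edgecore:::jaccard_loss_grad(f$probs, tg)$loss
  }
  fl <- unlist(net$params)
  gfl <- unlist(bw$grads)
  errs <- vapply(sample(which(abs(gfl) > 1e-8), 12), function(j) {
    eps <- 1e-5
    f1 <- fl; f1[j] <- f1[j] + eps
    f2 <- fl; f2[j] <- f2[j] - eps
    n1 <- net; n1$params <- relist_params(f1, net$params)
    n2 <- net; n2$params <- relist_params(f2, net$params)
    num <- (lossfn(n1) - lossfn(n2)) / (2 * eps)
    abs(num - gfl[j]) / max(abs(num), abs(gfl[j]), 1e-8)
  }, numeric(1))
  # a stray ReLU kink can spoil an individual finite difference; the bulk
  # must agree to numerical precision
  expect_lt(median(errs), 1e-6)
  expect_gte(sum(errs < 1e-4), 10L)
})

test_that("reduced-scale training overfits a tiny phantom with a falling loss", {
  ph <- generate_phantom(phantom_spec(shape = c(64L, 64L, 12L), n_cysts = 10L,
                                      seed = 5))
  exams <- list(list(mri = ph$volume, kidney = ph$kidney,
                     sem = encode_dilation(ph$truth)))
  net <- build_inception_unet(seed = 1)
  net <- train_reduced(net, exams, train_config(epochs = 12, batch_size = 6,
                                                seed = 2))
  h <- net$loss_history
  expect_identical(length(h), 12L)
  expect_lt(h[12], h[1])
  expect_lt(mean(h[9:12]), mean(h[1:4]))  # monotone in trend

  cfg <- train_config()
  expect_identical(cfg$epochs, 200L)
  expect_identical(cfg$batch_size, 6L)
  expect_equal(cfg$learning_rate, 1e-3)
  expect_identical(cfg$optimizer, "adam")
  expect_error(train_reduced(net, list()), "at least one")
  expect_error(train_config(epochs = 0), "epochs")
  expect_error(train_config(learning_rate = 0), "learning_rate")
})

test_that("training trajectories are reproducible under a fixed seed", {
  ph <- generate_phantom(phantom_spec(shape = c(32L, 32L, 4L), n_cysts = 4L,
                                      seed = 8))
  exams <- list(list(mri = ph$volume, kidney = ph$kidney,
                     sem = encode_dilation(ph$truth)))
  n1 <- train_reduced(build_inception_unet(seed = 1), exams,
                      train_config(epochs = 3, seed = 4))
  n2 <- train_reduced(build_inception_unet(seed = 1), exams,
                      train_config(epochs = 3, seed = 4))
  expect_identical(n1$loss_history, n2$loss_history)
  expect_identical(n1$params, n2$params)
})

test_that("majority voting follows the majority, then probabilities, then precedence", {
  d <- c(2L, 2L, 1L)
  hard <- function(v) semantic_map3d(array(v, d))
  expect_identical(majority_vote(list(hard(2L), hard(2L), hard(2L)))$data,
                   array(2L, d))
  expect_identical(majority_vote(list(hard(1L), hard(1L), hard(2L)))$data,
                   array(1L, d))
  # full three-way split without probabilities is unresolvable
  expect_error(majority_vote(list(hard(0L), hard(1L), hard(2L))), "probabilities")
  # with probabilities the largest summed probability wins the split
  onehotish <- function(cls, conf) {
    a <- array((1 - conf) / 2, c(2, 2, 1, 3))
    a[, , , cls + 1] <- conf
    a
  }
  out <- majority_vote(list(onehotish(0, 0.5), onehotish(1, 0.6),
                            onehotish(2, 0.9)))
  expect_true(all(out == 2L))
  # exact probability ties resolve core > edge > background
  flat <- array(1 / 3, c(2, 2, 1, 3))
  expect_true(all(majority_vote(list(flat, flat, flat)) == 2L))
})

test_that("exam prediction reproduces an oracle ensemble and respects the mask", {
  ph <- small_phantom(seed = 3, shape = c(32L, 32L, 8L), n_cysts = 5L)
  sem <- encode_dilation(ph$truth)
  ens <- ensemble_predictor(replicate(3, oracle_predictor(sem), simplify = FALSE))
  pred <- predict_exam(ens, ph$volume, ph$kidney)
  inside <- ph$kidney$data == 1L
  expect_identical(pred$data[inside], sem$data[inside])
  expect_true(all(pred$data[!inside] == 0L))

  zero_kid <- binary_mask3d(array(0L, dim(ph$kidney$data)), ph$kidney$spacing)
  expect_true(all(predict_exam(ens, ph$volume, zero_kid)$data == 0L))

  # an ensemble of three copies of one member is that member's argmax
  net <- build_inception_unet(seed = 2)
  tri <- ensemble_predictor(list(net, net, net))
  p3 <- predict_exam(tri, ph$volume, ph$kidney)
  p1 <- predict_exam(net, ph$volume, ph$kidney)
  expect_identical(p3$data, p1$data)
})

test_that("member selection keeps the predictors that score best on validation", {
  ph <- small_phantom(seed = 6, shape = c(32L, 32L, 8L), n_cysts = 5L)
  sem <- encode_dilation(ph$truth)
  val <- list(list(mri = ph$volume, kidney = ph$kidney, sem = sem))
  good <- oracle_predictor(sem)
  noise <- slice_predictor(function(stack, z) {
    a <- array(1 / 3, c(dim(stack)[1:2], 3L))
    a[, , 1] <- 0.5; a[, , 2] <- 0.3; a[, , 3] <- 0.2
    a
  })
  ens <- select_members(list(noise, good, good, good), val, n_keep = 3L)
  scores <- attr(ens, "scores")
  expect_identical(which.min(scores), 1L)
  expect_identical(length(ens$members), 3L)
  expect_false(any(vapply(ens$members, identical, logical(1), noise)))
})
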