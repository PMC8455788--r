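# Slice-wise 3-class inception U-Net, implemented directly on base-R matrix
# algebra: im2col convolutions with hand-written backprop, He init, inverted
# dropout, nearest-neighbor up-convolutions, per-voxel softmax, and a soft
# Jaccard loss (1 - J, eps = 1) optimized with Adam. Small by design — the
# predictor contract (4-channel slice stack in, 3-class probabilities out)
# is what the pipeline depends on, and this net genuinely trains at desk
# scale.

.im2col_cache <- new.env(parent = emptyenv())

# Index map for im2col: rows = output pixels (x fastest), cols = patch
# elements (kx, ky, channel); 0 marks zero padding.
im2col_index <- function(H, W, C, k, stride) {
  key <- paste(H, W, C, k, stride, sep = "_")
  if (!is.null(.im2col_cache[[key]])) return(.im2col_cache[[key]])
  pad <- (k - 1L) %/% 2L
  Ho <- H %/% stride
  Wo <- W %/% stride
  ox <- rep(0:(Ho - 1L), times = Wo)
  oy <- rep(0:(Wo - 1L), each = Ho)
  npix <- Ho * Wo
  idx <- matrix(0L, npix, k * k * C)
  col <- 0L
  for (c0 in 0:(C - 1L)) {
    for (ky in 0:(k - 1L)) {
      for (kx in 0:(k - 1L)) {
        col <- col + 1L
        x <- ox * stride + kx - pad
        y <- oy * stride + ky - pad
        ok <- x >= 0L & x < H & y >= 0L & y < W
        v <- integer(npix)
        v[ok] <- x[ok] + y[ok] * H + c0 * H * W + 1L
        idx[, col] <- v
      }
    }
  }
  out <- list(idx1 = idx + 1L, Ho = Ho, Wo = Wo)
  .im2col_cache[[key]] <- out
  out
}

conv_patches <- function(x, k, stride) {
  d <- dim(x)
  ic <- im2col_index(d[1], d[2], d[3], k, stride)
  P <- matrix(c(0, as.numeric(x))[ic$idx1], nrow = nrow(ic$idx1))
  list(P = P, Ho = ic$Ho, Wo = ic$Wo)
}

conv_fw <- function(x, W, b, stride = 1L) {
  k <- dim(W)[1]
  FF <- dim(W)[4]
  pp <- conv_patches(x, k, stride)
  y <- pp$P %*% matrix(W, ncol = FF)
  y <- sweep(y, 2, b, `+`)
  dim(y) <- c(pp$Ho, pp$Wo, FF)
  list(y = y, cache = list(P = pp$P, W = W, xdim = dim(x), k = k,
                           stride = stride))
}

# dX of a same-padded convolution is itself a convolution of dY (zero-
# upsampled when the forward pass was strided) with the spatially flipped,
# channel-transposed kernel.
conv_bw <- function(dy, cache) {
  FF <- dim(dy)[3]
  dYm <- matrix(dy, ncol = FF)
  dW <- crossprod(cache$P, dYm)
  db <- colSums(dYm)
  k <- cache$k
  Wf <- aperm(cache$W[k:1, k:1, , , drop = FALSE], c(1, 2, 4, 3))
  z <- if (cache$stride == 1L) dy else {
    zz <- array(0, cache$xdim[c(1, 2)] |> c(FF))
    zz[seq(1L, dim(zz)[1], cache$stride), seq(1L, dim(zz)[2], cache$stride), ] <- dy
    zz
  }
  pp <- conv_patches(z, k, 1L)
  dx <- pp$P %*% matrix(Wf, ncol = cache$xdim[3])
  dim(dx) <- cache$xdim
  dim(dW) <- c(k, k, cache$xdim[3], FF)
  list(dx = dx, dW = dW, db = db)
}

relu_fw <- function(x) list(y = pmax(x, 0), cache = x > 0)
relu_bw <- function(dy, cache) dy * cache

dropout_fw <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(y = x, cache = NULL))
  keep <- 1 - rate
  mask <- array((runif(length(x)) < keep) / keep, dim(x))
  list(y = x * mask, cache = mask)
}
dropout_bw <- function(dy, cache) if (is.null(cache)) dy else dy * cache

upsample2_fw <- function(x) {
  d <- dim(x)
  x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , drop = FALSE]
}
upsample2_bw <- function(dy) {
  d <- dim(dy)
  i1 <- seq(1L, d[1], 2L); i2 <- seq(2L, d[1], 2L)
  j1 <- seq(1L, d[2], 2L); j2 <- seq(2L, d[2], 2L)
  dy[i1, j1, , drop = FALSE] + dy[i2, j1, , drop = FALSE] +
    dy[i1, j2, , drop = FALSE] + dy[i2, j2, , drop = FALSE]
}

concat_ch <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1], da[2], da[3] + db[3]))
}

he_init <- function(k, cin, cout) {
  array(rnorm(k * k * cin * cout, 0, sqrt(2 / (k * k * cin))),
        c(k, k, cin, cout))
}

new_conv <- function(k, cin, cout) list(W = he_init(k, cin, cout), b = numeric(cout))

inception_fw <- function(x, blk, train) {
  caches <- list()
  outs <- list()
  for (nm in c("b1", "b3", "b5")) {
    cv <- conv_fw(x, blk[[nm]]$W, blk[[nm]]$b)
    rl <- relu_fw(cv$y)
    outs[[nm]] <- rl$y
    caches[[nm]] <- list(conv = cv$cache, relu = rl$cache)
  }
  y <- concat_ch(concat_ch(outs$b1, outs$b3), outs$b5)
  list(y = y, cache = list(caches = caches, f = dim(outs$b1)[3]))
}

inception_bw <- function(dy, cache) {
  f <- cache$f
  grads <- list()
  dx <- NULL
  for (i in 1:3) {
    nm <- c("b1", "b3", "b5")[i]
    dpart <- dy[, , ((i - 1) * f + 1):(i * f), drop = FALSE]
    dr <- relu_bw(dpart, cache$caches[[nm]]$relu)
    cb <- conv_bw(dr, cache$caches[[nm]]$conv)
    grads[[nm]] <- list(W = cb$dW, b = cb$db)
    dx <- if (is.null(dx)) cb$dx else dx + cb$dx
  }
  list(dx = dx, grads = grads)
}

#' Build a slice-wise inception U-Net predictor
#'
#' Encoder stages are inception blocks (parallel 1x1, 3x3 and 5x5
#' convolution branches, ReLU, channel concatenation) followed by a stride-2
#' 3x3 convolution and dropout; the decoder mirrors them with
#' nearest-neighbor up-convolutions and skip concatenations; a final 1x1
#' convolution and per-voxel softmax emit the three class probabilities.
#' Weights are He-initialized under the given seed, so two instantiations
#' with the same seed are identical; the untrained net is already a valid
#' slice predictor (probabilities sum to 1).
#'
#' @param base_filters filters per inception branch at the first stage
#'   (doubling per stage).
#' @param depth number of encoder stages, at least 2; input slices must have
#'   height and width divisible by `2^depth`.
#' @param dropout encoder dropout rate.
#' @param seed initialization seed.
#' @return an object of class `c("inception_unet", "slice_predictor")`.
#' @export
build_inception_unet <- function(base_filters = 4L, depth = 2L, dropout = 0.1,
                                 seed = 1L) {
  if (depth < 2L) stop("`depth` must be at least 2", call. = FALSE)
  with_seed(seed, {
    params <- list(enc = list(), dec = list())
    cin <- 4L
    widths <- integer(depth)
    for (s in seq_len(depth)) {
      f <- base_filters * 2L^(s - 1L)
      widths[s] <- 3L * f
      params$enc[[s]] <- list(
        b1 = new_conv(1L, cin, f), b3 = new_conv(3L, cin, f),
        b5 = new_conv(5L, cin, f),
        down = new_conv(3L, 3L * f, 3L * f)
      )
      cin <- 3L * f
    }
    fb <- base_filters * 2L^depth
    params$bottleneck <- list(b1 = new_conv(1L, cin, fb),
                              b3 = new_conv(3L, cin, fb),
                              b5 = new_conv(5L, cin, fb))
    cbelow <- 3L * fb
    for (s in rev(seq_len(depth))) {
      params$dec[[s]] <- list(
        up = new_conv(3L, cbelow, widths[s]),
        merge = new_conv(3L, 2L * widths[s], widths[s])
      )
      cbelow <- widths[s]
    }
    params$final <- new_conv(1L, widths[1], 3L)
    structure(
      list(params = params,
           config = list(base_filters = base_filters, depth = depth,
                         dropout = dropout, seed = seed),
           loss_history = numeric()),
      class = c("inception_unet", "slice_predictor")
    )
  })
}

unet_forward <- function(net, x, train = FALSE) {
  p <- net$params
  depth <- net$config$depth
  d <- dim(x)
  if (any(d[1:2] %% 2L^depth != 0L)) {
    stop("slice size must be divisible by 2^depth", call. = FALSE)
  }
  cache <- list(enc = vector("list", depth), dec = vector("list", depth))
  skips <- vector("list", depth)
  h <- x
  for (s in seq_len(depth)) {
    inc <- inception_fw(h, p$enc[[s]], train)
    skips[[s]] <- inc$y
    dn <- conv_fw(inc$y, p$enc[[s]]$down$W, p$enc[[s]]$down$b, stride = 2L)
    rl <- relu_fw(dn$y)
    dr <- dropout_fw(rl$y, net$config$dropout, train)
    cache$enc[[s]] <- list(inc = inc$cache, down = dn$cache, relu = rl$cache,
                           drop = dr$cache)
    h <- dr$y
  }
  bot <- inception_fw(h, p$bottleneck, train)
  cache$bottleneck <- bot$cache
  h <- bot$y
  for (s in rev(seq_len(depth))) {
    hu <- upsample2_fw(h)
    cv1 <- conv_fw(hu, p$dec[[s]]$up$W, p$dec[[s]]$up$b)
    r1 <- relu_fw(cv1$y)
    cat_ <- concat_ch(r1$y, skips[[s]])
    cv2 <- conv_fw(cat_, p$dec[[s]]$merge$W, p$dec[[s]]$merge$b)
    r2 <- relu_fw(cv2$y)
    cache$dec[[s]] <- list(conv1 = cv1$cache, relu1 = r1$cache,
                           conv2 = cv2$cache, relu2 = r2$cache,
                           nskip = dim(skips[[s]])[3])
    h <- r2$y
  }
  fin <- conv_fw(h, p$final$W, p$final$b)
  cache$final <- fin$cache
  logits <- fin$y
  m <- pmax(logits[, , 1], pmax(logits[, , 2], logits[, , 3]))
  e <- exp(logits - as.numeric(m))
  ssum <- e[, , 1] + e[, , 2] + e[, , 3]
  probs <- e / as.numeric(ssum)
  cache$probs <- probs
  list(probs = probs, cache = cache)
}

# Soft Jaccard loss over the edge and core classes: L = 1 - (J_e + J_c)/2.
jaccard_loss_grad <- function(probs, target, eps = 1) {
  dP <- array(0, dim(probs))
  js <- numeric(2)
  for (i in 1:2) {
    cls <- i + 1L  # channels: 1 bg, 2 edge, 3 core
    pc <- probs[, , cls]
    rc <- target[, , cls]
    A <- sum(pc * rc) + eps
    B <- sum(pc) + sum(rc) - sum(pc * rc) + eps
    js[i] <- A / B
    dP[, , cls] <- -0.5 * (rc * B - A * (1 - rc)) / B^2
  }
  list(loss = 1 - mean(js), dP = dP)
}

unet_backward <- function(net, cache, target, eps = 1) {
  p <- net$params
  depth <- net$config$depth
  probs <- cache$probs
  lg <- jaccard_loss_grad(probs, target, eps)
  # softmax jacobian
  inner <- lg$dP[, , 1] * probs[, , 1] + lg$dP[, , 2] * probs[, , 2] +
    lg$dP[, , 3] * probs[, , 3]
  dlogits <- probs * (lg$dP - as.numeric(inner))
  grads <- list(enc = vector("list", depth), dec = vector("list", depth))
  cb <- conv_bw(dlogits, cache$final)
  grads$final <- list(W = cb$dW, b = cb$db)
  dh <- cb$dx
  dskips <- vector("list", depth)
  for (s in seq_len(depth)) {
    cc <- cache$dec[[s]]
    dr2 <- relu_bw(dh, cc$relu2)
    cb2 <- conv_bw(dr2, cc$conv2)
    nch <- dim(cb2$dx)[3]
    dcat <- cb2$dx
    dup_out <- dcat[, , seq_len(nch - cc$nskip), drop = FALSE]
    dskips[[s]] <- dcat[, , (nch - cc$nskip + 1L):nch, drop = FALSE]
    dr1 <- relu_bw(dup_out, cc$relu1)
    cb1 <- conv_bw(dr1, cc$conv1)
    grads$dec[[s]] <- list(up = list(W = cb1$dW, b = cb1$db),
                           merge = list(W = cb2$dW, b = cb2$db))
    dh <- upsample2_bw(cb1$dx)
  }
  bot <- inception_bw(dh, cache$bottleneck)
  grads$bottleneck <- bot$grads
  dh <- bot$dx
  for (s in rev(seq_len(depth))) {
    cc <- cache$enc[[s]]
    dd <- dropout_bw(dh, cc$drop)
    dr <- relu_bw(dd, cc$relu)
    cbd <- conv_bw(dr, cc$down)
    dinc <- inception_bw(cbd$dx + dskips[[s]], cc$inc)
    grads$enc[[s]] <- c(dinc$grads, list(down = list(W = cbd$dW, b = cbd$db)))
    dh <- dinc$dx
  }
  list(loss = lg$loss, grads = grads)
}

# elementwise recursion over matching nested parameter lists; paired by
# name where names exist (gradient lists are assembled in reverse order)
map2_params <- function(a, b, f) {
  if (is.list(a)) {
    out <- vector("list", length(a))
    names(out) <- names(a)
    nm <- names(a)
    for (i in seq_along(a)) {
      bi <- if (!is.null(nm) && all(nzchar(nm))) b[[nm[i]]] else b[[i]]
      out[[i]] <- map2_params(a[[i]], bi, f)
    }
    out
  } else {
    f(a, b)
  }
}
map_params <- function(a, f) map2_params(a, a, function(x, ...) f(x))

#' Training configuration
#'
#' @param epochs number of passes over the slice dataset.
#' @param batch_size slices per optimizer step.
#' @param learning_rate Adam step size.
#' @param seed seed governing shuffling and dropout.
#' @return a `train_config` list (optimizer is Adam).
#' @export
train_config <- function(epochs = 200L, batch_size = 6L, learning_rate = 1e-3,
                         seed = 1L) {
  if (epochs < 1L) stop("`epochs` must be at least 1", call. = FALSE)
  if (batch_size < 1L) stop("`batch_size` must be at least 1", call. = FALSE)
  if (learning_rate <= 0) stop("`learning_rate` must be positive", call. = FALSE)
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 learning_rate = learning_rate, optimizer = "adam",
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Train a slice predictor at reduced scale
#'
#' Minimizes `1 - J` (mean soft Jaccard over the edge and core classes,
#' `eps = 1` smoothing) with Adam over all slices of the given exams. Each
#' exam supplies an MR volume, its kidney mask and the target edge-core map
#' on the same grid; slices are shuffled each epoch under the configuration
#' seed, so training is reproducible.
#'
#' @param predictor an `inception_unet` from [build_inception_unet()].
#' @param exams list of `list(mri, kidney, sem)` entries.
#' @param cfg a [train_config()].
#' @return the trained predictor, with the per-epoch mean loss in
#'   `$loss_history`.
#' @export
train_reduced <- function(predictor, exams, cfg = train_config()) {
  stopifnot(inherits(predictor, "inception_unet"))
  if (length(exams) == 0L) stop("at least one exam is required", call. = FALSE)
  for (ex in exams) {
    check_same_grid(ex$mri, ex$sem, "mri and semantic target")
  }
  stacks <- list()
  targets <- list()
  for (ex in exams) {
    norm <- normalize_volume(ex$mri, ex$kidney)
    Z <- dim(ex$mri$data)[3]
    for (z in seq_len(Z)) {
      stacks[[length(stacks) + 1L]] <- stack_slices(norm, ex$kidney, z,
                                                    normalize = FALSE)
      sl <- ex$sem$data[, , z]
      tg <- array(0, c(dim(sl), 3L))
      for (cls in 0:2) tg[, , cls + 1L] <- (sl == cls) * 1.0
      targets[[length(targets) + 1L]] <- tg
    }
  }
  n <- length(stacks)
  lr <- cfg$learning_rate
  beta1 <- 0.9; beta2 <- 0.999; adam_eps <- 1e-8
  m <- map_params(predictor$params, function(x) x * 0)
  v <- m
  t_step <- 0L
  history <- numeric(cfg$epochs)
  predictor <- with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      ep_loss <- 0
      for (start in seq(1L, n, by = cfg$batch_size)) {
        batch <- ord[start:min(start + cfg$batch_size - 1L, n)]
        acc <- NULL
        bloss <- 0
        for (j in batch) {
          fw <- unet_forward(predictor, stacks[[j]], train = TRUE)
          bw <- unet_backward(predictor, fw$cache, targets[[j]])
          bloss <- bloss + bw$loss
          acc <- if (is.null(acc)) bw$grads else map2_params(acc, bw$grads, `+`)
        }
        nb <- length(batch)
        acc <- map_params(acc, function(g) g / nb)
        ep_loss <- ep_loss + bloss
        t_step <- t_step + 1L
        m <- map2_params(m, acc, function(mm, g) beta1 * mm + (1 - beta1) * g)
        v <- map2_params(v, acc, function(vv, g) beta2 * vv + (1 - beta2) * g^2)
        bc1 <- 1 - beta1^t_step
        bc2 <- 1 - beta2^t_step
        upd <- map2_params(m, v, function(mm, vv) {
          lr * (mm / bc1) / (sqrt(vv / bc2) + adam_eps)
        })
        predictor$params <- map2_params(predictor$params, upd, `-`)
      }
      history[ep] <- ep_loss / n
    }
    predictor
  })
  predictor$loss_history <- c(predictor$loss_history, history)
  predictor
}

#' Predict class probabilities for one slice stack
#'
#' Generic predictor contract: a 4-channel 2D stack in, an `(X, Y, 3)`
#' probability array (summing to 1 per voxel) out. `z` is passed through for
#' predictors that need slice context (e.g. the truth-replay predictor used
#' to test the pipeline without trained weights).
#'
#' @param predictor a `slice_predictor`.
#' @param stack `(X, Y, 4)` array from [stack_slices()].
#' @param z slice index, optional.
#' @return `(X, Y, 3)` probability array.
#' @export
predict_slice <- function(predictor, stack, z = NULL) {
  UseMethod("predict_slice")
}

#' @export
predict_slice.inception_unet <- function(predictor, stack, z = NULL) {
  unet_forward(predictor, stack, train = FALSE)$probs
}

#' @export
predict_slice.function_predictor <- function(predictor, stack, z = NULL) {
  predictor$fn(stack, z)
}

#' Wrap a plain function as a slice predictor
#'
#' @param fn `function(stack, z)` returning an `(X, Y, 3)` probability
#'   array.
#' @return a `slice_predictor`.
#' @export
slice_predictor <- function(fn) {
  structure(list(fn = fn), class = c("function_predictor", "slice_predictor"))
}

#' @export
print.inception_unet <- function(x, ...) {
  np <- sum(unlist(map_params(x$params, length)))
  cat(sprintf("<inception_unet> depth %d, base filters %d, %d parameters\n",
              x$config$depth, x$config$base_filters, np))
  if (length(x$loss_history)) {
    cat(sprintf("  trained %d epochs, last loss %.4f\n",
                length(x$loss_history),
                x$loss_history[length(x$loss_history)]))
  }
  invisible(x)
}
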