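# Independent brute-force oracles used to pin down expected values. They are
# deliberately written as plain voxel loops, sharing no code with the
# package internals, and are only ever applied to small fixtures.

offsets6_list <- list(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                      c(0, 0, -1), c(0, 0, 1))
offsets4_list <- offsets6_list[1:4]

# 6-connected component labeling by explicit flood fill.
bf_components6 <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    nxt <- nxt + 1L
    queue <- s
    lab[s] <- nxt
    while (length(queue) > 0L) {
      v <- queue[1]
      queue <- queue[-1]
      ai <- as.integer(arrayInd(v, d))
      for (o in offsets6_list) {
        w <- ai + o
        if (any(w < 1L) || any(w > d)) next
        wi <- w[1] + (w[2] - 1L) * d[1] + (w[3] - 1L) * d[1] * d[2]
        if (mask[wi] && lab[wi] == 0L) {
          lab[wi] <- nxt
          queue <- c(queue, wi)
        }
      }
    }
  }
  lab
}

bf_shift_ok <- function(ai, o, d) {
  w <- ai + o
  !(any(w < 1L) || any(w > d))
}

# Brute-force binary dilation/erosion with the 6-connected cross (3D) or the
# in-plane 4-connected cross (2D, per z-plane when offsets4 given).
bf_dilate <- function(mask, offsets = offsets6_list) {
  d <- dim(mask)
  out <- mask
  for (v in which(mask)) {
    ai <- as.integer(arrayInd(v, d))
    for (o in offsets) {
      w <- ai + o
      if (any(w < 1L) || any(w > d)) next
      out[w[1], w[2], w[3]] <- TRUE
    }
  }
  out
}

bf_erode <- function(mask, offsets = offsets6_list) {
  d <- dim(mask)
  out <- mask
  for (v in which(mask)) {
    ai <- as.integer(arrayInd(v, d))
    for (o in offsets) {
      w <- ai + o
      if (any(w < 1L) || any(w > d) || !mask[w[1], w[2], w[3]]) {
        out[v] <- FALSE
        break
      }
    }
  }
  out
}

bf_open6 <- function(mask) bf_dilate(bf_erode(mask))

# Digitized sphere by voxel-center containment (mm coordinates).
make_sphere <- function(dims, center, r, spacing = c(1, 1, 1)) {
  arr <- array(FALSE, dims)
  for (i in seq_len(dims[1])) for (j in seq_len(dims[2])) for (k in seq_len(dims[3])) {
    p <- (c(i, j, k) - 0.5) * spacing
    if (sum((p - center)^2) <= r^2) arr[i, j, k] <- TRUE
  }
  arr
}

# Are any two distinct positive labels 6-adjacent?
labels_touch6 <- function(lab_arr) {
  for (axis in 1:3) {
    d <- dim(lab_arr)
    n <- d[axis]
    idx_a <- lapply(d, seq_len)
    idx_b <- idx_a
    idx_a[[axis]] <- 1:(n - 1)
    idx_b[[axis]] <- 2:n
    a <- do.call(`[`, c(list(lab_arr), idx_a, list(drop = FALSE)))
    b <- do.call(`[`, c(list(lab_arr), idx_b, list(drop = FALSE)))
    if (any(a > 0L & b > 0L & a != b)) return(TRUE)
  }
  FALSE
}

# Restore a flat numeric vector into the nested array structure of `skel`.
relist_params <- function(flat, skel) {
  i <- 0
  rec <- function(s) {
    if (is.list(s)) return(lapply(s, rec))
    v <- flat[(i + 1):(i + length(s))]
    i <<- i + length(s)
    dim(v) <- dim(s)
    v
  }
  rec(skel)
}

# A small clustered phantom used across tests.
small_phantom <- function(seed = 7L, shape = c(64L, 64L, 16L), n_cysts = 12L,
                          ...) {
  generate_phantom(phantom_spec(shape = shape, n_cysts = n_cysts, seed = seed,
                                ...))
}
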