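# Minimal convolutional-network engine used by the patch classifier and its
# dense expansion. Tensors are H x W x C arrays; every backbone stage is an
# affine map (standard, depthwise, or pointwise convolution) followed by
# ReLU. Forward passes cache what backward needs; gradients are exact
# (verified against finite differences in the test suite).

zero_pad_hw <- function(x, pb, pe, qb, qe) {
  if (pb + pe + qb + qe == 0) return(x)
  d <- dim(x)
  out <- array(0, c(d[1] + pb + pe, d[2] + qb + qe, d[3]))
  out[pb + seq_len(d[1]), qb + seq_len(d[2]), ] <- x
  out
}

# im2col for a standard convolution on a pre-padded array; column order
# matches dim(W) <- c(k*k*Cin, Cout) (row offset fastest, then column
# offset, then input channel — R column-major).
im2col <- function(xpad, k, s, ho, wo) {
  cin <- dim(xpad)[3]
  cols <- matrix(0, ho * wo, k * k * cin)
  idx <- 0L
  rows0 <- s * (seq_len(ho) - 1L)
  cols0 <- s * (seq_len(wo) - 1L)
  for (c in seq_len(cin)) {
    for (v in seq_len(k)) {
      for (u in seq_len(k)) {
        idx <- idx + 1L
        cols[, idx] <- xpad[rows0 + u, cols0 + v, c]
      }
    }
  }
  # reorder: loop above fills u fastest within v within c, matching the
  # column index u + (v-1)k + (c-1)k^2 directly
  cols
}

col2im_add <- function(dcols, dxpad_dim, k, s, ho, wo) {
  dxpad <- array(0, dxpad_dim)
  idx <- 0L
  rows0 <- s * (seq_len(ho) - 1L)
  cols0 <- s * (seq_len(wo) - 1L)
  for (c in seq_len(dxpad_dim[3])) {
    for (v in seq_len(k)) {
      for (u in seq_len(k)) {
        idx <- idx + 1L
        dxpad[rows0 + u, cols0 + v, c] <-
          dxpad[rows0 + u, cols0 + v, c] + matrix(dcols[, idx], ho, wo)
      }
    }
  }
  dxpad
}

unpad_hw <- function(dxpad, pb, pe, qb, qe) {
  d <- dim(dxpad)
  dxpad[pb + seq_len(d[1] - pb - pe), qb + seq_len(d[2] - qb - qe), ,
        drop = FALSE]
}

# ---- layer forward passes ----------------------------------------------

layer_forward <- function(layer, x, keep_cache = FALSE) {
  h <- dim(x)[1]; w <- dim(x)[2]
  k <- layer$kernel; s <- layer$stride
  ph <- same_pad(h, k, s); pw <- same_pad(w, k, s)
  cache <- NULL
  if (layer$type == "pw") {
    cin <- dim(x)[3]
    xm <- matrix(x, h * w, cin)
    zm <- xm %*% layer$W
    zm <- sweep(zm, 2, layer$b, "+")
    z <- array(zm, c(h, w, ncol(layer$W)))
    if (keep_cache) cache <- list(xm = xm, hw = c(h, w))
  } else if (layer$type == "dw") {
    xpad <- zero_pad_hw(x, ph[["beg"]], ph[["end"]], pw[["beg"]], pw[["end"]])
    ho <- ph[["out"]]; wo <- pw[["out"]]
    cc <- dim(x)[3]
    z <- array(rep(layer$b, each = ho * wo), c(ho, wo, cc))
    rows0 <- s * (seq_len(ho) - 1L); cols0 <- s * (seq_len(wo) - 1L)
    for (v in seq_len(k)) {
      for (u in seq_len(k)) {
        kw <- rep(layer$W[u, v, ], each = ho * wo)
        z <- z + xpad[rows0 + u, cols0 + v, , drop = FALSE] * kw
      }
    }
    if (keep_cache) cache <- list(xpad = xpad, ho = ho, wo = wo, ph = ph,
                                  pw = pw)
  } else if (layer$type == "conv") {
    xpad <- zero_pad_hw(x, ph[["beg"]], ph[["end"]], pw[["beg"]], pw[["end"]])
    ho <- ph[["out"]]; wo <- pw[["out"]]
    cin <- dim(x)[3]; cout <- dim(layer$W)[4]
    wmat <- matrix(layer$W, k * k * cin, cout)
    cols <- im2col(xpad, k, s, ho, wo)
    zm <- cols %*% wmat
    zm <- sweep(zm, 2, layer$b, "+")
    z <- array(zm, c(ho, wo, cout))
    if (keep_cache) cache <- list(cols = cols, xpad_dim = dim(xpad),
                                  ho = ho, wo = wo, ph = ph, pw = pw)
  } else {
    stop_rcm(paste0("unknown layer type: ", layer$type), "internal")
  }
  a <- z
  a[a < 0] <- 0
  list(a = a, cache = cache)
}

backbone_forward <- function(layers, x, keep_cache = FALSE) {
  caches <- vector("list", length(layers))
  inputs <- vector("list", length(layers))
  for (i in seq_along(layers)) {
    if (keep_cache) inputs[[i]] <- x
    fw <- layer_forward(layers[[i]], x, keep_cache)
    x <- fw$a
    caches[[i]] <- fw$cache
  }
  list(out = x, caches = caches, inputs = inputs)
}

# ---- backward passes ----------------------------------------------------

layer_backward <- function(layer, da, a_out, cache, need_dx = TRUE) {
  dz <- da * (a_out > 0)
  if (layer$type == "pw") {
    h <- cache$hw[1]; w <- cache$hw[2]
    dzm <- matrix(dz, h * w, dim(dz)[3])
    dW <- crossprod(cache$xm, dzm)
    db <- colSums(dzm)
    dx <- if (need_dx) array(dzm %*% t(layer$W),
                             c(h, w, nrow(layer$W))) else NULL
  } else if (layer$type == "dw") {
    k <- layer$kernel; s <- layer$stride
    ho <- cache$ho; wo <- cache$wo
    cc <- dim(layer$W)[3]
    dW <- array(0, dim(layer$W))
    rows0 <- s * (seq_len(ho) - 1L); cols0 <- s * (seq_len(wo) - 1L)
    dxpad <- if (need_dx) array(0, dim(cache$xpad)) else NULL
    dzm <- matrix(dz, ho * wo, cc)
    for (v in seq_len(k)) {
      for (u in seq_len(k)) {
        xsub <- matrix(cache$xpad[rows0 + u, cols0 + v, , drop = FALSE],
                       ho * wo, cc)
        dW[u, v, ] <- colSums(dzm * xsub)
        if (need_dx) {
          kw <- rep(layer$W[u, v, ], each = ho * wo)
          dxpad[rows0 + u, cols0 + v, ] <-
            dxpad[rows0 + u, cols0 + v, , drop = FALSE] + dz * kw
        }
      }
    }
    db <- colSums(dzm)
    dx <- if (need_dx) unpad_hw(dxpad, cache$ph[["beg"]], cache$ph[["end"]],
                                cache$pw[["beg"]], cache$pw[["end"]]) else NULL
  } else {  # conv
    k <- layer$kernel; s <- layer$stride
    ho <- cache$ho; wo <- cache$wo
    cout <- dim(layer$W)[4]
    dzm <- matrix(dz, ho * wo, cout)
    dWmat <- crossprod(cache$cols, dzm)
    dW <- array(dWmat, dim(layer$W))
    db <- colSums(dzm)
    dx <- NULL
    if (need_dx) {
      cin <- dim(layer$W)[3]
      wmat <- matrix(layer$W, k * k * cin, cout)
      dcols <- dzm %*% t(wmat)
      dxpad <- col2im_add(dcols, cache$xpad_dim, k, s, ho, wo)
      dx <- unpad_hw(dxpad, cache$ph[["beg"]], cache$ph[["end"]],
                     cache$pw[["beg"]], cache$pw[["end"]])
    }
  }
  list(dW = dW, db = db, dx = dx)
}

# Full forward + backward for one patch; y is 1 (healthy) or 2 (malignant).
# Returns loss, probabilities and gradients for all layers plus the head.
patch_grad <- function(layers, head, x, y) {
  fw <- backbone_forward(layers, x, keep_cache = TRUE)
  f <- fw$out
  hw <- dim(f)[1] * dim(f)[2]
  g <- apply(f, 3, mean)
  logits <- drop(crossprod(head$W, g)) + head$b
  logits <- logits - max(logits)
  p <- exp(logits) / sum(exp(logits))
  loss <- -log(max(p[y], 1e-12))
  dlogit <- p
  dlogit[y] <- dlogit[y] - 1
  dW_head <- outer(g, dlogit)
  db_head <- dlogit
  dg <- drop(head$W %*% dlogit)
  df <- array(rep(dg / hw, each = hw), dim(f))
  grads <- vector("list", length(layers))
  da <- df
  a_outs <- c(fw$inputs[-1], list(f))
  for (i in rev(seq_along(layers))) {
    bk <- layer_backward(layers[[i]], da, a_outs[[i]], fw$caches[[i]],
                         need_dx = i > 1L)
    grads[[i]] <- list(dW = bk$dW, db = bk$db)
    da <- bk$dx
  }
  list(loss = loss, p = p, grads = grads,
       head_grad = list(dW = dW_head, db = db_head))
}

# ---- Adam ----------------------------------------------------------------

adam_init_like <- function(x) list(m = x * 0, v = x * 0)

adam_init <- function(layers, head) {
  list(
    layers = lapply(layers, function(l)
      list(W = adam_init_like(l$W), b = adam_init_like(l$b))),
    head = list(W = adam_init_like(head$W), b = adam_init_like(head$b)),
    t = 0L
  )
}

adam_update <- function(param, grad, st, lr, b1 = 0.9, b2 = 0.999,
                        eps = 1e-8, t = 1L) {
  st$m <- b1 * st$m + (1 - b1) * grad
  st$v <- b2 * st$v + (1 - b2) * grad^2
  mhat <- st$m / (1 - b1^t)
  vhat <- st$v / (1 - b2^t)
  list(param = param - lr * mhat / (sqrt(vhat) + eps), state = st)
}
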