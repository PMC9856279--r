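# Low-level layer primitives for the multi-slice tensor network.
#
# Convolutions are 3x3, stride 1, same-padding, realised as im2col + GEMM so
# the heavy lifting runs in BLAS. The im2col index matrices depend only on
# the input shape and are cached per (H, W, C).

.idx_cache <- new.env(parent = emptyenv())

# (H*W) x (9*C) matrix of linear indices into the zero-padded (H+2, W+2, C)
# array; column order matches the (3, 3, C, F) weight layout (di fastest,
# then dj, then channel)
im2col_idx <- function(H, W, C) {
  key <- paste(H, W, C, sep = "x")
  hit <- .idx_cache[[key]]
  if (!is.null(hit)) return(hit)
  P <- H + 2L
  pos_i <- rep(seq_len(H), times = W)
  pos_j <- rep(seq_len(W), each = H)
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1))
  idx <- matrix(0L, H * W, 9L * C)
  k <- 0L
  plane <- P * (W + 2L)
  for (c0 in seq_len(C)) {
    for (o in seq_len(9L)) {
      k <- k + 1L
      idx[, k] <- (pos_i + 1L + off[o, 1L]) + (pos_j + off[o, 2L]) * P +
        (c0 - 1L) * plane
    }
  }
  .idx_cache[[key]] <- idx
  idx
}

# x: (H, W, C) array -> col: (H*W) x (9C) matrix
im2col <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]
  xp <- array(0, c(H + 2L, W + 2L, C))
  xp[2:(H + 1L), 2:(W + 1L), ] <- x
  col <- xp[im2col_idx(H, W, C)]
  dim(col) <- c(H * W, 9L * C)
  col
}

# scatter-add of dcol back to the (unpadded) input gradient; nine
# vectorised indexed additions, one per kernel offset, reusing the cached
# im2col index matrix (within one offset all target positions are distinct)
col2im <- function(dcol, H, W, C) {
  idx <- im2col_idx(H, W, C)
  dxp <- numeric((H + 2L) * (W + 2L) * C)
  for (o in seq_len(9L)) {
    cols_o <- seq.int(o, 9L * C, by = 9L)
    v <- idx[, cols_o]
    dxp[v] <- dxp[v] + dcol[, cols_o]
  }
  dim(dxp) <- c(H + 2L, W + 2L, C)
  dxp[2:(H + 1L), 2:(W + 1L), , drop = FALSE]
}

# conv + bias; returns pre-activation as (H*W) x F matrix plus the col
# matrix needed for the weight gradient
conv_fwd <- function(x, Wm, b) {
  col <- im2col(x)
  pre <- col %*% Wm
  pre <- pre + rep(b, each = nrow(pre))
  list(pre = pre, col = col)
}

relu <- function(x) { x[x < 0] <- 0; x }

# dpre: gradient at the pre-activation, (H*W) x F
conv_bwd <- function(dpre, col, Wm, H, W, C, need_dx = TRUE) {
  g <- list(dW = crossprod(col, dpre), db = colSums(dpre))
  if (need_dx) g$dx <- col2im(tcrossprod(dpre, Wm), H, W, C)
  g
}

# 2x2 max pool, stride 2; x: (H, W, C) -> out (H/2, W/2, C) with the argmax
# quadrant (1=TL, 2=BL, 3=TR, 4=BR; ties to the first) kept for backprop
maxpool_fwd <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  ro <- seq.int(1L, H, 2L); re <- seq.int(2L, H, 2L)
  co <- seq.int(1L, W, 2L); ce <- seq.int(2L, W, 2L)
  a <- x[ro, co, , drop = FALSE]; b <- x[re, co, , drop = FALSE]
  cc <- x[ro, ce, , drop = FALSE]; dd <- x[re, ce, , drop = FALSE]
  out <- pmax(a, b, cc, dd)
  sel <- array(4L, dim(out))
  sel[cc == out] <- 3L
  sel[b == out] <- 2L
  sel[a == out] <- 1L
  list(out = out, sel = sel)
}

maxpool_bwd <- function(dout, sel, H, W) {
  d <- dim(dout); h <- d[1]; w <- d[2]; C <- d[3]
  # linear index of each argmax cell in the (H, W, C) input
  # sel coding: 1 = TL, 2 = BL, 3 = TR, 4 = BR of each 2x2 block
  i <- rep.int(seq_len(h), w * C)
  j <- rep.int(rep(seq_len(w), each = h), C)
  cc <- rep(seq_len(C), each = h * w)
  row <- 2L * i - 1L + (sel == 2L | sel == 4L)
  col <- 2L * j - 1L + (sel == 3L | sel == 4L)
  dx <- numeric(H * W * C)
  dx[row + (col - 1L) * H + (cc - 1L) * (H * W)] <- dout
  dim(dx) <- c(H, W, C)
  dx
}

# 2x2 average pool, stride 2
avgpool_fwd <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]
  ro <- seq.int(1L, H, 2L); re <- seq.int(2L, H, 2L)
  co <- seq.int(1L, W, 2L); ce <- seq.int(2L, W, 2L)
  (x[ro, co, , drop = FALSE] + x[re, co, , drop = FALSE] +
   x[ro, ce, , drop = FALSE] + x[re, ce, , drop = FALSE]) / 4
}

avgpool_bwd <- function(dout, H, W) {
  C <- dim(dout)[3]
  dx <- array(0, c(H, W, C))
  q <- dout / 4
  ro <- seq.int(1L, H, 2L); re <- seq.int(2L, H, 2L)
  co <- seq.int(1L, W, 2L); ce <- seq.int(2L, W, 2L)
  dx[ro, co, ] <- q; dx[re, co, ] <- q; dx[ro, ce, ] <- q; dx[re, ce, ] <- q
  dx
}

softmax <- function(z) {
  z <- z - max(z)
  e <- exp(z)
  e / sum(e)
}

# Adam optimizer state and update
adam_init <- function(params) {
  st <- new.env(parent = emptyenv())
  st$m <- lapply(params, function(p) p * 0)
  st$v <- lapply(params, function(p) p * 0)
  st$t <- 0L
  st
}

adam_step <- function(params, grads, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  # bias-corrected step rewritten as lr_t * m / (sqrt(v) + eps_t) to avoid
  # per-parameter temporaries for the corrections
  bc2r <- sqrt(1 - beta2^st$t)
  lr_t <- lr * bc2r / (1 - beta1^st$t)
  eps_t <- eps * bc2r
  for (nm in names(params)) {
    g <- grads[[nm]]
    m <- st$m[[nm]] <- beta1 * st$m[[nm]] + (1 - beta1) * g
    v <- st$v[[nm]] <- beta2 * st$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] - lr_t * m / (sqrt(v) + eps_t)
  }
  params
}
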