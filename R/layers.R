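# Thin R wrappers over the C++ kernels. Activations are plain R arrays
# dim c(H, W, C); weights are arrays dim c(k, k, Cin, Cout).

as_feature <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  x
}

conv2d <- function(x, W, b) {
  d <- dim(W)
  .cpp_conv2d(as_feature(x), matrix(W, d[1] * d[2] * d[3], d[4]), b, d[1])
}

conv2d_bwd <- function(x, W, gout) {
  d <- dim(W)
  out <- .cpp_conv2d_backward(as_feature(x),
                              matrix(W, d[1] * d[2] * d[3], d[4]),
                              d[1], gout)
  dim(out$gW) <- d
  out$gb <- as.vector(out$gb)
  out
}

convT2x2 <- function(x, W, b) {
  d <- dim(W)
  .cpp_convT2x2(as_feature(x), matrix(W, 4L * d[3], d[4]), b)
}

convT2x2_bwd <- function(x, W, gout) {
  d <- dim(W)
  out <- .cpp_convT2x2_backward(as_feature(x), matrix(W, 4L * d[3], d[4]),
                                gout)
  dim(out$gW) <- d
  out$gb <- as.vector(out$gb)
  out
}

relu <- function(x) x * (x > 0)
relu_bwd <- function(x, g) g * (x > 0)

# numerically clamped so outputs are strictly inside (0, 1) in double
# precision even for extreme logits
sigmoid <- function(x) 1 / (1 + exp(-pmin(pmax(x, -30), 30)))

# nearest-neighbour 2x upsampling (for upsample_mode = "interp_plus_conv")
upsample_nn2 <- function(x) {
  x <- as_feature(x)
  idx_h <- rep(seq_len(dim(x)[1]), each = 2L)
  idx_w <- rep(seq_len(dim(x)[2]), each = 2L)
  x[idx_h, idx_w, , drop = FALSE]
}

upsample_nn2_bwd <- function(g, H, W) {
  C <- dim(g)[3]
  gx <- array(0, c(H, W, C))
  for (a in 1:2) for (b in 1:2) {
    gx <- gx + g[seq(a, 2 * H, by = 2), seq(b, 2 * W, by = 2), ,
                 drop = FALSE]
  }
  gx
}

concat_channels <- function(a, b) {
  da <- dim(a); db <- dim(b)
  array(c(a, b), c(da[1], da[2], da[3] + db[3]))
}

# multiply every channel of x (H,W,C) by the plane m (H,W[,1]);
# relies on column-major recycling: the first H*W elements are channel 1
gate <- function(x, m) x * as.vector(m)
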