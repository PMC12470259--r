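# Forward and backward passes. The network is a function of a flat named
# weight list, so the training engine can treat parameters uniformly.
# Caches hold exactly what each backward step needs (conv inputs,
# pre-activation signs, pooling argmaxes, attention planes).

## ---- encoder -------------------------------------------------------------

encoder_forward <- function(x, wts, cfg, train = FALSE) {
  L <- cfg$depth
  cur <- as_feature(x)
  skips <- vector("list", L - 1L)
  cache <- if (train) list(levels = vector("list", L)) else NULL
  for (l in seq_len(L)) {
    w1 <- wts[[sprintf("enc%d.c1.W", l)]]
    z1 <- conv2d(cur, w1, wts[[sprintf("enc%d.c1.b", l)]])
    a1 <- relu(z1)
    z2 <- conv2d(a1, wts[[sprintf("enc%d.c2.W", l)]],
                 wts[[sprintf("enc%d.c2.b", l)]])
    a2 <- relu(z2)
    if (train) {
      cache$levels[[l]] <- list(x_in = cur, z1 = z1, a1 = a1, z2 = z2)
    }
    if (l < L) {
      skips[[l]] <- a2
      mp <- .cpp_maxpool2(a2)
      if (train) cache$levels[[l]]$argmax <- mp$argmax
      cur <- mp$out
    } else {
      cur <- a2
    }
  }
  list(bottleneck = cur, skips = skips, cache = cache)
}

# gbottleneck: grad wrt level-L output; gskips: list of grads wrt each skip
encoder_backward <- function(gbottleneck, gskips, cache, wts, cfg) {
  L <- cfg$depth
  grads <- list()
  gdown <- gbottleneck
  for (l in rev(seq_len(L))) {
    cv <- cache$levels[[l]]
    if (l < L) {
      d <- dim(cv$z2)
      ga2 <- .cpp_maxpool2_backward(cv$argmax, gdown, d[1], d[2])
      if (!is.null(gskips[[l]])) ga2 <- ga2 + gskips[[l]]
    } else {
      ga2 <- gdown
    }
    gz2 <- relu_bwd(cv$z2, ga2)
    b2 <- conv2d_bwd(cv$a1, wts[[sprintf("enc%d.c2.W", l)]], gz2)
    grads[[sprintf("enc%d.c2.W", l)]] <- b2$gW
    grads[[sprintf("enc%d.c2.b", l)]] <- b2$gb
    gz1 <- relu_bwd(cv$z1, b2$gx)
    b1 <- conv2d_bwd(cv$x_in, wts[[sprintf("enc%d.c1.W", l)]], gz1)
    grads[[sprintf("enc%d.c1.W", l)]] <- b1$gW
    grads[[sprintf("enc%d.c1.b", l)]] <- b1$gb
    gdown <- b1$gx
  }
  grads
}

## ---- spatial attention ---------------------------------------------------

sa_forward <- function(feature, W, b, train = FALSE) {
  k <- dim(W)[1]
  d <- dim(feature)
  if (k %% 2L == 0L) stop("SA kernel size must be odd", call. = FALSE)
  if (d[1] < k || d[2] < k) {
    stop(sprintf("feature map %dx%d is smaller than the %dx%d SA kernel",
                 d[1], d[2], k, k), call. = FALSE)
  }
  cp <- .cpp_channel_pool(feature)
  z <- conv2d(cp$out, W, b)
  A <- sigmoid(z[, , 1])
  out <- gate(feature, A)
  cache <- if (train) {
    list(feature = feature, cp_out = cp$out, argmax = cp$argmax, A = A)
  }
  list(out = out, attention = A, cache = cache)
}

sa_backward <- function(g, cache, W) {
  C <- dim(cache$feature)[3]
  gfeat <- gate(g, cache$A)
  gA <- rowSums(g * cache$feature, dims = 2L)
  gz <- gA * cache$A * (1 - cache$A)
  dim(gz) <- c(dim(gz), 1L)
  bb <- conv2d_bwd(cache$cp_out, W, gz)
  gfeat <- gfeat + .cpp_channel_pool_backward(bb$gx, cache$argmax, C)
  list(gx = gfeat, gW = bb$gW, gb = bb$gb)
}

#' Spatial attention gate
#'
#' Applies the bottleneck spatial-attention operator to a feature map:
#' channel-wise max- and average-pooling produce two HxW descriptor planes,
#' their 2-channel stack passes through a single k x k same-padded
#' convolution, a sigmoid yields the attention plane in (0,1), and the input
#' is gated by it channel-wise. Output shape equals input shape.
#'
#' @param feature HxWxC array (or HxW matrix, treated as one channel).
#' @param W Convolution weights, array dim `c(k, k, 2, 1)` with odd `k`.
#' @param b Bias (length 1). Default 0.
#' @return List with `out` (gated feature map) and `attention` (HxW plane).
#' @export
spatial_attention <- function(feature, W, b = 0) {
  feature <- as_feature(feature)
  res <- sa_forward(feature, W, b, train = FALSE)
  res[c("out", "attention")]
}

## ---- decoder -------------------------------------------------------------

decoder_forward <- function(bottleneck, skips, wts, cfg, train = FALSE) {
  L <- cfg$depth
  cur <- bottleneck
  cache <- if (train) list(levels = vector("list", L - 1L)) else NULL
  for (l in seq_len(L - 1L)) {
    upW <- wts[[sprintf("dec%d.up.W", l)]]
    upb <- wts[[sprintf("dec%d.up.b", l)]]
    if (cfg$upsample_mode == "transposed_conv") {
      up <- convT2x2(cur, upW, upb)
    } else {
      nn <- upsample_nn2(cur)
      up <- conv2d(nn, upW, upb)
    }
    skip <- skips[[L - l]]
    du <- dim(up); ds <- dim(skip)
    if (!identical(du[1:2], ds[1:2])) {
      stop(sprintf(
        "decoder level %d: upsampled map is %dx%dx%d but skip is %dx%dx%d",
        l, du[1], du[2], du[3], ds[1], ds[2], ds[3]), call. = FALSE)
    }
    cat_ <- concat_channels(up, skip)
    z1 <- conv2d(cat_, wts[[sprintf("dec%d.c1.W", l)]],
                 wts[[sprintf("dec%d.c1.b", l)]])
    a1 <- relu(z1)
    z2 <- conv2d(a1, wts[[sprintf("dec%d.c2.W", l)]],
                 wts[[sprintf("dec%d.c2.b", l)]])
    a2 <- relu(z2)
    if (train) {
      cache$levels[[l]] <- list(x_in = cur, cat_ = cat_, z1 = z1, a1 = a1,
                                z2 = z2, n_up = du[3])
    }
    cur <- a2
  }
  list(out = cur, cache = cache)
}

decoder_backward <- function(g, cache, wts, cfg) {
  L <- cfg$depth
  grads <- list()
  gskips <- vector("list", L - 1L)
  for (l in rev(seq_len(L - 1L))) {
    cv <- cache$levels[[l]]
    gz2 <- relu_bwd(cv$z2, g)
    b2 <- conv2d_bwd(cv$a1, wts[[sprintf("dec%d.c2.W", l)]], gz2)
    grads[[sprintf("dec%d.c2.W", l)]] <- b2$gW
    grads[[sprintf("dec%d.c2.b", l)]] <- b2$gb
    gz1 <- relu_bwd(cv$z1, b2$gx)
    b1 <- conv2d_bwd(cv$cat_, wts[[sprintf("dec%d.c1.W", l)]], gz1)
    grads[[sprintf("dec%d.c1.W", l)]] <- b1$gW
    grads[[sprintf("dec%d.c1.b", l)]] <- b1$gb
    nu <- cv$n_up
    gup <- b1$gx[, , seq_len(nu), drop = FALSE]
    gskips[[L - l]] <- b1$gx[, , -seq_len(nu), drop = FALSE]
    upW <- wts[[sprintf("dec%d.up.W", l)]]
    if (cfg$upsample_mode == "transposed_conv") {
      bu <- convT2x2_bwd(cv$x_in, upW, gup)
      g <- bu$gx
    } else {
      nn <- upsample_nn2(cv$x_in)
      bu <- conv2d_bwd(nn, upW, gup)
      d <- dim(cv$x_in)
      g <- upsample_nn2_bwd(bu$gx, d[1], d[2])
    }
    grads[[sprintf("dec%d.up.W", l)]] <- bu$gW
    grads[[sprintf("dec%d.up.b", l)]] <- bu$gb
  }
  list(g_bottleneck = g, gskips = gskips, grads = grads)
}

## ---- segmentation head ---------------------------------------------------

head_forward <- function(feature, wts) {
  z <- conv2d(feature, wts[["head.W"]], wts[["head.b"]])
  list(z = z, p = sigmoid(z))
}

#' Segmentation head
#'
#' Maps a final decoder (or ISA-fused) feature map to per-pixel foreground
#' probabilities through a 1x1 convolution and a sigmoid. Probabilities are
#' strictly inside (0,1).
#'
#' @param feature HxWxC feature map.
#' @param model An `attunet_model`.
#' @return HxW matrix of probabilities, class `segmentation_map`.
#' @export
segmentation_head <- function(feature, model) {
  p <- head_forward(as_feature(feature), model$weights)$p[, , 1]
  structure(p, class = c("segmentation_map", class(p)))
}

## ---- inter-slice attention -----------------------------------------------

isa_mask <- function(Fn, W, b, train = FALSE) {
  cp <- .cpp_channel_pool(Fn)
  z <- conv2d(cp$out, W, b)
  M <- sigmoid(z[, , 1])
  list(M = M,
       cache = if (train) list(Fn = Fn, cp_out = cp$out,
                               argmax = cp$argmax))
}

isa_forward <- function(Fp, Fc, Fn, W, b, train = FALSE) {
  dp <- dim(Fp); dc <- dim(Fc); dn <- dim(Fn)
  if (!identical(dp, dc) || !identical(dn, dc)) {
    stop(sprintf(
      "slice triplet shapes differ: prev %s, curr %s, next %s",
      paste(dp, collapse = "x"), paste(dc, collapse = "x"),
      paste(dn, collapse = "x")), call. = FALSE)
  }
  mp <- isa_mask(Fp, W, b, train)
  mn <- isa_mask(Fn, W, b, train)
  fused <- gate(Fc, mp$M) + gate(Fc, mn$M)
  list(out = fused, m_prev = mp$M, m_next = mn$M,
       cache = if (train) list(Fc = Fc, mp = mp, mn = mn))
}

isa_backward <- function(g, cache, W) {
  C <- dim(cache$Fc)[3]
  gFc <- gate(g, cache$mp$M) + gate(g, cache$mn$M)
  gW <- 0; gb <- 0
  neigh <- list(cache$mp, cache$mn)
  gFs <- vector("list", 2L)
  for (i in 1:2) {
    m <- neigh[[i]]
    gM <- rowSums(g * cache$Fc, dims = 2L)
    gz <- gM * m$M * (1 - m$M)
    dim(gz) <- c(dim(gz), 1L)
    bb <- conv2d_bwd(m$cache$cp_out, W, gz)
    gW <- gW + bb$gW
    gb <- gb + bb$gb
    gFs[[i]] <- .cpp_channel_pool_backward(bb$gx, m$cache$argmax, C)
  }
  list(g_prev = gFs[[1]], g_curr = gFc, g_next = gFs[[2]],
       gW = gW, gb = gb)
}

#' Inter-slice attention fusion
#'
#' Computes attention planes from the two neighbouring slices' feature maps
#' (each through the shared lightweight operator: channel max+avg pooling,
#' 2-channel 3x3 convolution, sigmoid) and fuses the current slice as
#' `curr * M_prev + curr * M_next`. The same weights serve both neighbours,
#' so the operator is symmetric by construction.
#'
#' @param prev,curr,next_ HxWxC feature maps of slices i-1, i, i+1.
#' @param W ISA convolution weights, array dim `c(3, 3, 2, 1)`.
#' @param b Bias (length 1). Default 0.
#' @return List with `out` (fused HxWxC map), `m_prev`, `m_next` (HxW
#'   attention planes).
#' @export
inter_slice_attention <- function(prev, curr, next_, W, b = 0) {
  res <- isa_forward(as_feature(prev), as_feature(curr), as_feature(next_),
                     W, b, train = FALSE)
  res[c("out", "m_prev", "m_next")]
}

## ---- public encode / decode ----------------------------------------------

#' Run the encoder
#'
#' @param image Input slice: HxW matrix (or HxWx1 array) matching the
#'   configured input size.
#' @param model An `attunet_model`.
#' @return List with `bottleneck` (the deepest feature map, before the SA
#'   gate) and `skips` (pre-pooling outputs of the shallower levels,
#'   shallowest first).
#' @export
encode <- function(image, model) {
  validate_slice_input(image, model$config)
  enc <- encoder_forward(image, model$weights, model$config)
  enc[c("bottleneck", "skips")]
}

#' Run the decoder
#'
#' @param bottleneck Deepest feature map (after the SA gate, if enabled).
#' @param skips Skip feature maps as returned by [encode()].
#' @param model An `attunet_model`.
#' @return The final decoder feature map (HxW x base_channels), before the
#'   segmentation head.
#' @export
decode <- function(bottleneck, skips, model) {
  decoder_forward(bottleneck, skips, model$weights, model$config)$out
}

## ---- full forward over a subject ------------------------------------------

core_forward <- function(x, wts, cfg, train = FALSE) {
  enc <- encoder_forward(x, wts, cfg, train)
  bn <- enc$bottleneck
  sa <- NULL
  if (cfg$sa_enabled) {
    sa <- sa_forward(bn, wts[["sa.W"]], wts[["sa.b"]], train)
    bn <- sa$out
  }
  dec <- decoder_forward(bn, enc$skips, wts, cfg, train)
  list(out = dec$out,
       cache = if (train) list(enc = enc$cache, sa = sa$cache,
                               dec = dec$cache))
}

core_backward <- function(gF, cache, wts, cfg) {
  db <- decoder_backward(gF, cache$dec, wts, cfg)
  grads <- db$grads
  gbn <- db$g_bottleneck
  if (cfg$sa_enabled) {
    sb <- sa_backward(gbn, cache$sa, wts[["sa.W"]])
    grads[["sa.W"]] <- sb$gW
    grads[["sa.b"]] <- sb$gb
    gbn <- sb$gx
  }
  ge <- encoder_backward(gbn, db$gskips, cache$enc, wts, cfg)
  c(grads, ge)
}

neighbour_feature <- function(feats, i, offset, policy) {
  j <- i + offset
  if (j >= 1L && j <= length(feats)) return(feats[[j]])
  if (policy == "replicate") return(feats[[i]])
  array(0, dim(feats[[i]]))
}

#' Forward pass over a whole subject volume
#'
#' Runs every slice through the encoder--decoder (with the SA gate if
#' enabled). When inter-slice attention is enabled, each slice's pre-head
#' decoder features are fused with attention planes derived from its two
#' neighbours (boundary slices follow the configured boundary policy) before
#' the 1x1 sigmoid head; otherwise the head is applied directly, which is
#' exactly the plain U-Net forward pass.
#'
#' @param volume A [subject_volume()] (slices already sized to the model's
#'   input, e.g. via [pad_to_canvas()]).
#' @param model An `attunet_model`.
#' @return List of HxW probability matrices (class `segmentation_map`),
#'   one per slice, in stacking order.
#' @export
forward_subject <- function(volume, model) {
  n <- length(volume$slices)
  if (n == 0L) stop("volume has no slices", call. = FALSE)
  cfg <- model$config
  wts <- model$weights
  feats <- lapply(volume$slices, function(s) {
    validate_slice_input(s, cfg)
    core_forward(s, wts, cfg, train = FALSE)$out
  })
  lapply(seq_len(n), function(i) {
    f <- feats[[i]]
    if (cfg$isa_enabled) {
      fp <- neighbour_feature(feats, i, -1L, cfg$isa_boundary_policy)
      fn <- neighbour_feature(feats, i, +1L, cfg$isa_boundary_policy)
      f <- isa_forward(fp, f, fn, wts[["isa.W"]], wts[["isa.b"]])$out
    }
    p <- head_forward(f, wts)$p[, , 1]
    structure(p, class = c("segmentation_map", class(p)))
  })
}

#' Threshold a probability map into a binary mask
#'
#' A pixel is foreground iff its probability strictly exceeds the threshold,
#' so an exactly-at-threshold probability maps to background.
#'
#' @param map HxW probability matrix.
#' @param threshold Decision threshold in the open interval (0,1).
#' @return HxW binary (0/1) matrix.
#' @export
binarize <- function(map, threshold = 0.5) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      threshold <= 0 || threshold >= 1) {
    stop("threshold must be a single number strictly between 0 and 1",
         call. = FALSE)
  }
  (unclass(map) > threshold) * 1
}
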