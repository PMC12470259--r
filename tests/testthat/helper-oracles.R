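# Brute-force reference implementations, deliberately written as explicit
# loops over pixels so they share no code with the package's kernels.

oracle_conv2d <- function(x, W, b) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L)
  H <- dim(x)[1]; Wd <- dim(x)[2]; Cin <- dim(x)[3]
  k <- dim(W)[1]; Cout <- dim(W)[4]
  pad <- (k - 1) / 2
  out <- array(0, c(H, Wd, Cout))
  for (co in seq_len(Cout)) {
    for (h in seq_len(H)) {
      for (w in seq_len(Wd)) {
        acc <- b[co]
        for (ci in seq_len(Cin)) {
          for (ky in seq_len(k)) {
            for (kx in seq_len(k)) {
              hy <- h + ky - 1 - pad
              wx <- w + kx - 1 - pad
              if (hy >= 1 && hy <= H && wx >= 1 && wx <= Wd) {
                acc <- acc + x[hy, wx, ci] * W[ky, kx, ci, co]
              }
            }
          }
        }
        out[h, w, co] <- acc
      }
    }
  }
  out
}

oracle_channel_pool <- function(x) {
  H <- dim(x)[1]; Wd <- dim(x)[2]
  out <- array(0, c(H, Wd, 2))
  for (h in seq_len(H)) {
    for (w in seq_len(Wd)) {
      out[h, w, 1] <- max(x[h, w, ])
      out[h, w, 2] <- mean(x[h, w, ])
    }
  }
  out
}

oracle_sigmoid <- function(z) 1 / (1 + exp(-z))

# spatial attention: channel max/avg pool -> concat -> conv -> sigmoid -> gate
oracle_sa <- function(feature, W, b) {
  desc <- oracle_channel_pool(feature)
  A <- oracle_sigmoid(oracle_conv2d(desc, W, b)[, , 1])
  out <- feature
  for (c in seq_len(dim(feature)[3])) out[, , c] <- feature[, , c] * A
  list(out = out, attention = A)
}

# inter-slice attention with weights shared between the two neighbours
oracle_isa <- function(prev, curr, nxt, W, b) {
  mask_of <- function(f) {
    oracle_sigmoid(oracle_conv2d(oracle_channel_pool(f), W, b)[, , 1])
  }
  mp <- mask_of(prev)
  mn <- mask_of(nxt)
  out <- curr
  for (c in seq_len(dim(curr)[3])) {
    out[, , c] <- curr[, , c] * mp + curr[, , c] * mn
  }
  list(out = out, m_prev = mp, m_next = mn)
}

# explicit double-loop confusion tally
oracle_confusion <- function(pred, truth) {
  tp <- fp <- tn <- fn <- 0
  for (i in seq_len(nrow(pred))) {
    for (j in seq_len(ncol(pred))) {
      if (pred[i, j] == 1 && truth[i, j] == 1) tp <- tp + 1
      else if (pred[i, j] == 1 && truth[i, j] == 0) fp <- fp + 1
      else if (pred[i, j] == 0 && truth[i, j] == 1) fn <- fn + 1
      else tn <- tn + 1
    }
  }
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

# set-overlap metrics from explicit pixel index sets
oracle_overlap_metrics <- function(pred, truth) {
  A <- which(pred == 1)
  B <- which(truth == 1)
  inter <- length(intersect(A, B))
  uni <- length(union(A, B))
  list(dice = 2 * inter / (length(A) + length(B)), iou = inter / uni)
}

rand_mask <- function(h, w, p = 0.3) {
  matrix(as.numeric(rbinom(h * w, 1, p)), h, w)
}

# small phantom dataset for fast training tests
tiny_phantom <- function(n_subjects = 4L, seed = 11L,
                         n_train = n_subjects - 1L) {
  params <- phantom_params(
    n_subjects = n_subjects, slices_per_subject = 6L, labeled_band = 4L,
    image_size = c(32L, 32L), crescent_outer_radius = c(6, 8),
    crescent_thickness = c(2.5, 3.5), drift_per_slice = 0.6,
    noise_sigma = 0.05, bias_amplitude = 0.1, seed = seed)
  generate_dataset(params, n_train = n_train)
}
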