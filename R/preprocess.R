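# Slice conditioning. Images are HxW matrices in [0,1]; masks are strictly
# {0,1} HxW matrices. Enhancement stages never touch masks; the only
# geometric operations (pad/crop/flip) are applied to both in lockstep.

#' Per-slice min-max intensity normalization
#'
#' Scales a raw slice to [0,1]. A constant slice (no dynamic range) maps to
#' all zeros rather than dividing by zero.
#'
#' @param raw_slice Numeric matrix with finite values.
#' @return Matrix in [0,1], same size.
#' @export
normalize_intensity <- function(raw_slice) {
  if (!all(is.finite(raw_slice))) {
    stop("slice contains non-finite values", call. = FALSE)
  }
  rng <- range(raw_slice)
  if (rng[1] == rng[2]) {
    return(array(0, dim(raw_slice)))
  }
  (raw_slice - rng[1]) / (rng[2] - rng[1])
}

#' Zero-pad a slice onto a fixed canvas / crop it back
#'
#' `pad_to_canvas()` centres the slice on a `target`-sized zero canvas and
#' records the original size and offset as attributes, so that
#' `crop_back(pad_to_canvas(x))` is exactly `x`. Used to bring arbitrary
#' acquisition sizes to the network's input size without resampling, and to
#' undo it at output so no distortion is introduced.
#'
#' @param img HxW matrix (image or mask).
#' @param target Target size `c(height, width)`; default 256x256.
#' @return Padded matrix with attributes `original_size` and `offset`.
#' @export
pad_to_canvas <- function(img, target = c(256L, 256L)) {
  d <- dim(img)
  if (d[1] > target[1] || d[2] > target[2]) {
    stop(sprintf("slice %dx%d exceeds the %dx%d canvas; refusing to downscale",
                 d[1], d[2], target[1], target[2]), call. = FALSE)
  }
  off <- c((target[1] - d[1]) %/% 2L, (target[2] - d[2]) %/% 2L)
  out <- matrix(0, target[1], target[2])
  out[off[1] + seq_len(d[1]), off[2] + seq_len(d[2])] <- img
  attr(out, "original_size") <- d
  attr(out, "offset") <- off
  out
}

#' @rdname pad_to_canvas
#' @export
crop_back <- function(img) {
  d <- attr(img, "original_size")
  off <- attr(img, "offset")
  if (is.null(d) || is.null(off)) {
    stop("no padding metadata on this slice; was it produced by pad_to_canvas()?",
         call. = FALSE)
  }
  out <- img[off[1] + seq_len(d[1]), off[2] + seq_len(d[2]), drop = FALSE]
  attributes(out)[c("original_size", "offset")] <- NULL
  out
}

# carry pad metadata from a padded input onto a same-size output map
copy_pad_meta <- function(to, from) {
  attr(to, "original_size") <- attr(from, "original_size")
  attr(to, "offset") <- attr(from, "offset")
  to
}

#' Contrast-limited adaptive histogram equalization
#'
#' Local-contrast enhancement for images only (never masks); delegates to
#' `EBImage::clahe()`. Output is clamped back into [0,1].
#'
#' @param img HxW matrix in [0,1].
#' @param clip_limit Contrast clip limit (> 0); default 2.
#' @param tiles Tile grid `c(nx, ny)`; default 8x8.
#' @return Enhanced matrix in [0,1].
#' @export
clahe_enhance <- function(img, clip_limit = 2, tiles = c(8L, 8L)) {
  if (!is.numeric(clip_limit) || clip_limit <= 0) {
    stop("clip_limit must be positive", call. = FALSE)
  }
  # the tile grid must divide the image evenly; replicate edges up to the
  # next multiple and crop back afterwards
  d <- dim(img)
  dp <- ceiling(d / tiles) * tiles
  work <- img[pmin(seq_len(dp[1]), d[1]), pmin(seq_len(dp[2]), d[2])]
  out <- EBImage::clahe(work, nx = tiles[1], ny = tiles[2],
                        limit = clip_limit)
  out <- pmin(pmax(as.matrix(out), 0), 1)[seq_len(d[1]), seq_len(d[2])]
  dim(out) <- d
  out
}

#' Gaussian denoising
#'
#' Linear Gaussian smoothing via `EBImage::gblur()`; preserves mean
#' intensity up to boundary effects.
#'
#' @param img HxW matrix.
#' @param sigma Gaussian standard deviation in pixels (> 0); default 1.
#' @return Smoothed matrix.
#' @export
gaussian_denoise <- function(img, sigma = 1) {
  if (!is.numeric(sigma) || sigma <= 0) {
    stop("sigma must be positive", call. = FALSE)
  }
  out <- as.matrix(EBImage::gblur(img, sigma = sigma))
  dim(out) <- dim(img)
  out
}

flip_h <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
flip_v <- function(m) m[rev(seq_len(nrow(m))), , drop = FALSE]

#' Paired flip augmentation
#'
#' Applies a random horizontal flip and a random vertical flip, each with
#' probability 0.5, identically to an image and its mask. Fully determined
#' by `rng_seed`, so augmentation is reproducible.
#'
#' @param img HxW image matrix.
#' @param mask HxW binary mask matrix, same size.
#' @param rng_seed Integer seed for the flip draws.
#' @return List with `img`, `mask`, and the applied `flips`
#'   (named logical vector `h`, `v`).
#' @export
augment_pair <- function(img, mask, rng_seed) {
  if (!identical(dim(img), dim(mask))) {
    stop(sprintf("image is %s but mask is %s",
                 paste(dim(img), collapse = "x"),
                 paste(dim(mask), collapse = "x")), call. = FALSE)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(rng_seed)
  do_h <- runif(1) < 0.5
  do_v <- runif(1) < 0.5
  if (do_h) { img <- flip_h(img); mask <- flip_h(mask) }
  if (do_v) { img <- flip_v(img); mask <- flip_v(mask) }
  list(img = img, mask = mask, flips = c(h = do_h, v = do_v))
}

#' Full image-conditioning pipeline for one slice
#'
#' Normalization, optional CLAHE, optional Gaussian denoising, then zero-pad
#' to the canvas. Enhancement stages are independent switches; masks go
#' through [pad_to_canvas()] only.
#'
#' @param img Raw HxW slice.
#' @param target Canvas size `c(height, width)`.
#' @param use_clahe,use_denoise Enable the respective enhancement stage.
#' @param clip_limit,tiles,sigma Stage parameters, see [clahe_enhance()] and
#'   [gaussian_denoise()].
#' @return Padded, conditioned slice with crop-back metadata.
#' @export
preprocess_slice <- function(img, target = c(256L, 256L),
                             use_clahe = TRUE, use_denoise = TRUE,
                             clip_limit = 2, tiles = c(8L, 8L), sigma = 1) {
  out <- normalize_intensity(img)
  if (use_clahe) out <- clahe_enhance(out, clip_limit, tiles)
  if (use_denoise) out <- pmin(pmax(gaussian_denoise(out, sigma), 0), 1)
  pad_to_canvas(out, target)
}
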