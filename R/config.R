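#' Model configuration
#'
#' Builds the architectural configuration of the segmentation network. The
#' reference configuration is a five-level U-Net on 256x256 single-channel
#' input with widths 32, 64, 128, 256, 512, a 3x3-kernel spatial-attention
#' gate at the bottleneck and the inter-slice attention module enabled; the
#' four ablation variants (plain U-Net, +SA, +ISA, full dual-attention) are
#' one flag apart.
#'
#' @param input_height,input_width Input slice size in pixels; each must be
#'   divisible by `2^(depth - 1)` so the pooling schedule is exact.
#' @param input_channels Number of input channels (1 for grayscale MRI).
#' @param depth Number of encoder levels (the last one is the bottleneck).
#' @param base_channels Width of the first level; level `k` has
#'   `base_channels * 2^(k-1)` channels.
#' @param sa_enabled Enable the bottleneck spatial-attention gate.
#' @param sa_kernel Odd kernel size of the SA convolution, one of 1, 3, 5, 7.
#' @param isa_enabled Enable the inter-slice attention module.
#' @param isa_boundary_policy How to fill the missing neighbour at the first
#'   and last slice of a volume: `"replicate"` (neighbour := current slice)
#'   or `"zero"`.
#' @param upsample_mode `"transposed_conv"` (2x2 stride-2 transposed
#'   convolution, the default) or `"interp_plus_conv"` (nearest-neighbour
#'   upsampling followed by a 1x1 channel-mixing convolution).
#' @param seed Integer seed controlling weight initialization.
#'
#' @return An object of class `unet_config`.
#' @examples
#' cfg <- unet_config()
#' cfg$channel_schedule
#' @export
unet_config <- function(input_height = 256L, input_width = 256L,
                        input_channels = 1L, depth = 5L, base_channels = 32L,
                        sa_enabled = TRUE, sa_kernel = 3L,
                        isa_enabled = TRUE,
                        isa_boundary_policy = c("replicate", "zero"),
                        upsample_mode = c("transposed_conv",
                                          "interp_plus_conv"),
                        seed = 1L) {
  isa_boundary_policy <- match.arg(isa_boundary_policy)
  upsample_mode <- match.arg(upsample_mode)
  depth <- as.integer(depth)
  if (depth < 2L) stop("depth must be at least 2", call. = FALSE)
  div <- 2L^(depth - 1L)
  for (nm in c("input_height", "input_width")) {
    v <- get(nm)
    if (v %% div != 0L) {
      stop(sprintf("%s = %d is not divisible by 2^(depth-1) = %d",
                   nm, v, div), call. = FALSE)
    }
  }
  if (!sa_kernel %in% c(1L, 3L, 5L, 7L)) {
    stop("sa_kernel must be one of 1, 3, 5, 7", call. = FALSE)
  }
  structure(list(
    input_height = as.integer(input_height),
    input_width = as.integer(input_width),
    input_channels = as.integer(input_channels),
    depth = depth,
    base_channels = as.integer(base_channels),
    channel_schedule = as.integer(base_channels * 2^(seq_len(depth) - 1L)),
    sa_enabled = isTRUE(sa_enabled),
    sa_kernel = as.integer(sa_kernel),
    isa_enabled = isTRUE(isa_enabled),
    isa_boundary_policy = isa_boundary_policy,
    upsample_mode = upsample_mode,
    seed = as.integer(seed)
  ), class = "unet_config")
}

#' @export
print.unet_config <- function(x, ...) {
  cat("<unet_config>\n")
  cat(sprintf("  input: %dx%dx%d, depth %d, widths %s\n",
              x$input_height, x$input_width, x$input_channels, x$depth,
              paste(x$channel_schedule, collapse = "-")))
  cat(sprintf("  spatial attention: %s (kernel %dx%d)\n",
              if (x$sa_enabled) "on" else "off", x$sa_kernel, x$sa_kernel))
  cat(sprintf("  inter-slice attention: %s (boundary: %s)\n",
              if (x$isa_enabled) "on" else "off", x$isa_boundary_policy))
  cat(sprintf("  upsampling: %s, seed %d\n", x$upsample_mode, x$seed))
  invisible(x)
}

#' The four ablation variants
#'
#' Returns the configurations of the ablation lattice: the plain U-Net, the
#' U-Net with the spatial-attention gate, the U-Net with inter-slice
#' attention, and the full dual-attention network. All other settings are
#' shared, so the variants differ only in the two enable flags.
#'
#' @param ... Passed on to [unet_config()] (e.g. `input_height`,
#'   `base_channels`, `seed`).
#' @return Named list of four `unet_config` objects:
#'   `unet`, `unet_sa`, `unet_isa`, `dual`.
#' @export
ablation_variants <- function(...) {
  list(
    unet     = unet_config(..., sa_enabled = FALSE, isa_enabled = FALSE),
    unet_sa  = unet_config(..., sa_enabled = TRUE,  isa_enabled = FALSE),
    unet_isa = unet_config(..., sa_enabled = FALSE, isa_enabled = TRUE),
    dual     = unet_config(..., sa_enabled = TRUE,  isa_enabled = TRUE)
  )
}

validate_slice_input <- function(x, config) {
  d <- dim(x)
  if (is.null(d) || length(d) == 2L) d <- c(d %||% length(x), 1L)
  if (d[1] != config$input_height || d[2] != config$input_width) {
    stop(sprintf("input slice is %dx%d but the configuration expects %dx%d",
                 d[1], d[2], config$input_height, config$input_width),
         call. = FALSE)
  }
  if (!all(is.finite(x))) {
    stop("input slice contains non-finite values", call. = FALSE)
  }
  invisible(TRUE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
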