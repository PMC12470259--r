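# Synthetic hippocampus-like phantoms: volumes of axial slices whose
# central band contains a small bright crescent (difference of two offset
# discs — thin and concave, the geometry that makes hippocampus
# segmentation hard) drifting smoothly from slice to slice so adjacent
# masks overlap strongly and inter-slice attention has a real signal.
# Images get smooth tissue texture, a low-order multiplicative bias field
# and additive Gaussian noise; masks are the exact analytic crescent
# supports and are never perturbed.

#' Phantom generator parameters
#'
#' Defaults mirror the layout of a cross-sectional hippocampus MRI study:
#' 135 subjects of 189 axial 256x256 slices each, with a central band of 30
#' slices containing the structure. Sizes are in pixels, intensities on the
#' [0,1] scale.
#'
#' @param n_subjects Number of subjects.
#' @param slices_per_subject Slices per subject volume.
#' @param labeled_band Number of central slices carrying foreground.
#' @param image_size Slice size `c(height, width)`.
#' @param crescent_outer_radius Range (min,max) of the outer disc radius.
#' @param crescent_thickness Range (min,max) of the crescent thickness
#'   (offset of the cutting disc).
#' @param drift_per_slice Maximum centre displacement per slice step.
#' @param noise_sigma SD of additive Gaussian intensity noise.
#' @param bias_amplitude Relative amplitude of the smooth multiplicative
#'   bias field.
#' @param seed Master seed; per-subject seeds are derived from it.
#' @return Object of class `phantom_params`.
#' @export
phantom_params <- function(n_subjects = 135L, slices_per_subject = 189L,
                           labeled_band = 30L, image_size = c(256L, 256L),
                           crescent_outer_radius = c(18, 26),
                           crescent_thickness = c(5, 9),
                           drift_per_slice = 1,
                           noise_sigma = 0.05, bias_amplitude = 0.1,
                           seed = 1L) {
  if (labeled_band > slices_per_subject) {
    stop("labeled_band exceeds slices_per_subject", call. = FALSE)
  }
  if (any(crescent_outer_radius <= 0) || any(crescent_thickness <= 0) ||
      drift_per_slice < 0) {
    stop("radii and thickness must be positive and drift non-negative",
         call. = FALSE)
  }
  structure(list(
    n_subjects = as.integer(n_subjects),
    slices_per_subject = as.integer(slices_per_subject),
    labeled_band = as.integer(labeled_band),
    image_size = as.integer(image_size),
    crescent_outer_radius = crescent_outer_radius,
    crescent_thickness = crescent_thickness,
    drift_per_slice = drift_per_slice,
    noise_sigma = noise_sigma,
    bias_amplitude = bias_amplitude,
    seed = as.integer(seed)
  ), class = "phantom_params")
}

#' Subject volume container
#'
#' @param subject_id Identifier string.
#' @param slices List of HxW image matrices in stacking order.
#' @param masks List of HxW binary mask matrices, same order and sizes.
#' @param spacing Voxel spacing (arbitrary units).
#' @return Object of class `subject_volume`.
#' @export
subject_volume <- function(subject_id, slices, masks,
                           spacing = c(1, 1, 1)) {
  if (length(slices) != length(masks)) {
    stop("slices and masks differ in length", call. = FALSE)
  }
  for (i in seq_along(slices)) {
    if (!identical(dim(slices[[i]]), dim(masks[[i]]))) {
      stop(sprintf("slice %d: image and mask sizes differ", i),
           call. = FALSE)
    }
  }
  structure(list(subject_id = subject_id, slices = slices, masks = masks,
                 spacing = spacing), class = "subject_volume")
}

#' @export
print.subject_volume <- function(x, ...) {
  d <- dim(x$slices[[1]])
  cat(sprintf("<subject_volume> %s: %d slices of %dx%d, %d with foreground\n",
              x$subject_id, length(x$slices), d[1], d[2],
              sum(vapply(x$masks, function(m) any(m > 0), logical(1)))))
  invisible(x)
}

# analytic crescent support: inside the outer disc at `centre`, outside the
# equal-radius cutting disc offset by `thickness` along `theta`
crescent_mask <- function(h, w, centre, radius, thickness, theta) {
  yy <- matrix(seq_len(h), h, w)
  xx <- matrix(seq_len(w), h, w, byrow = TRUE)
  cut_c <- centre + thickness * c(cos(theta), sin(theta))
  outer_d2 <- (yy - centre[1])^2 + (xx - centre[2])^2
  cut_d2 <- (yy - cut_c[1])^2 + (xx - cut_c[2])^2
  (outer_d2 <= radius^2 & cut_d2 > radius^2) * 1
}

smooth_field <- function(h, w, n_terms = 3L) {
  yy <- matrix(seq_len(h) / h, h, w)
  xx <- matrix(seq_len(w) / w, h, w, byrow = TRUE)
  f <- matrix(0, h, w)
  for (i in seq_len(n_terms)) {
    f <- f + runif(1, 0.3, 1) *
      sin(2 * pi * (runif(1, 0.3, 1.2) * xx + runif(1, 0.3, 1.2) * yy +
                    runif(1)))
  }
  f / max(abs(f))
}

#' Generate one phantom subject
#'
#' @param params A [phantom_params()].
#' @param subject_seed Integer seed; the whole volume is a deterministic
#'   function of `params` and this seed.
#' @return A [subject_volume()] whose masks are the exact noiseless
#'   crescent supports.
#' @export
generate_subject <- function(params, subject_seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(subject_seed)
  h <- params$image_size[1]; w <- params$image_size[2]
  S <- params$slices_per_subject
  band <- params$labeled_band
  band_start <- (S - band) %/% 2L + 1L
  in_band <- seq(band_start, length.out = band)

  radius <- runif(1, params$crescent_outer_radius[1],
                  params$crescent_outer_radius[2])
  thickness <- runif(1, params$crescent_thickness[1],
                     params$crescent_thickness[2])
  theta <- runif(1, 0, 2 * pi)
  centre <- c(runif(1, 0.35, 0.65) * h, runif(1, 0.35, 0.65) * w)

  tissue <- 0.35 + 0.12 * smooth_field(h, w)
  bias <- 1 + params$bias_amplitude * smooth_field(h, w, 2L)

  slices <- vector("list", S)
  masks <- vector("list", S)
  for (i in seq_len(S)) {
    if (i %in% in_band) {
      m <- crescent_mask(h, w, centre, radius, thickness, theta)
      # smooth drift: displacement uniform in [0, drift_per_slice],
      # direction wanders slowly
      step <- runif(1, 0, params$drift_per_slice)
      dir <- runif(1, 0, 2 * pi)
      centre <- centre + step * c(cos(dir), sin(dir))
      theta <- theta + runif(1, -0.05, 0.05)
    } else {
      m <- matrix(0, h, w)
    }
    img <- tissue + 0.35 * m
    img <- img * bias +
      rnorm(h * w, sd = params$noise_sigma)
    slices[[i]] <- pmin(pmax(img, 0), 1)
    masks[[i]] <- m
  }
  subject_volume(sprintf("sub%04d", subject_seed %% 10000L), slices, masks)
}

subject_seeds_for <- function(params) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(params$seed)
  sample.int(.Machine$integer.max - 1L, params$n_subjects)
}

split_subjects <- function(ids, n_train, seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  train <- sample(ids, n_train)
  ifelse(ids %in% train, "train", "test")
}

#' Dataset manifest bookkeeping
#'
#' Builds the manifest (one row per slice: subject, slice index, paths,
#' split) for a phantom layout without materializing any pixel data, so the
#' bookkeeping of arbitrarily large layouts — e.g. 135 subjects x 189
#' slices split 100/35 into 18,900 training and 6,615 test images — is
#' instant. Splits are assigned per subject, never per slice.
#'
#' @param params A [phantom_params()].
#' @param n_train Number of training subjects (the rest are test).
#' @return Tibble with columns `subject_id`, `slice_index`, `image_path`,
#'   `mask_path`, `split`.
#' @export
dataset_manifest <- function(params, n_train) {
  if (n_train < 0L || n_train > params$n_subjects) {
    stop("n_train must be between 0 and n_subjects", call. = FALSE)
  }
  sub_ids <- sprintf("sub%03d", seq_len(params$n_subjects))
  split <- split_subjects(sub_ids, n_train, params$seed)
  S <- params$slices_per_subject
  tibble::tibble(
    subject_id = rep(sub_ids, each = S),
    slice_index = rep(seq_len(S) - 1L, times = params$n_subjects),
    image_path = sprintf("mem://%s/slice%03d_img",
                         rep(sub_ids, each = S),
                         rep(seq_len(S) - 1L, params$n_subjects)),
    mask_path = sprintf("mem://%s/slice%03d_mask",
                        rep(sub_ids, each = S),
                        rep(seq_len(S) - 1L, params$n_subjects)),
    split = rep(split, each = S)
  )
}

#' Generate a phantom dataset
#'
#' Materializes all subject volumes (deterministically from the master
#' seed), assigns a subject-level train/test split, and optionally writes
#' per-slice grayscale PNGs plus a manifest CSV under `dir`.
#'
#' @param params A [phantom_params()].
#' @param n_train Number of training subjects.
#' @param dir Output directory for PNG slices and `manifest.csv`; `NULL`
#'   (default) keeps the dataset in memory with virtual paths.
#' @return Object of class `phantom_dataset`: list with `params`,
#'   `volumes` (named by subject id) and `manifest` tibble.
#' @export
generate_dataset <- function(params, n_train, dir = NULL) {
  if (params$n_subjects < 1L) stop("need at least one subject", call. = FALSE)
  seeds <- subject_seeds_for(params)
  volumes <- vector("list", params$n_subjects)
  sub_ids <- sprintf("sub%03d", seq_len(params$n_subjects))
  for (s in seq_len(params$n_subjects)) {
    vol <- generate_subject(params, seeds[s])
    vol$subject_id <- sub_ids[s]
    volumes[[s]] <- vol
  }
  names(volumes) <- sub_ids
  manifest <- dataset_manifest(params, n_train)
  if (!is.null(dir)) {
    manifest <- write_dataset_png(volumes, manifest, dir)
  }
  structure(list(params = params, volumes = volumes, manifest = manifest),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf(
    "<phantom_dataset> %d subjects x %d slices (%dx%d), %d train / %d test rows\n",
    x$params$n_subjects, x$params$slices_per_subject,
    x$params$image_size[1], x$params$image_size[2],
    sum(x$manifest$split == "train"), sum(x$manifest$split == "test")))
  invisible(x)
}

#' The standard phantom benchmark fixture
#'
#' A fixed small benchmark used throughout the test suite: 20 subjects of
#' 12 slices at 64x64 with a 6-slice labeled band, seed 7, split 16
#' training / 4 test subjects. Regeneration is bit-identical across runs.
#'
#' @param dir Optional output directory (see [generate_dataset()]).
#' @return A `phantom_dataset`.
#' @export
fixture_benchmark <- function(dir = NULL) {
  params <- phantom_params(
    n_subjects = 20L, slices_per_subject = 12L, labeled_band = 6L,
    image_size = c(64L, 64L),
    crescent_outer_radius = c(10, 12), crescent_thickness = c(3.5, 4.5),
    drift_per_slice = 0.8, noise_sigma = 0.05, bias_amplitude = 0.1,
    seed = 7L)
  generate_dataset(params, n_train = 16L, dir = dir)
}
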