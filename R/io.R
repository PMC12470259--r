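# Volume and manifest I/O. Axial slices run along the third array axis;
# slice indices are 0-based in manifests (internally R lists are 1-based).
# Mask files may encode foreground as any positive value (e.g. 255); they
# are mapped to strict {0,1} on load with a message.

#' Read / write a subject volume as NIfTI
#'
#' `write_volume()` stores the image stack and the mask stack as two NIfTI
#' files; `read_volume()` restores them (intensities widened to double).
#' Reading then writing reproduces the data arrays exactly.
#'
#' @param volume A [subject_volume()].
#' @param image_path,mask_path Paths to the image and mask `.nii`/`.nii.gz`
#'   files (mask optional on read).
#' @param subject_id Subject identifier for the restored volume.
#' @return `write_volume` returns the paths invisibly; `read_volume`
#'   returns a `subject_volume`.
#' @export
write_volume <- function(volume, image_path, mask_path = NULL) {
  arr <- simplify2array(volume$slices)
  RNifti::writeNifti(RNifti::asNifti(arr), image_path)
  if (!is.null(mask_path)) {
    RNifti::writeNifti(RNifti::asNifti(simplify2array(volume$masks)),
                       mask_path)
  }
  invisible(c(image_path, mask_path))
}

#' @rdname write_volume
#' @export
read_volume <- function(image_path, mask_path = NULL,
                        subject_id = sub("\\.nii(\\.gz)?$", "",
                                         basename(image_path))) {
  if (!file.exists(image_path)) {
    stop("volume file not found: ", image_path, call. = FALSE)
  }
  nii <- RNifti::readNifti(image_path)
  arr <- array(as.numeric(nii), dim = dim(nii))
  if (length(dim(arr)) == 2L) dim(arr) <- c(dim(arr), 1L)
  slices <- lapply(seq_len(dim(arr)[3]), function(i) arr[, , i])
  masks <- NULL
  if (!is.null(mask_path)) {
    if (!file.exists(mask_path)) {
      stop("mask file not found: ", mask_path, call. = FALSE)
    }
    mnii <- RNifti::readNifti(mask_path)
    marr <- array(as.numeric(mnii), dim = dim(mnii))
    if (length(dim(marr)) == 2L) dim(marr) <- c(dim(marr), 1L)
    if (!identical(dim(marr), dim(arr))) {
      stop(sprintf("%s is %s but %s is %s", image_path,
                   paste(dim(arr), collapse = "x"), mask_path,
                   paste(dim(marr), collapse = "x")), call. = FALSE)
    }
    masks <- lapply(seq_len(dim(marr)[3]),
                    function(i) coerce_mask(marr[, , i], mask_path))
  } else {
    masks <- lapply(slices, function(s) matrix(0, nrow(s), ncol(s)))
  }
  subject_volume(subject_id, slices, masks)
}

# map {0, anything>0} to {0,1}; more than two distinct values is an error
coerce_mask <- function(m, path) {
  vals <- unique(as.vector(m))
  if (length(vals) > 2L) {
    stop(sprintf("mask %s has %d distinct values; expected a binary mask",
                 path, length(vals)), call. = FALSE)
  }
  if (!all(vals %in% c(0, 1))) {
    message(sprintf("mask %s: mapping values {%s} to {0,1}", path,
                    paste(sort(vals), collapse = ", ")))
  }
  (m > 0) * 1
}

#' Write a dataset as per-slice PNGs plus a manifest
#'
#' One grayscale PNG per image slice and one per mask, laid out as
#' `<dir>/<subject>/slice<idx>_{img,mask}.png`, with `manifest.csv`
#' recording the pairing and the subject-level split.
#'
#' @param volumes Named list of [subject_volume()]s.
#' @param manifest Manifest tibble (see [dataset_manifest()]).
#' @param dir Output directory.
#' @return The manifest with real file paths, invisibly written to
#'   `<dir>/manifest.csv`.
#' @export
write_dataset_png <- function(volumes, manifest, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir, call. = FALSE)
  manifest$image_path <- file.path(dir, manifest$subject_id,
                                   sprintf("slice%03d_img.png",
                                           manifest$slice_index))
  manifest$mask_path <- file.path(dir, manifest$subject_id,
                                  sprintf("slice%03d_mask.png",
                                          manifest$slice_index))
  for (sid in names(volumes)) {
    sdir <- file.path(dir, sid)
    dir.create(sdir, showWarnings = FALSE)
    vol <- volumes[[sid]]
    for (i in seq_along(vol$slices)) {
      png::writePNG(pmin(pmax(vol$slices[[i]], 0), 1),
                    file.path(sdir, sprintf("slice%03d_img.png", i - 1L)))
      png::writePNG(vol$masks[[i]],
                    file.path(sdir, sprintf("slice%03d_mask.png", i - 1L)))
    }
  }
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  manifest
}

#' Read a PNG-slice subject directory back into a volume
#'
#' @param manifest Manifest tibble with real paths.
#' @param subject_id Which subject to load.
#' @return A [subject_volume()].
#' @export
read_subject_png <- function(manifest, subject_id) {
  rows <- manifest[manifest$subject_id == subject_id, ]
  if (nrow(rows) == 0L) {
    stop("subject not in manifest: ", subject_id, call. = FALSE)
  }
  rows <- rows[order(rows$slice_index), ]
  slices <- lapply(rows$image_path, function(p) {
    m <- png::readPNG(p)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    m
  })
  masks <- lapply(rows$mask_path, function(p) {
    m <- png::readPNG(p)
    if (length(dim(m)) == 3L) m <- m[, , 1]
    coerce_mask(m, p)
  })
  subject_volume(subject_id, slices, masks)
}

#' Read / write a manifest table
#'
#' @param manifest Manifest tibble.
#' @param path CSV path.
#' @return `read_manifest` returns the tibble (validating that splits are
#'   subject-disjoint); `write_manifest` returns `path` invisibly.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  check_subject_disjoint(m)
  m
}

check_subject_disjoint <- function(manifest) {
  per <- tapply(manifest$split, manifest$subject_id,
                function(s) length(unique(s)))
  if (any(per > 1L)) {
    bad <- names(per)[per > 1L]
    stop("subjects assigned to multiple splits: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Build a manifest by scanning a slice directory tree
#'
#' Discovers `slice*_img.png` / `slice*_mask.png` pairs under
#' `root/<subject>/`, errors on orphans, and assigns a subject-level split:
#' either a count of training subjects (seeded subject shuffle) or explicit
#' id lists, which take precedence.
#'
#' @param root Dataset root directory.
#' @param split_spec Either `list(n_train = <int>, seed = <int>)` or
#'   `list(train_ids = <chr>, test_ids = <chr>)`.
#' @return Manifest tibble.
#' @export
build_manifest <- function(root, split_spec = list(n_train = 0L, seed = 1L)) {
  subjects <- sort(list.dirs(root, recursive = FALSE, full.names = FALSE))
  if (length(subjects) == 0L) stop("no subject directories under ", root,
                                   call. = FALSE)
  rows <- lapply(subjects, function(sid) {
    files <- list.files(file.path(root, sid), pattern = "^slice.*\\.png$")
    imgs <- sort(grep("_img\\.png$", files, value = TRUE))
    msks <- sort(grep("_mask\\.png$", files, value = TRUE))
    stem <- function(x, suf) sub(suf, "", x)
    orphans <- c(setdiff(stem(imgs, "_img\\.png$"), stem(msks, "_mask\\.png$")),
                 setdiff(stem(msks, "_mask\\.png$"), stem(imgs, "_img\\.png$")))
    if (length(orphans) > 0L) {
      stop(sprintf("unpaired slice files for %s: %s", sid,
                   paste(orphans, collapse = ", ")), call. = FALSE)
    }
    idx <- as.integer(sub("^slice0*([0-9]+)_img\\.png$", "\\1", imgs))
    tibble::tibble(subject_id = sid, slice_index = idx,
                   image_path = file.path(root, sid, imgs),
                   mask_path = file.path(root, sid, msks))
  })
  m <- do.call(rbind, rows)
  if (!is.null(split_spec$train_ids)) {
    m$split <- ifelse(m$subject_id %in% split_spec$train_ids, "train",
                      ifelse(m$subject_id %in% (split_spec$test_ids %||%
                                                  character()),
                             "test", "none"))
  } else {
    split <- split_subjects(subjects, split_spec$n_train,
                            split_spec$seed %||% 1L)
    m$split <- split[match(m$subject_id, subjects)]
  }
  check_subject_disjoint(m)
  m
}
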