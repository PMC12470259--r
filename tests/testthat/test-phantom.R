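# Synthetic phantom generator: geometry, determinism, bookkeeping.

test_that("masks exist only in the labeled band and are exactly binary", {
  params <- phantom_params(n_subjects = 1L, slices_per_subject = 10L,
                           labeled_band = 4L, image_size = c(48L, 48L),
                           crescent_outer_radius = c(8, 10),
                           crescent_thickness = c(3, 4), seed = 5L)
  vol <- generate_subject(params, 123L)
  nonempty <- which(vapply(vol$masks, function(m) any(m > 0), logical(1)))
  expect_length(nonempty, 4L)
  expect_equal(nonempty, seq(min(nonempty), length.out = 4L))  # contiguous
  expect_true(all(vapply(vol$masks,
                         function(m) all(m %in% c(0, 1)), logical(1))))
  expect_true(all(vapply(vol$slices,
                         function(s) all(s >= 0 & s <= 1), logical(1))))
  expect_error(phantom_params(slices_per_subject = 5L, labeled_band = 10L),
               "labeled_band")
})

test_that("volumes are bit-identical under the same subject seed", {
  params <- phantom_params(n_subjects = 1L, slices_per_subject = 6L,
                           labeled_band = 3L, image_size = c(32L, 32L),
                           crescent_outer_radius = c(6, 8),
                           crescent_thickness = c(2, 3), seed = 1L)
  v1 <- generate_subject(params, 99L)
  v2 <- generate_subject(params, 99L)
  expect_identical(v1$slices, v2$slices)
  expect_identical(v1$masks, v2$masks)
  v3 <- generate_subject(params, 100L)
  expect_false(identical(v1$slices, v3$slices))
})

test_that("adjacent in-band masks overlap strongly under small drift", {
  # brute-force overlap of the analytic supports: drift <= 1 px and outer
  # radius >= 10 px must keep neighbouring dice at or above 0.7
  params <- phantom_params(n_subjects = 1L, slices_per_subject = 12L,
                           labeled_band = 8L, image_size = c(64L, 64L),
                           crescent_outer_radius = c(10, 12),
                           crescent_thickness = c(3.5, 4.5),
                           drift_per_slice = 1, seed = 2L)
  for (s in c(13L, 29L, 57L)) {
    vol <- generate_subject(params, s)
    idx <- which(vapply(vol$masks, function(m) any(m > 0), logical(1)))
    for (i in head(idx, -1)) {
      ov <- oracle_overlap_metrics(vol$masks[[i]], vol$masks[[i + 1]])
      expect_gte(ov$dice, 0.7)
    }
  }
})

test_that("the standard fixture has the pinned layout and composition", {
  ds <- fixture_benchmark()
  expect_equal(nrow(ds$manifest), 240L)  # 20 subjects x 12 slices
  expect_length(ds$volumes, 20L)
  expect_equal(length(unique(ds$manifest$subject_id[ds$manifest$split ==
                                                      "train"])), 16L)
  # regeneration is bit-identical
  ds2 <- fixture_benchmark()
  expect_identical(ds$volumes, ds2$volumes)
  expect_identical(ds$manifest, ds2$manifest)
  # foreground occupies 1-15% of in-band pixels (small-structure regime)
  for (vol in ds$volumes) {
    idx <- which(vapply(vol$masks, function(m) any(m > 0), logical(1)))
    expect_length(idx, 6L)
    frac <- vapply(vol$masks[idx], mean, numeric(1))
    expect_true(all(frac >= 0.01 & frac <= 0.15))
  }
})

test_that("manifest bookkeeping mirrors subject-level splits", {
  params <- phantom_params(n_subjects = 6L, slices_per_subject = 5L,
                           labeled_band = 3L, seed = 9L)
  man <- dataset_manifest(params, n_train = 4L)
  expect_equal(nrow(man), 30L)
  expect_equal(sum(man$split == "train"), 20L)
  per <- tapply(man$split, man$subject_id, function(s) length(unique(s)))
  expect_true(all(per == 1L))  # no subject in both splits
  expect_error(dataset_manifest(params, n_train = 7L), "n_train")
})

test_that("generate_dataset is reproducible and split-consistent", {
  ds <- tiny_phantom(n_subjects = 3L, seed = 21L)
  ds2 <- tiny_phantom(n_subjects = 3L, seed = 21L)
  expect_identical(ds$volumes, ds2$volumes)
  expect_equal(nrow(ds$manifest), 18L)
  expect_setequal(unique(ds$manifest$split), c("train", "test"))
})
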