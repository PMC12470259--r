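# Spatial and inter-slice attention: oracle equivalence on toy tensors,
# bound contracts, and the parameter-count lattice.

test_that("spatial attention matches the brute-force oracle on toy maps", {
  set.seed(101)
  for (k in c(1L, 3L)) {
    feature <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
    W <- array(rnorm(k * k * 2), c(k, k, 2, 1))
    b <- rnorm(1)
    got <- spatial_attention(feature, W, b)
    ref <- oracle_sa(feature, W, b)
    expect_equal(got$attention, ref$attention, tolerance = 1e-12)
    expect_equal(got$out, ref$out, tolerance = 1e-12)
  }
  # larger map, more channels
  feature <- array(rnorm(8 * 8 * 5), c(8, 8, 5))
  W <- array(rnorm(9 * 2), c(3, 3, 2, 1))
  got <- spatial_attention(feature, W, 0.3)
  ref <- oracle_sa(feature, W, 0.3)
  expect_equal(got$out, ref$out, tolerance = 1e-12)
})

test_that("attention values are strictly inside (0,1) and shrink magnitudes", {
  set.seed(102)
  feature <- array(rnorm(6 * 6 * 3, sd = 10), c(6, 6, 3))
  W <- array(rnorm(18, sd = 5), c(3, 3, 2, 1))
  got <- spatial_attention(feature, W)
  expect_true(all(got$attention > 0 & got$attention < 1))
  expect_true(all(abs(got$out) < abs(feature) | feature == 0))
  expect_equal(dim(got$out), dim(feature))
})

test_that("spatial attention validates kernel size against the map", {
  feature <- array(rnorm(8), c(2, 2, 2))
  expect_error(spatial_attention(feature, array(0, c(2, 2, 2, 1))), "odd")
  expect_error(spatial_attention(feature, array(0, c(3, 3, 2, 1))),
               "smaller than")
})

test_that("inter-slice attention matches its composed brute-force oracle", {
  set.seed(103)
  prev <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  curr <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  nxt <- array(rnorm(4 * 4 * 2), c(4, 4, 2))
  W <- array(rnorm(18), c(3, 3, 2, 1))
  b <- 0.1
  got <- inter_slice_attention(prev, curr, nxt, W, b)
  ref <- oracle_isa(prev, curr, nxt, W, b)
  expect_equal(got$out, ref$out, tolerance = 1e-12)
  expect_equal(got$m_prev, ref$m_prev, tolerance = 1e-12)
  expect_equal(got$m_next, ref$m_next, tolerance = 1e-12)
  expect_equal(dim(got$out), dim(curr))
  expect_true(all(got$m_prev > 0 & got$m_prev < 1))
})

test_that("identical neighbours give identical masks and a doubled gate", {
  set.seed(104)
  edge <- array(rnorm(32), c(4, 4, 2))
  curr <- array(rnorm(32), c(4, 4, 2))
  W <- array(rnorm(18), c(3, 3, 2, 1))
  got <- inter_slice_attention(edge, curr, edge, W)
  expect_identical(got$m_prev, got$m_next)
  gated <- curr
  for (c in 1:2) gated[, , c] <- 2 * curr[, , c] * got$m_prev
  expect_equal(got$out, gated, tolerance = 1e-12)
})

test_that("inter-slice attention rejects mismatched triplets", {
  a <- array(0, c(4, 4, 2))
  b <- array(0, c(4, 4, 3))
  expect_error(inter_slice_attention(a, a, b, array(0, c(3, 3, 2, 1))),
               "triplet")
})

test_that("parameter count matches an independent per-layer tally", {
  # depth 3, base 4, single-channel 32x32 input, SA+ISA on: tallied by hand
  # as sum over convolutions of k*k*cin*cout + cout
  cfg <- unet_config(input_height = 32L, input_width = 32L, depth = 3L,
                     base_channels = 4L)
  hand <- (3 * 3 * 1 * 4 + 4) + (3 * 3 * 4 * 4 + 4) +      # enc level 1
    (3 * 3 * 4 * 8 + 8) + (3 * 3 * 8 * 8 + 8) +            # enc level 2
    (3 * 3 * 8 * 16 + 16) + (3 * 3 * 16 * 16 + 16) +       # bottleneck
    (3 * 3 * 2 * 1 + 1) +                                  # SA conv
    (2 * 2 * 16 * 8 + 8) + (3 * 3 * 16 * 8 + 8) + (3 * 3 * 8 * 8 + 8) +
    (2 * 2 * 8 * 4 + 4) + (3 * 3 * 8 * 4 + 4) + (3 * 3 * 4 * 4 + 4) +
    (3 * 3 * 2 * 1 + 1) +                                  # ISA conv
    (1 * 1 * 4 * 1 + 1)                                    # head
  expect_equal(count_parameters(cfg), hand)
  expect_equal(sum(parameter_table(cfg)$params), hand)
})

test_that("parameter counts respect the ablation lattice and monotonicity", {
  v <- ablation_variants()
  counts <- vapply(v, count_parameters, numeric(1))
  expect_lt(counts["unet"], counts["unet_sa"])
  expect_lte(counts["unet_sa"], counts["dual"])
  expect_lt(counts["unet"], counts["unet_isa"])
  expect_lte(counts["unet_isa"], counts["dual"])
  expect_lt(count_parameters(unet_config(base_channels = 32L)),
            count_parameters(unet_config(base_channels = 64L)))
})

test_that("initialized weights agree in number with the configured count", {
  cfg <- unet_config(input_height = 32L, input_width = 32L,
                     base_channels = 4L, seed = 20L)
  model <- build_model(cfg)
  expect_equal(sum(vapply(model$weights, length, numeric(1))),
               count_parameters(cfg))
  # builds are reproducible from the seed
  expect_identical(model$weights, build_model(cfg)$weights)
})
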