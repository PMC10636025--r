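test_that("mask volume is count times voxel volume in cm^3", {
  m <- array(FALSE, c(10, 10, 10))
  m[seq_len(1000)] <- TRUE
  expect_equal(compute_volume(m, c(1, 1, 1)), 1.000)
  expect_equal(compute_volume(array(FALSE, c(5, 5, 5)), c(1, 1, 1)), 0)
  m2 <- array(FALSE, c(10, 10, 10))
  m2[seq_len(500)] <- TRUE
  expect_equal(compute_volume(m2, c(2, 2, 2)), 4.000)
})

test_that("volumetric grading follows the half-open severity bands", {
  r <- volumetric_grade(1400, 1000)
  expect_equal(r$ct_diff_percent, 40)
  expect_equal(r$severity_grade, 4)
  expect_equal(volumetric_grade(1000, 1000)$severity_grade, 0)
  r2 <- volumetric_grade(1195, 1000)
  expect_equal(r2$ct_diff_percent, 19.5)
  expect_equal(r2$severity_grade, 1)
  expect_warning(neg <- volumetric_grade(900, 1000), "smaller")
  expect_equal(neg$severity_grade, 0)
  expect_error(volumetric_grade(1000, 0), "positive")
  expect_error(volumetric_grade(1000, -5), "positive")
})

test_that("HP windowing matches an exhaustive voxel-scan oracle", {
  set.seed(42)
  d <- c(16, 16, 16)
  hu <- array(runif(prod(d), -200, 200), d)
  sc <- array(runif(prod(d)) < 0.6, d)
  ct <- image_volume(hu, c(2, 2, 2), "CT")
  res <- hp_ratio(ct, sc)

  oracle <- array(FALSE, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3])
    oracle[i, j, k] <- sc[i, j, k] && hu[i, j, k] >= -60 && hu[i, j, k] <= 10
  expect_identical(res$hp_mask, oracle)
  expect_equal(res$hp_ratio, sum(oracle) / sum(sc))
})

test_that("degenerate SC compositions give ratio 0 and 1; empty SC errors", {
  d <- c(6, 6, 6)
  sc <- array(TRUE, d)
  ct0 <- image_volume(array(-100, d), c(1, 1, 1), "CT")
  expect_equal(hp_ratio(ct0, sc)$hp_ratio, 0)
  ct1 <- image_volume(array(0, d), c(1, 1, 1), "CT")
  expect_equal(hp_ratio(ct1, sc)$hp_ratio, 1)
  expect_error(hp_ratio(ct1, array(FALSE, d)), "empty")
})

test_that("recovered HP ratio is monotone in the generator target", {
  targets <- c(0, 0.1, 0.2, 0.3, 0.4, 0.5)
  got <- vapply(seq_along(targets), function(i) {
    spec <- small_phantom_spec(hp_fraction = c(targets[i], targets[i]),
                               ct_noise_sd = 0, seed = 100 + i)
    ph <- generate_phantom(spec)
    limb <- segment_limb(ph$ct)
    comp <- segment_compartments(ph$ct, limb)
    hp_ratio(ph$ct, comp$subcutaneous)$hp_ratio
  }, numeric(1))
  expect_true(all(diff(got) >= 0))
  expect_lt(max(abs(got - targets)), 0.03)
})

test_that("limb region growing recovers the phantom limb exactly", {
  ph <- generate_phantom(small_phantom_spec(ct_noise_sd = 0, seed = 21))
  limb <- segment_limb(ph$ct)
  expect_gte(dice(limb, ph$truth$masks$limb), 0.99)
  lab <- label_components(limb)
  expect_equal(attr(lab, "n_components"), 1L) # one connected component
  expect_error(segment_limb(ph$ct, seed_point = c(1, 1, 1)), "air")
})

test_that("compartment segmentation recovers SC and honours subtraction", {
  ph <- generate_phantom(small_phantom_spec(seed = 22))
  limb <- segment_limb(ph$ct)
  comp <- segment_compartments(ph$ct, limb)
  expect_gte(dice(comp$subcutaneous, ph$truth$masks$subcutaneous), 0.95)
  expect_identical(comp$subcutaneous,
                   comp$limb & !(comp$bone | comp$muscle))
  expect_error(segment_compartments(ph$ct, array(FALSE, dim(ph$ct$voxels))),
               "empty")
})

test_that("without bone or muscle the SC compartment is the whole limb", {
  ct <- fat_cylinder_ct()
  limb <- segment_limb(ct, seed_point = c(12, 12, 12))
  comp <- segment_compartments(ct, limb)
  expect_identical(comp$subcutaneous, limb)
  expect_false(any(comp$bone))
  expect_false(any(comp$muscle))
})
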