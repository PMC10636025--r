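# Plain-R flood fill used as the independent oracle for the iso-contour
# growth (6-connectivity, breadth-first over an explicit queue).
flood_fill_r <- function(cand, seed) {
  d <- dim(cand)
  out <- array(FALSE, d)
  if (!cand[seed[1], seed[2], seed[3]]) return(out)
  queue <- matrix(seed, ncol = 3)
  out[seed[1], seed[2], seed[3]] <- TRUE
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  while (nrow(queue)) {
    v <- queue[1, ]
    queue <- queue[-1, , drop = FALSE]
    for (o in seq_len(6)) {
      w <- v + offs[o, ]
      if (any(w < 1) || any(w > d)) next
      if (cand[w[1], w[2], w[3]] && !out[w[1], w[2], w[3]]) {
        out[w[1], w[2], w[3]] <- TRUE
        queue <- rbind(queue, w)
      }
    }
  }
  out
}

iso_oracle <- function(act, seed, iso) {
  m <- act[seed[1], seed[2], seed[3]]
  repeat {
    comp <- flood_fill_r(act >= iso * m, seed)
    m2 <- max(act[comp])
    if (m2 <= m) break
    m <- m2
  }
  comp
}

# A smooth non-negative activity field with peaks at the given voxel
# centres.
blob_field <- function(d, centres, heights, width = 2.5) {
  act <- array(0, d)
  for (i in 1:d[1]) for (j in 1:d[2]) for (k in 1:d[3]) {
    for (b in seq_along(heights)) {
      r2 <- sum((c(i, j, k) - centres[[b]])^2)
      act[i, j, k] <- act[i, j, k] + heights[b] * exp(-r2 / (2 * width^2))
    }
  }
  act
}

raw_dbf_cfg <- function(...) {
  dbf_config(seed_gate_median_factor = 0, seed_gate_fraction = 0,
             min_volume_cm3 = 0, ...)
}

test_that("iso-contour growth equals the exhaustive flood-fill oracle", {
  d <- c(12, 12, 12)
  act <- blob_field(d, list(c(4, 4, 4), c(9, 9, 9)), c(100, 60))
  spect <- image_volume(act, c(2, 2, 2), "SPECT")
  sc <- array(TRUE, d)
  for (iso in c(0.1, 0.3, 0.6)) {
    got <- extract_dbf(spect, seed_points = c(5, 4, 4), sc_mask = sc,
                       cfg = raw_dbf_cfg(iso_fraction = iso))
    want <- iso_oracle(act, c(5, 4, 4), iso)
    expect_identical(as.vector(got), as.vector(want))
  }
})

test_that("raising the iso fraction never enlarges the VOI", {
  d <- c(14, 14, 14)
  act <- blob_field(d, list(c(7, 7, 7)), 50, width = 3)
  spect <- image_volume(act, c(2, 2, 2), "SPECT")
  sc <- array(TRUE, d)
  prev <- NULL
  for (iso in c(0.05, 0.1, 0.2, 0.4, 0.8)) {
    m <- extract_dbf(spect, seed_points = c(7, 7, 7), sc_mask = sc,
                     cfg = raw_dbf_cfg(iso_fraction = iso))
    if (!is.null(prev)) expect_false(any(m & !prev)) # nested
    prev <- m
  }
})

test_that("DBF ratio arithmetic and scale invariance", {
  expect_equal(dbf_ratio(array(FALSE, c(10, 10, 10)), 500,
                         c(2, 2, 2))$dbf_ratio, 0)
  m <- array(FALSE, c(20, 20, 20))
  m[seq_len(6250)] <- TRUE # 6250 * 8 mm^3 = 50 cm^3
  expect_equal(dbf_ratio(m, 500, c(2, 2, 2))$dbf_ratio, 0.10)
  expect_error(dbf_ratio(m, 0, c(2, 2, 2)), "positive")

  # doubling the spacing scales DBF and SC volumes together: ratio fixed
  sc_vol1 <- compute_volume(array(TRUE, c(20, 20, 20)), c(1, 1, 1))
  sc_vol2 <- compute_volume(array(TRUE, c(20, 20, 20)), c(2, 2, 2))
  r1 <- dbf_ratio(m, sc_vol1, c(1, 1, 1))$dbf_ratio
  r2 <- dbf_ratio(m, sc_vol2, c(2, 2, 2))$dbf_ratio
  expect_equal(r1, r2)
})

test_that("extent calls follow per-region presence at the minimum volume", {
  d <- c(10, 10, 20)
  regs <- region_masks(array(TRUE, d), 0.5)
  mk <- function(z_range, nvox = 400) {
    m <- array(FALSE, d)
    m[, , z_range][seq_len(nvox)] <- TRUE
    m
  }
  sp <- c(2, 2, 2)
  expect_equal(dbf_extent(mk(15:18), regs, sp)$extent, "distal")
  expect_equal(dbf_extent(mk(2:5), regs, sp)$extent, "proximal")
  both <- mk(2:5) | mk(15:18)
  expect_equal(dbf_extent(both, regs, sp)$extent, "entire")
  expect_equal(dbf_extent(array(FALSE, d), regs, sp)$extent, "none")
  # sub-threshold volume in a region does not count as presence
  tiny <- array(FALSE, d); tiny[1:5, 1, 19] <- TRUE # 5 voxels = 0.04 cm^3
  expect_equal(dbf_extent(tiny, regs, sp)$extent, "none")
  overlapping <- list(proximal = regs$proximal, distal = regs$proximal)
  expect_error(dbf_extent(both, overlapping, sp), "overlap")
})

test_that("hotspots inside the exclusion mask contribute nothing", {
  d <- c(12, 12, 12)
  act <- blob_field(d, list(c(6, 6, 6)), 80)
  spect <- image_volume(act, c(2, 2, 2), "SPECT")
  sc <- array(TRUE, d)
  excl <- array(FALSE, d)
  excl[2:11, 2:11, 2:11] <- TRUE
  got <- extract_dbf(spect, seed_points = NULL, sc_mask = sc,
                     cfg = dbf_config(), exclusion_mask = excl)
  expect_false(any(got))
  expect_equal(nrow(attr(got, "seeds")), 0)
})

test_that("manual seeds below the background gate are rejected", {
  ph <- generate_phantom(small_phantom_spec(dbf = c(FALSE, TRUE), seed = 8))
  limb <- segment_limb(ph$ct)
  comp <- segment_compartments(ph$ct, limb)
  # a corner voxel outside the limb has essentially zero counts
  expect_error(
    extract_dbf(ph$spect, seed_points = c(1, 1, 1),
                sc_mask = comp$subcutaneous,
                exclusion_mask = ph$truth$exclusion_mask),
    "gate")
})

test_that("a distal dermal rim is recovered with high overlap", {
  spec <- phantom_spec(dbf = c(proximal = FALSE, distal = TRUE), seed = 31)
  ph <- generate_phantom(spec)
  limb <- segment_limb(ph$ct)
  comp <- segment_compartments(ph$ct, limb)
  dbf <- extract_dbf(ph$spect, NULL, comp$subcutaneous,
                     exclusion_mask = ph$truth$exclusion_mask)
  expect_gte(dice(dbf, ph$truth$dbf_mask), 0.80)
  regs <- region_masks(comp$subcutaneous)
  expect_equal(dbf_extent(dbf, regs, ph$spect$spacing)$extent, "distal")
})

test_that("a phantom without DBF yields an empty VOI under auto-seeding", {
  ph <- generate_phantom(small_phantom_spec(seed = 14))
  limb <- segment_limb(ph$ct)
  comp <- segment_compartments(ph$ct, limb)
  dbf <- extract_dbf(ph$spect, NULL, comp$subcutaneous,
                     exclusion_mask = ph$truth$exclusion_mask)
  expect_false(any(dbf))
  regs <- region_masks(comp$subcutaneous)
  expect_equal(dbf_extent(dbf, regs, ph$spect$spacing)$extent, "none")
})
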