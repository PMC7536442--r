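test_that("isodata threshold matches the brute-force oracle", {
  set.seed(21)
  for (rep in 1:5) {
    img <- matrix(c(rnorm(300, 10, 2), rnorm(100, 40, 4)), 20, 20)
    tm <- threshold_mask(img)
    oracle_t <- isodata_oracle(img)
    bin_w <- diff(range(img)) / 256
    expect_lt(abs(tm$threshold - oracle_t), 2 * bin_w)
    # the masks may only disagree within a bin width of the threshold
    disagree <- tm$mask != (img > oracle_t)
    expect_true(all(abs(img[disagree] - oracle_t) < 2 * bin_w))
  }
  expect_error(threshold_mask(matrix(1, 4, 4)), "constant")
})

test_that("isodata is invariant under positive affine rescaling", {
  set.seed(22)
  img <- matrix(c(rnorm(200, 5, 1), rnorm(56, 20, 2)), 16, 16)
  m1 <- threshold_mask(img)
  m2 <- threshold_mask(img * 37.5 + 12)
  expect_equal(m1$mask, m2$mask)
})

test_that("resample_mask applies the block coverage rule", {
  fine <- matrix(FALSE, 4, 4)
  fine[1:2, 1:2] <- TRUE              # block (1,1): coverage 1
  fine[1, 3] <- TRUE                  # block (1,2): coverage 0.25
  fine[3:4, 3] <- TRUE                # block (2,2): coverage 0.5
  bm <- binary_mask(fine, pitch_um = 30)
  out <- resample_mask(bm, source_pitch_um = 30, target_pitch_um = 60,
                       coverage = 0.5)
  expect_equal(dim(out$mask), c(2, 2))
  expect_true(out$mask[1, 1])
  expect_false(out$mask[1, 2])        # 0.25 < 0.5
  expect_true(out$mask[2, 2])         # 0.5 >= 0.5
  expect_false(out$mask[2, 1])
  strict <- resample_mask(bm, 30, 60, coverage = 0.75)
  expect_false(strict$mask[2, 2])
  expect_error(resample_mask(bm, 30, 45, 0.5))
})

test_that("overlap_stats reproduces hand-computed toy values", {
  # 4x4 toy: reference mask covers the left half; ion intensity 2 on a
  # 2x2 square straddling the boundary
  ion <- matrix(0, 4, 4)
  ion[2:3, 2:3] <- 2
  ion[1, 1] <- 1e-6   # break constancy outside the square
  ref <- binary_mask(matrix(rep(c(TRUE, FALSE), each = 8), 4, 4))
  st <- overlap_stats(ion, ref)
  expect_s3_class(st, "coloc_stats")
  # M1: ion mass inside reference / total ion mass = (2*2)/(2*4) (up to the
  # tie-break pixel)
  expect_equal(st$m1, (2 * 2 + 1e-6) / (2 * 4 + 1e-6), tolerance = 1e-9)
  expect_gte(st$m2, 0); expect_lte(st$m2, 1)
  expect_gte(st$dice, 0); expect_lte(st$dice, 1)
  expect_error(overlap_stats(matrix(1, 4, 4), ref), "constant")
  expect_error(overlap_stats(ion, ref, matrix(FALSE, 4, 4)), "tissue")
})

test_that("band_depth separates a central band from a rim band", {
  # disk reference with an ion band at its centre vs at its rim
  n <- 41
  yy <- row(matrix(0, n, n)); xx <- col(matrix(0, n, n))
  r <- sqrt((yy - 21)^2 + (xx - 21)^2)
  ref <- binary_mask(r <= 15)
  central <- binary_mask(r <= 4)
  rim <- binary_mask(r <= 15 & r >= 13)
  bd_c <- band_depth(central, ref)
  bd_r <- band_depth(rim, ref)
  expect_gt(bd_c$median_depth, 0.7)
  expect_lt(bd_r$median_depth, 0.25)
  expect_equal(bd_c$fraction_outside, 0)
  # depth is normalized to [0, 1]
  expect_true(all(bd_c$depths >= 0 & bd_c$depths <= 1))
  expect_error(band_depth(central, binary_mask(matrix(FALSE, n, n))),
               "empty")
  outside <- binary_mask(r > 17 & r < 19)
  expect_error(band_depth(outside, ref), "inside")
})

test_that("dice_coefficient matches enumeration on toy sets", {
  a <- matrix(FALSE, 3, 3); b <- matrix(FALSE, 3, 3)
  a[1, 1:3] <- TRUE          # cells 1,4,7 (column-major)
  b[1, 2:3] <- TRUE; b[2, 1] <- TRUE
  set_a <- which(a); set_b <- which(b)
  expect_equal(dice_coefficient(a, b), dice_oracle(set_a, set_b))
  expect_equal(dice_coefficient(a, a), 1)
  expect_equal(dice_coefficient(a, !a), 0)
  empty <- matrix(FALSE, 3, 3)
  expect_equal(dice_coefficient(empty, empty), 1)
  expect_equal(dice_coefficient(a, empty), 0)
})
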