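test_that("rigid_transform wraps angles and composes/inverts exactly", {
  expect_equal(rigid_transform(370, 0, 0)$angle_deg, 10)
  expect_equal(rigid_transform(-190, 0, 0)$angle_deg, 170)
  tf <- rigid_transform(7.3, 120, -240)
  inv <- invert_transform(tf)
  id1 <- compose_transforms(tf, inv)
  expect_equal(id1$angle_deg, 0, tolerance = 1e-12)
  expect_equal(id1$tx_um, 0, tolerance = 1e-9)
  expect_equal(id1$ty_um, 0, tolerance = 1e-9)
  # composition order: applying first then second equals the composite
  a <- rigid_transform(5, 60, 0); b <- rigid_transform(-3, 0, 120)
  img <- structured_image()
  two_step <- apply_transform(apply_transform(img, a, 120), b, 120)
  one_step <- apply_transform(img, compose_transforms(a, b), 120)
  interior <- 8:34
  expect_lt(max(abs(two_step[interior, interior] -
                    one_step[interior, interior])),
            0.05 * diff(range(img)))
})

test_that("apply_transform performs exact 90-degree rotation and identity", {
  img <- matrix(runif(25), 5, 5)
  expect_equal(apply_transform(img, rigid_transform(0, 0, 0), 1), img)
  r90 <- apply_transform(img, rigid_transform(90, 0, 0), 1,
                         interpolation = "nearest")
  # 90 degree CCW rotation in y-up display convention is an exact
  # permutation of the grid
  expect_equal(sort(as.vector(r90)), sort(as.vector(img)))
  r360 <- apply_transform(img, rigid_transform(360, 0, 0), 1)
  expect_equal(r360, img, tolerance = 1e-9)
})

test_that("pure translations are recovered exactly on integer shifts", {
  img <- structured_image()
  tf <- rigid_transform(0, 3 * 120, -2 * 120)
  warped <- apply_transform(img, tf, 120)
  est <- estimate_rigid(warped, img, pitch_um = 120, polish = FALSE)
  inv <- invert_transform(tf)
  expect_equal(est$angle_deg, 0, tolerance = 0.5)
  expect_equal(est$tx_um, inv$tx_um, tolerance = 30)
  expect_equal(est$ty_um, inv$ty_um, tolerance = 30)
})

test_that("a planted 7-degree, (2,-3)-pixel transform is recovered", {
  spec <- phantom_spec(tic_cv = 0, additive_sd = 0, mz_jitter_ppm = 0,
                       rot_range_deg = 0, trans_range_um = 0, seed = 3)
  truth <- build_phantom(spec)
  img <- tic_image(render_sections(truth, "positive")[[8]])
  tf <- rigid_transform(7, 2 * 120, -3 * 120)
  warped <- apply_transform(img, tf, 120)
  est <- estimate_rigid(warped, img, pitch_um = 120)
  inv <- invert_transform(tf)
  expect_lt(abs(est$angle_deg - inv$angle_deg), 1)
  expect_lt(sqrt((est$tx_um - inv$tx_um)^2 + (est$ty_um - inv$ty_um)^2),
            0.5 * 120)
  # NCC at the recovered transform is at least that at the planted one
  ncc <- function(a, b) {
    stats::cor(as.vector(a), as.vector(b))
  }
  sc_est <- attr(est, "score")
  sc_true <- ncc(apply_transform(warped, inv, 120), img)
  expect_gte(sc_est, sc_true - 1e-6)
})

test_that("estimate_rigid rejects blank images and breaks ties to identity", {
  img <- structured_image()
  expect_error(estimate_rigid(matrix(0, 10, 10), matrix(1, 10, 10)), "blank")
  est <- estimate_rigid(img, img, polish = FALSE)
  expect_equal(est$angle_deg, 0)
  # sub-pixel parabolic refinement may move off zero by float noise only
  expect_equal(est$tx_um, 0, tolerance = 1e-3)
  expect_equal(est$ty_um, 0, tolerance = 1e-3)
})

test_that("register_series recovers planted transforms along the chain", {
  base <- structured_image()
  set.seed(55)
  planted <- c(list(rigid_transform(0, 0, 0)),
               lapply(1:4, function(i) {
                 rigid_transform(runif(1, -8, 8), runif(1, -240, 240),
                                 runif(1, -240, 240))
               }))
  series <- lapply(planted, function(tf) apply_transform(base, tf, 120))
  tfs <- register_series(series, pitch_um = 120)
  expect_equal(tfs[[1]]$angle_deg, 0)
  for (i in seq_along(tfs)) {
    inv <- invert_transform(planted[[i]])
    expect_lt(abs(tfs[[i]]$angle_deg - inv$angle_deg), 1)
    expect_lt(sqrt((tfs[[i]]$tx_um - inv$tx_um)^2 +
                   (tfs[[i]]$ty_um - inv$ty_um)^2), 60)
  }
})

test_that("stack_volume builds isotropic volumes and warns otherwise", {
  imgs <- lapply(1:3, function(i) matrix(i, 4, 5))
  vol <- stack_volume(imgs, pixel_pitch_um = 120, z_step_um = 120)
  expect_s3_class(vol, "msi_volume")
  expect_true(vol$isotropic)
  expect_equal(dim(vol$data), c(3, 4, 5))
  expect_equal(vol$data[2, 1, 1], 2)
  expect_warning(stack_volume(imgs, 100, 120), "anisotropic")
  expect_error(stack_volume(list(matrix(0, 2, 2), matrix(0, 3, 3)), 1, 1))
})

test_that("transform tables round-trip through CSV", {
  tfs <- list(rigid_transform(0, 0, 0), rigid_transform(-7.25, 120.5, -36))
  path <- file.path(tempdir(), "tf.csv")
  write_transforms(tfs, path)
  back <- read_transforms(path)
  expect_length(back, 2)
  expect_equal(back[[2]]$angle_deg, -7.25)
  expect_equal(back[[2]]$tx_um, 120.5)
  expect_equal(back[[2]]$ty_um, -36)
})
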