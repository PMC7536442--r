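synthetic_lowrank <- function(n = 60, m = 25, k = 3, seed = 8) {
  set.seed(seed)
  W <- matrix(rexp(n * k), n, k)
  H <- matrix(0, k, m)
  for (j in seq_len(k)) H[j, ((j - 1) * 8 + 1):((j - 1) * 8 + 6)] <- runif(6, 1, 3)
  list(W = W, H = H, X = W %*% H)
}

test_that("nnmf reduces the objective monotonically and normalizes H", {
  sl <- synthetic_lowrank()
  fit <- nnmf(sl$X, k = 3, seed = 1, max_iter = 400)
  expect_s3_class(fit, "nmf_model")
  expect_true(all(diff(fit$objective) <= 1e-8))
  expect_true(all(fit$W >= 0))
  expect_true(all(fit$H >= 0))
  expect_equal(unname(sqrt(rowSums(fit$H^2))), rep(1, 3), tolerance = 1e-9)
  relerr <- norm(sl$X - fit$W %*% fit$H, "F") / norm(sl$X, "F")
  expect_lt(relerr, 0.05)
})

test_that("nnmf with nndsvd init is deterministic; random init obeys the seed", {
  sl <- synthetic_lowrank()
  f1 <- nnmf(sl$X, 3, init = "nndsvd", max_iter = 50)
  f2 <- nnmf(sl$X, 3, init = "nndsvd", max_iter = 50)
  expect_identical(f1$W, f2$W)
  r1 <- nnmf(sl$X, 3, init = "random", seed = 7, max_iter = 50)
  r2 <- nnmf(sl$X, 3, init = "random", seed = 7, max_iter = 50)
  r3 <- nnmf(sl$X, 3, init = "random", seed = 8, max_iter = 50)
  expect_identical(r1$W, r2$W)
  expect_false(identical(r1$W, r3$W))
})

test_that("match_components recovers a planted permutation", {
  sl <- synthetic_lowrank()
  H_ref <- sl$H / sqrt(rowSums(sl$H^2))
  perm <- c(3, 1, 2)
  H_perm <- H_ref[perm, ]
  mc <- match_components(H_perm, H_ref)
  expect_equal(mc$assignment, order(perm))
  expect_equal(unname(mc$cosines), rep(1, 3), tolerance = 1e-12)
})

test_that("segment_regions assigns argmax labels with an abstain floor", {
  W <- rbind(c(10, 0.1), c(0.2, 8), c(0.5, 0.5))
  H <- matrix(c(1, 0, 0, 1), 2, 2)
  pm <- data.frame(section = c(0, 0, 0), row = c(0, 0, 0), col = 0:2)
  model <- structure(list(W = W, H = H, pixel_map = pm, k = 2L),
                     class = "nmf_model")
  seg <- segment_regions(model, floor = 0.6)
  expect_equal(seg$labels[1:2], c(1L, 2L))
  # pixel 3 splits 50/50: no component reaches a 0.6 share -> unassigned
  expect_equal(seg$labels[3], 0L)
  # a share exactly at the floor counts as assigned
  seg2 <- segment_regions(model, floor = 0.5)
  expect_equal(seg2$labels[3], 1L)
  expect_equal(dim(seg$label_volume), c(1, 1, 3))
})

test_that("component_ion_ranking surfaces each component's signature ions", {
  sl <- synthetic_lowrank()
  fit <- nnmf(sl$X, 3, max_iter = 300)
  fit$bin_centers <- seq(100, by = 10, length.out = ncol(sl$X))
  rk <- component_ion_ranking(fit, top_n = 3)
  expect_length(rk, 3)
  for (comp in 1:3) {
    expect_equal(nrow(rk[[comp]]), 3)
    expect_false(is.unsorted(rev(rk[[comp]]$weight)))
    # each component's top ion carries its largest H loading
    expect_equal(rk[[comp]]$weight[1], max(fit$H[comp, ]))
    expect_equal(rk[[comp]]$mz[1], fit$bin_centers[which.max(fit$H[comp, ])])
  }
  expect_error(component_ion_ranking(fit, top_n = 0))
})

test_that("select_rank reports a decreasing error curve and an elbow", {
  sl <- synthetic_lowrank()
  sr <- select_rank(sl$X, ks = 1:5, replicates = 2, max_iter = 150)
  # the curve decreases up to local-optimum wiggle, and collapses at the
  # planted rank
  err <- sr$error_curve$error
  expect_true(all(diff(err) <= 0.05 * err[1]))
  expect_lt(err[3], 0.05 * err[1])
  expect_equal(sr$k, 3)
  expect_equal(nrow(sr$diagnostics), 10)
  expect_true(all(sr$stability$mean_cosine >= -1 &
                    sr$stability$mean_cosine <= 1 + 1e-9))
})
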