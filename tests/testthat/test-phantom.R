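test_that("a single straight bundle dominates every seed voxel's mixture", {
  spec <- phantom_spec(
    grid_shape = c(24L, 24L, 24L),
    seeds = list(s = region_box("s", c(4, 4, 10), c(8, 8, 14))),
    targets = list(t = region_box("t", c(16, 4, 10), c(20, 8, 14))),
    bundles = list(bundle_def("s", "t", "limbic",
                              from = region_box("s", c(4, 4, 10), c(8, 8, 14)),
                              to = region_box("t", c(16, 4, 10), c(20, 8, 14)))))
  ph <- build_phantom(spec)
  sv <- which(ph$seeds$s)
  w <- ph$field$weights[sv, , drop = FALSE]
  dom <- max.col(w, ties.method = "first")
  dx <- ph$field$dirs[cbind(sv, dom, 1L)]
  expect_true(all(abs(dx - 1) < 1e-12))       # bundle runs along +x
  # noise-free, crossing-free: exactly one nonzero direction per bundle voxel
  expect_true(all(rowSums(w > 0) == 1L))
})

test_that("three parallel bundles give three contiguous ground-truth slabs", {
  gt <- PH32$ground_truth$striatum_L
  for (k in 1:3) {
    zs <- sort(unique(which(gt == k, arr.ind = TRUE)[, 3]))
    expect_equal(zs, seq(min(zs), max(zs)))   # contiguous in z
  }
  # stacked in order along the topography axis
  ztop <- vapply(1:3, function(k) max(which(gt == k, arr.ind = TRUE)[, 3]), numeric(1))
  expect_true(all(diff(ztop) > 0))
})

test_that("phantom build is deterministic and jitter is seed-controlled", {
  s <- default_phantom_spec(c(32L, 32L, 32L), angular_noise_deg = 10, rng_seed = 3L)
  a <- build_phantom(s); b <- build_phantom(s)
  expect_identical(a$field$dirs, b$field$dirs)
  expect_identical(a$field$weights, b$field$weights)
  s2 <- default_phantom_spec(c(32L, 32L, 32L), angular_noise_deg = 10, rng_seed = 4L)
  expect_false(identical(build_phantom(s2)$field$dirs, a$field$dirs))
})

test_that("territories tile each seed ROI exactly", {
  for (s in names(PH32$seeds)) {
    gt <- PH32$ground_truth[[s]]
    expect_true(all(gt[PH32$seeds[[s]]] > 0L))
    expect_equal(sum(gt > 0L), sum(PH32$seeds[[s]]))
  }
})

test_that("overlapping regions are rejected with names", {
  expect_error(
    phantom_spec(grid_shape = c(16L, 16L, 16L),
                 seeds = list(a = region_box("a", c(0, 0, 0), c(5, 5, 5))),
                 targets = list(b = region_box("b", c(4, 4, 4), c(8, 8, 8))),
                 bundles = list(bundle_def("a", "b", "limbic",
                                           region_box("a", c(0, 0, 0), c(5, 5, 5)),
                                           region_box("b", c(4, 4, 4), c(8, 8, 8))))),
    "overlap.*'a' and 'b'")
  expect_error(default_phantom_spec(c(8L, 32L, 32L)), "grid_shape")
})

test_that("orientation weights are a normalized mixture wherever mass exists", {
  w <- PH32$field$weights
  tot <- rowSums(w)
  expect_true(all(w >= 0))
  expect_true(all(abs(tot[tot > 0] - 1) < 1e-12))
  # seed voxels all carry mass (tracking can start anywhere in the seed)
  for (s in names(PH32$seeds)) {
    expect_true(all(tot[which(PH32$seeds[[s]])] > 0))
  }
})

test_that("crossing fraction adds a shared orthogonal component", {
  ph <- build_phantom(default_phantom_spec(c(32L, 32L, 32L),
                                           crossing_fraction = 0.3, rng_seed = 5L))
  sv <- which(ph$seeds$striatum_L)
  w <- ph$field$weights[sv, , drop = FALSE]
  expect_true(all(rowSums(w > 0) == 2L))
  k2 <- apply(w, 1L, function(r) which(r > 0)[2L])
  expect_true(all(abs(w[cbind(seq_along(sv), k2)] - 0.3) < 1e-12))
  # orthogonality of the secondary to the primary
  k1 <- apply(w, 1L, function(r) which(r > 0)[1L])
  d1 <- cbind(ph$field$dirs[cbind(sv, k1, 1L)], ph$field$dirs[cbind(sv, k1, 2L)],
              ph$field$dirs[cbind(sv, k1, 3L)])
  d2 <- cbind(ph$field$dirs[cbind(sv, k2, 1L)], ph$field$dirs[cbind(sv, k2, 2L)],
              ph$field$dirs[cbind(sv, k2, 3L)])
  expect_lt(max(abs(rowSums(d1 * d2))), 1e-9)
})

test_that("cohort volumes follow baseline + group offset + clipped noise", {
  cs <- cohort_spec(n_hc = 2L, n_sz = 2L, fa_baseline = 0.47,
                    fa_group_offset = -0.036, fa_noise_sd = 0, master_seed = 9L)
  co <- build_cohort(PH32, cs)
  expect_equal(nrow(co$manifest), 4L)
  sz <- co$fa[[which(co$manifest$diagnosis == "SZ")[1L]]]
  expect_true(all(sz == 0.434))               # noise-free SZ volume is exact
  hc <- co$fa[[which(co$manifest$diagnosis == "HC")[1L]]]
  expect_true(all(hc == 0.47))

  # full-size manifest and law-of-large-numbers check with noise
  cs2 <- cohort_spec(n_hc = 24L, n_sz = 30L, fa_noise_sd = 0.01, master_seed = 9L)
  co2 <- build_cohort(PH32, cs2)
  expect_equal(nrow(co2$manifest), 54L)
  i <- which(co2$manifest$diagnosis == "SZ")[1L]
  V <- prod(PH32$grid)
  expect_lt(abs(mean(co2$fa[[i]]) - 0.434), 3 * 0.01 / sqrt(V))
})

test_that("cohort seeds derive deterministically and invalid FA bounds fail", {
  a <- build_cohort(PH32, cohort_spec(n_hc = 3L, n_sz = 3L, master_seed = 2L))
  b <- build_cohort(PH32, cohort_spec(n_hc = 3L, n_sz = 3L, master_seed = 2L))
  expect_identical(a$manifest$seed, b$manifest$seed)
  expect_identical(a$fa, b$fa)
  expect_error(cohort_spec(fa_baseline = 0.02, fa_group_offset = -0.036),
               "within \\(0, 1\\)")
})

test_that("field volumes round-trip through the NIfTI layout", {
  f <- tempfile(fileext = ".nii.gz")
  write_field(PH32$field, f)
  rt <- read_field(f)
  expect_equal(rt$dirs, PH32$field$dirs, tolerance = 1e-12)
  expect_equal(rt$weights, PH32$field$weights, tolerance = 1e-12)
  expect_identical(rt$grid, PH32$field$grid)
  unlink(f)
})
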