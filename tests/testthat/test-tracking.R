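test_that("direction sampling honors the mixture and the angular cone", {
  g <- c(16L, 16L, 16L)
  f1 <- uniform_field(g, c(1, 0, 0))
  set.seed(1)
  for (i in 1:20) {
    r <- sample_direction(f1, c(8, 8, 8), prev_dir = c(1, 0, 0))
    expect_equal(r$direction, c(1, 0, 0))
    expect_identical(r$status, "ok")
  }
  # single direction at 90 degrees to the previous one: empty cone
  r <- sample_direction(f1, c(8, 8, 8), prev_dir = c(0, 1, 0), max_angle_deg = 30)
  expect_identical(r$status, "terminated_angle")
  expect_null(r$direction)
  # massless voxel and out-of-grid position terminate on the field
  r <- sample_direction(empty_field(g), c(8, 8, 8))
  expect_identical(r$status, "terminated_field")
  r <- sample_direction(f1, c(50, 8, 8))
  expect_identical(r$status, "terminated_field")
})

test_that("two-component draws match binomial frequencies", {
  g <- c(16L, 16L, 16L)
  d <- matrix(c(1, 0, 0,
                0.9, 0.4358899, 0), 2L, 3L, byrow = TRUE)  # both within 30 deg of +x
  d <- d / sqrt(rowSums(d^2))
  f <- mixture_field(g, d, c(0.8, 0.2))
  set.seed(42)
  n <- 10000L
  hits <- 0L
  r <- sample_directions_batch(f, matrix(rep(c(8, 8, 8), each = n), n, 3L),
                               matrix(rep(c(1, 0, 0), each = n), n, 3L), 30)
  hits <- sum(abs(r$dir[, 2]) < 1e-9)
  p <- 0.8
  expect_lt(abs(hits / n - p), 3 * sqrt(p * (1 - p) / n))
})

test_that("a uniform +x field reaches an x-slab target in exact steps", {
  g <- c(16L, 16L, 16L)
  f <- uniform_field(g, c(1, 0, 0))
  target <- box_mask(g, c(5, 0, 0), c(15, 15, 15))
  s <- track_streamline(f, c(0, 4, 4), targets = list(t = target),
                        params = tracking_params(step_size = 1.25), rng_seed = 7L)
  expect_identical(s$status, "reached_target")
  expect_identical(s$target, "t")
  expect_equal(nrow(s$points), 5L)            # start + 4 steps of 1.25 = 5.0
  expect_equal(s$points[5L, ], c(5, 4, 4))
  # zero field at the start: one point, field termination
  s0 <- track_streamline(empty_field(g), c(4, 4, 4), targets = list(t = target),
                         rng_seed = 7L)
  expect_identical(s0$status, "terminated_field")
  expect_equal(nrow(s0$points), 1L)
})

test_that("streamlines follow a curved arc bundle to its far end", {
  # quarter-circle bundle (radii 25-35 mm) in the xy-plane around (4, 4, 8);
  # the band starts at the seed row, so backward starts die in one step and
  # are retried forward
  g <- c(48L, 48L, 16L)
  nvox <- prod(g)
  idx <- as.matrix(expand.grid(x = 0:(g[1] - 1), y = 0:(g[2] - 1), z = 0:(g[3] - 1)))
  cx <- idx[, 1] - 4; cy <- idx[, 2] - 4
  rr <- sqrt(cx^2 + cy^2)
  band <- rr >= 25 & rr <= 35 & cy >= 0 & abs(idx[, 3] - 8) <= 2
  dirs <- array(0, c(nvox, 1L, 3L))
  tang <- cbind(-cy, cx, 0) / pmax(rr, 1e-9)
  dirs[band, 1L, 1L] <- tang[band, 1L]
  dirs[band, 1L, 2L] <- tang[band, 2L]
  w <- matrix(0, nvox, 1L); w[band, 1L] <- 1
  f <- orientation_field(dirs, w, g)
  seed <- box_mask(g, c(32, 4, 7), c(36, 4, 9))          # angle-0 row
  target <- box_mask(g, c(0, 20, 0), c(8, 44, 15))       # near angle 90
  tg <- seed_tractography(seed, list(end = target), f,
                          tracking_params(n_streamlines = 400L, rng_seed = 5L))
  # oracle: deterministic fine-step integration along the same arc reaches it
  p <- c(34, 4, 8); d <- c(0, 1, 0); ok <- FALSE
  for (k in 1:4000) {
    v <- f$dirs[voxel_to_linear(pos_to_voxel(matrix(p, 1, 3), 1), g), 1L, ]
    if (sum(v^2) == 0) break
    if (sum(v * d) < 0) v <- -v
    p <- p + 0.05 * v; d <- v
    if (target[voxel_to_linear(pos_to_voxel(matrix(p, 1, 3), 1), g)]) { ok <- TRUE; break }
  }
  expect_true(ok)
  expect_gte(mean(tg$status == "reached_target"), 0.95)
  geo <- check_streamline_geometry(tg)
  expect_true(all(geo$step_ok) && all(geo$angle_ok))
})

test_that("seed tractography keeps every attempt and is reproducible", {
  params <- tracking_params(n_streamlines = 300L, rng_seed = 21L)
  targets <- stats::setNames(
    lapply(TERRITORIES, function(l) PH32$targets[[paste0(l, "_L")]]), TERRITORIES)
  tg <- seed_tractography(PH32$seeds$striatum_L, targets, PH32$field, params)
  expect_length(tg$lengths, 300L)
  expect_equal(sum(tg$counts), sum(tg$status == "reached_target"))
  tg2 <- seed_tractography(PH32$seeds$striatum_L, targets, PH32$field, params)
  expect_identical(tg$points, tg2$points)
  expect_identical(tg$status, tg2$status)
  # all-zero field: everything terminates on the field
  tg0 <- seed_tractography(PH32$seeds$striatum_L, targets,
                           empty_field(PH32$grid), params)
  expect_true(all(tg0$status == "terminated_field"))
  expect_error(seed_tractography(array(FALSE, PH32$grid), targets, PH32$field,
                                 params), "empty")
})

test_that("flipping the sign of every stored direction changes nothing", {
  params <- tracking_params(n_streamlines = 400L, rng_seed = 13L)
  targets <- stats::setNames(
    lapply(TERRITORIES, function(l) PH32$targets[[paste0(l, "_L")]]), TERRITORIES)
  tg <- seed_tractography(PH32$seeds$striatum_L, targets, PH32$field, params)
  flipped <- PH32$field
  flipped$dirs <- -flipped$dirs
  tgf <- seed_tractography(PH32$seeds$striatum_L, targets, flipped, params)
  expect_identical(tg$counts, tgf$counts)
  expect_identical(tg$points, tgf$points)
})

test_that("target counts vary on a binomial scale across seeds", {
  # one seed voxel with a 50/50 two-way split toward two x-slab targets
  g <- c(24L, 16L, 16L)
  d <- matrix(c(1, 0, 0, 1, 0, 0), 2L, 3L, byrow = TRUE)
  f <- mixture_field(g, d, c(0.5, 0.5))      # both components +x; split by polarity
  seed <- box_mask(g, c(11, 7, 7), c(12, 8, 8))
  tA <- box_mask(g, c(18, 0, 0), c(23, 15, 15))
  tB <- box_mask(g, c(0, 0, 0), c(5, 15, 15))
  n <- 256L
  counts <- vapply(1:30, function(s) {
    tg <- seed_tractography(seed, list(A = tA, B = tB), f,
                            tracking_params(n_streamlines = n, rng_seed = 100L + s))
    tg$counts[["A"]]
  }, integer(1))
  p_hat <- mean(counts) / n
  expect_lt(abs(p_hat - 0.5), 0.05)
  expect_lt(stats::sd(counts), 3 * sqrt(n * 0.25))
  expect_gt(stats::sd(counts), sqrt(n * 0.25) / 3)
})

test_that("stored streamlines satisfy the step and angle invariants on the phantom", {
  params <- tracking_params(n_streamlines = 500L, rng_seed = 3L)
  ph <- build_phantom(default_phantom_spec(c(32L, 32L, 32L),
                                           angular_noise_deg = 8, rng_seed = 2L))
  targets <- stats::setNames(
    lapply(TERRITORIES, function(l) ph$targets[[paste0(l, "_L")]]), TERRITORIES)
  tg <- seed_tractography(ph$seeds$striatum_L, targets, ph$field, params)
  geo <- check_streamline_geometry(tg, params)
  expect_true(all(geo$step_ok))
  expect_true(all(geo$angle_ok))
})
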