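test_that("track-density maps rasterize paths once per streamline and mask to the seed", {
  g <- c(16L, 16L, 16L)
  seed <- box_mask(g, c(2, 4, 4), c(6, 4, 4))    # 5 voxels along x
  straight <- cbind(seq(2, 9, by = 1), 4, 4)     # exits the seed at x = 7..9
  tg <- make_tractogram(list(straight), "reached_target", "A", labels = c("A", "B"))
  maps <- tdi_map(tg, seed, 1)
  expect_equal(sum(maps$A), 5L)                  # only the 5 seed voxels count
  expect_true(all(maps$A[seed] == 1L))
  expect_equal(sum(maps$B), 0L)

  # coincident streamlines are additive; revisited voxels count once
  wiggle <- rbind(straight, straight[nrow(straight):1, ])  # doubles back
  tg2 <- make_tractogram(list(straight, straight, wiggle),
                         rep("reached_target", 3), c("A", "A", "A"),
                         labels = c("A", "B"))
  maps2 <- tdi_map(tg2, seed, 1)
  expect_true(all(maps2$A[seed] == 3L))

  # non-reaching streamlines contribute to no map
  tg3 <- make_tractogram(list(straight, straight),
                         c("reached_target", "terminated_field"),
                         c("A", NA), labels = c("A", "B"))
  expect_true(all(tdi_map(tg3, seed, 1)$A[seed] == 1L))

  # endpoint-only variant counts a single voxel per streamline
  ep <- tdi_map(tg, seed, 1, endpoints_only = TRUE)
  expect_equal(sum(ep$A), 0L)                    # endpoint lies outside the seed
})

test_that("mean normalization rescales to mean one and flags all-zero maps", {
  g <- c(4L, 1L, 1L)
  seed <- array(c(TRUE, TRUE, TRUE, FALSE), g)
  m <- array(c(2, 4, 6, 99), g)
  nm <- normalize_map(m, seed)
  expect_equal(nm[seed], c(0.5, 1, 1.5))
  expect_equal(mean(nm[seed]), 1)
  expect_equal(nm[4], 0)                         # outside the seed is zeroed
  expect_equal(normalize_map(array(5, g), array(TRUE, g))[1], 1)
  z <- normalize_map(array(0, g), seed)
  expect_true(isTRUE(attr(z, "all_zero")))
  # proportional maps normalize identically (the point of the normalization)
  expect_equal(normalize_map(m * 7, seed), normalize_map(m, seed))
})

test_that("winner-take-all matches the stated conventions", {
  g <- c(3L, 1L, 1L)
  seed <- array(TRUE, g)
  mk <- function(v) array(v, g)
  maps <- list(limbic = mk(c(0.2, 0, 1.0)),
               prefrontal = mk(c(1.7, 0, 1.0)),
               sensorimotor = mk(c(0.4, 0, 0.3)))
  p <- classify(maps, seed)
  expect_equal(p$map[1], 2L)                     # argmax -> prefrontal
  expect_equal(p$map[2], 0L)                     # all-zero -> unclassified
  expect_equal(p$map[3], 1L)                     # tie -> lowest index (limbic)
  expect_error(classify(maps["limbic"], seed), "at least 2")
  bad <- maps; bad$limbic <- array(0, c(4L, 1L, 1L))
  expect_error(classify(bad, seed), "grid")
})

test_that("classification equals the exhaustive argmax oracle on random maps", {
  set.seed(77)
  g <- c(6L, 5L, 4L)
  seed <- array(stats::runif(prod(g)) < 0.7, g)
  for (rep in 1:25) {
    K <- sample(2:4, 1)
    V <- matrix(stats::rpois(sum(seed) * K, lambda = sample(c(0.5, 2, 10), 1)),
                ncol = K)
    maps <- lapply(seq_len(K), function(k) {
      m <- array(0, g); m[seed] <- V[, k]; m
    })
    names(maps) <- paste0("t", seq_len(K))
    norm <- lapply(maps, normalize_map, seed_mask = seed)
    p <- classify(norm, seed)
    Vn <- vapply(norm, function(m) m[seed], numeric(sum(seed)))
    expect_identical(p$map[seed], classify_oracle(Vn))
  }
})

test_that("parcel volumes plus unclassified always conserve the seed volume", {
  params <- tracking_params(n_streamlines = 800L, rng_seed = 5L)
  targets <- stats::setNames(
    lapply(TERRITORIES, function(l) PH32$targets[[paste0(l, "_L")]]), TERRITORIES)
  res <- two_step_parcellate(PH32$seeds$striatum_L, targets,
                             PH32$seeds$midbrain_L, PH32$field, params)
  for (p in res) {
    sv <- p$map[p$seed_mask]
    expect_equal(sum(sv >= 0L), sum(p$seed_mask))
    vols <- vapply(0:3, function(k) sum(sv == k), integer(1))
    expect_equal(sum(vols), sum(p$seed_mask))
  }
})

test_that("scaling one target's raw counts never changes the parcellation", {
  params <- tracking_params(n_streamlines = 600L, rng_seed = 8L)
  targets <- stats::setNames(
    lapply(TERRITORIES, function(l) PH32$targets[[paste0(l, "_L")]]), TERRITORIES)
  seed <- PH32$seeds$striatum_L
  tg <- seed_tractography(seed, targets, PH32$field, params)
  maps <- tdi_map(tg, seed, 1)
  base <- classify(lapply(maps, normalize_map, seed_mask = seed), seed)
  scaled <- maps
  scaled$prefrontal <- scaled$prefrontal * 13
  rescaled <- classify(lapply(scaled, normalize_map, seed_mask = seed), seed)
  expect_identical(base$map, rescaled$map)
})

test_that("midbrain labels collapse to one territory when only one is wired", {
  # custom phantom: every midbrain bundle rewired to the limbic striatal slab
  g <- c(32L, 32L, 32L)
  spec <- default_phantom_spec(g, rng_seed = 6L)
  zlim <- local({
    b <- Filter(function(b) startsWith(b$seed, "midbrain_L") &&
                  b$territory == "limbic", spec$bundles)[[1L]]
    c(b$to$lo[3], b$to$hi[3])
  })
  for (i in seq_along(spec$bundles)) {
    if (startsWith(spec$bundles[[i]]$seed, "midbrain")) {
      spec$bundles[[i]]$territory <- "limbic"
      spec$bundles[[i]]$to$lo[3] <- zlim[1]
      spec$bundles[[i]]$to$hi[3] <- zlim[2]
    }
  }
  ph <- build_phantom(spec)
  targets <- stats::setNames(
    lapply(TERRITORIES, function(l) ph$targets[[paste0(l, "_L")]]), TERRITORIES)
  res <- two_step_parcellate(ph$seeds$striatum_L, targets, ph$seeds$midbrain_L,
                             ph$field, tracking_params(n_streamlines = 1000L,
                                                       rng_seed = 6L))
  mb <- res$midbrain$map[res$midbrain$seed_mask]
  expect_true(all(mb %in% c(0L, 1L)))            # limbic or unclassified only
  expect_gt(mean(mb == 1L), 0)
})

test_that("parcellation recovery degrades as angular noise grows", {
  med_dice <- vapply(c(0, 12, 25), function(noise) {
    d <- vapply(1:2, function(s) {
      ph <- build_phantom(default_phantom_spec(c(32L, 32L, 32L),
                                               angular_noise_deg = noise,
                                               rng_seed = 40L + s))
      targets <- stats::setNames(
        lapply(TERRITORIES, function(l) ph$targets[[paste0(l, "_L")]]), TERRITORIES)
      res <- two_step_parcellate(ph$seeds$striatum_L, targets,
                                 ph$seeds$midbrain_L, ph$field,
                                 tracking_params(n_streamlines = 1500L,
                                                 rng_seed = 40L + s))
      median(parcellation_dice(res$striatal, ph$ground_truth$striatum_L))
    }, numeric(1))
    mean(d)
  }, numeric(1))
  expect_true(all(diff(med_dice) < 0))
})

test_that("maximum probability maps implement the at-least-half rule exactly", {
  g <- c(4L, 4L, 4L)
  seed <- array(TRUE, g)
  mk_parc <- function(lab1_voxels) {
    m <- array(2L, g)                            # background label 2
    m[lab1_voxels] <- 1L
    structure(list(map = m, labels = c("A", "B"), seed_mask = seed,
                   provenance = list()), class = "parcellation")
  }
  # voxel 1 labeled A in exactly 12 of 24 subjects; voxel 2 in 11 of 24
  parcs24 <- c(lapply(1:11, function(i) mk_parc(c(1L, 2L))),
               list(mk_parc(1L)),
               lapply(1:12, function(i) mk_parc(integer(0))))
  mpm <- build_mpm(parcs24, threshold = 0.5)
  expect_equal(mpm$counts$A[1], 12L)
  expect_true(mpm$masks$A[1])                    # 12/24 included
  expect_equal(mpm$counts$A[2], 11L)
  expect_false(mpm$masks$A[2])                   # 11/24 excluded
  # n = 30: threshold count is 15
  parcs30 <- c(lapply(1:15, function(i) mk_parc(1L)),
               lapply(1:15, function(i) mk_parc(integer(0))))
  expect_true(build_mpm(parcs30, 0.5)$masks$A[1])
  parcs30b <- c(lapply(1:14, function(i) mk_parc(1L)),
                lapply(1:16, function(i) mk_parc(integer(0))))
  expect_false(build_mpm(parcs30b, 0.5)$masks$A[1])
  # union / intersection limits and monotonicity in the threshold
  vols <- vapply(c(0, 0.25, 0.5, 0.75, 1),
                 function(th) sum(build_mpm(parcs24, th)$masks$A), integer(1))
  expect_true(all(diff(vols) <= 0))
  expect_equal(vols[1], sum(Reduce(`|`, lapply(parcs24, function(p) p$map == 1L))))
  expect_equal(vols[5], sum(Reduce(`&`, lapply(parcs24, function(p) p$map == 1L))))
  # mixed grids are rejected
  bad <- mk_parc(1L); bad$map <- array(2L, c(5L, 4L, 4L))
  expect_error(build_mpm(c(parcs24, list(bad))), "mixed grids")
})
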