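# Shared fixtures, built in code at load time.

# one small phantom reused across tests (32^3, noise-free, crossing-free)
PH32 <- build_phantom(default_phantom_spec(c(32L, 32L, 32L), rng_seed = 11L))

# a field with one identical direction everywhere
uniform_field <- function(grid, dir, voxel_size = 1) {
  nvox <- prod(grid)
  d <- dir / sqrt(sum(dir^2))
  dirs <- array(0, c(nvox, 1L, 3L))
  for (a in 1:3) dirs[, 1L, a] <- d[a]
  orientation_field(dirs, matrix(1, nvox, 1L), grid, voxel_size)
}

# a field with the same K-component mixture in every voxel
mixture_field <- function(grid, dirs_mat, weights, voxel_size = 1) {
  nvox <- prod(grid)
  K <- nrow(dirs_mat)
  dd <- array(0, c(nvox, K, 3L))
  for (k in seq_len(K)) for (a in 1:3) dd[, k, a] <- dirs_mat[k, a]
  orientation_field(dd, matrix(weights, nvox, K, byrow = TRUE), grid, voxel_size)
}

# assemble a minimal tractogram object from explicit point matrices
make_tractogram <- function(point_list, statuses, targets, labels,
                            params = tracking_params(n_streamlines = length(point_list))) {
  n <- length(point_list)
  maxlen <- max(c(1L, vapply(point_list, nrow, integer(1))))
  pts <- array(NA_real_, c(n, 3L, maxlen))
  for (i in seq_len(n)) pts[i, , seq_len(nrow(point_list[[i]]))] <- t(point_list[[i]])
  counts <- stats::setNames(
    vapply(labels, function(l) sum(statuses == "reached_target" & targets == l,
                                   na.rm = TRUE), integer(1)), labels)
  seeds <- if (n > 0L) t(vapply(point_list, function(p) p[1L, ], numeric(3)))
           else matrix(0, 0L, 3L)
  structure(list(points = pts,
                 lengths = vapply(point_list, nrow, integer(1)),
                 status = statuses, target = targets,
                 seed_points = seeds,
                 params = params, counts = counts, labels = labels),
            class = "tractogram")
}

# box mask helper (0-based inclusive bounds)
box_mask <- function(grid, lo, hi) region_mask(region_box("m", lo, hi), grid)
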