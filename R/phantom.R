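# Digital phantom: a striatum-like seed connected to three cortical-like
# target groups (limbic, prefrontal, sensorimotor) by parallel fiber bundles
# stacked along a ventro-dorsal gradient, plus a midbrain-like seed whose
# medio-lateral subdivisions connect to the three striatal territories.
# Ground-truth territory maps are produced alongside, so every downstream
# stage (tracking, parcellation, metrics, stats) can be validated against a
# known topography.

#' Canonical territory labels, in fixed classification order
#' @export
TERRITORIES <- c("limbic", "prefrontal", "sensorimotor")

# --- regions -----------------------------------------------------------------

#' Axis-aligned box region (0-based inclusive voxel bounds)
#' @param name region name. @param lo,hi integer 3-vectors, 0-based inclusive.
#' @export
region_box <- function(name, lo, hi) {
  stopifnot(all(hi >= lo))
  list(name = name, type = "box", lo = as.numeric(lo), hi = as.numeric(hi))
}

#' Ellipsoid region (voxel-center test)
#' @param name region name. @param center,radii numeric 3-vectors in voxels.
#' @export
region_ellipsoid <- function(name, center, radii) {
  stopifnot(all(radii > 0))
  list(name = name, type = "ellipsoid", center = as.numeric(center),
       radii = as.numeric(radii))
}

#' Rasterize a region definition to a logical mask
#' @keywords internal
region_mask <- function(def, grid) {
  m <- array(FALSE, grid)
  if (def$type == "box") {
    lo <- pmax(ceiling(def$lo), 0); hi <- pmin(floor(def$hi), grid - 1L)
    if (any(hi < lo)) return(m)
    m[(lo[1]:hi[1]) + 1L, (lo[2]:hi[2]) + 1L, (lo[3]:hi[3]) + 1L] <- TRUE
  } else if (def$type == "ellipsoid") {
    x <- ((seq_len(grid[1]) - 1) - def$center[1]) / def$radii[1]
    y <- ((seq_len(grid[2]) - 1) - def$center[2]) / def$radii[2]
    z <- ((seq_len(grid[3]) - 1) - def$center[3]) / def$radii[3]
    d2 <- outer(outer(x^2, y^2, `+`), z^2, `+`)
    m[d2 <= 1] <- TRUE
  } else stop("unknown region type: ", def$type)
  m
}

box_center <- function(def) (def$lo + def$hi) / 2

# --- bundles -----------------------------------------------------------------

#' Define a fiber bundle between two boxes
#'
#' The bundle occupies the prism swept between `from` and `to` (linear
#' interpolation of the box faces along the dominant axis of separation),
#' optionally dilated by `radius` voxels in cross-section; voxels inside the
#' `to` box itself carry no mass from this bundle (streamlines terminate on
#' target arrival, so the target interior needs no orientation). The
#' orientation is the constant unit vector joining the two box centers.
#'
#' @param seed name of the seed ROI this bundle serves.
#' @param target name of the target region it reaches.
#' @param territory ground-truth territory label of its seed voxels.
#' @param from,to box regions (as from [region_box()]).
#' @param radius cross-sectional dilation in voxels (default 0).
#' @export
bundle_def <- function(seed, target, territory, from, to, radius = 0) {
  list(seed = seed, target = target, territory = territory,
       from = from, to = to, radius = radius)
}

#' Linear voxel indices covered by a bundle prism
#'
#' The prism is the forward sweep of the `from` box along the bundle
#' direction: every point of the from box, translated by any travel
#' distance up to the far face of the `to` box, is inside. This guarantees
#' that a streamline following the bundle direction from anywhere in the
#' from box never leaves the prism before arrival.
#' @keywords internal
rasterize_bundle <- function(b, grid) {
  fc <- box_center(b$from); tc <- box_center(b$to)
  d <- tc - fc
  sweep_ax <- which.max(abs(d))
  others <- setdiff(1:3, sweep_ax)
  sgn <- sign(d[sweep_ax])
  sh <- d[others] / abs(d[sweep_ax])       # cross-axis shear per unit sweep
  f_near <- if (sgn > 0) b$from$lo[sweep_ax] else b$from$hi[sweep_ax]
  f_far  <- if (sgn > 0) b$from$hi[sweep_ax] else b$from$lo[sweep_ax]
  s_end  <- if (sgn > 0) b$to$hi[sweep_ax] else b$to$lo[sweep_ax]
  svals <- seq(max(min(f_near, s_end), 0),
               min(max(f_near, s_end), grid[sweep_ax] - 1))
  vox <- NULL
  for (s in svals) {
    p_min <- max(sgn * (s - f_far), 0)     # least travel reaching this slice
    p_max <- max(sgn * (s - f_near), 0)    # most travel reaching this slice
    rr <- vector("list", 2L)
    for (j in 1:2) {
      a <- others[j]
      lo <- b$from$lo[a] + sh[j] * (if (sh[j] >= 0) p_min else p_max)
      hi <- b$from$hi[a] + sh[j] * (if (sh[j] >= 0) p_max else p_min)
      lo <- max(ceiling(lo - b$radius), 0)
      hi <- min(floor(hi + b$radius), grid[a] - 1)
      if (hi < lo) { rr <- NULL; break }
      rr[[j]] <- lo:hi
    }
    if (is.null(rr)) next
    g <- as.matrix(expand.grid(a = rr[[1L]], b = rr[[2L]]))
    slab <- matrix(0L, nrow(g), 3L)
    slab[, sweep_ax] <- s
    slab[, others[1]] <- g[, 1]; slab[, others[2]] <- g[, 2]
    vox <- rbind(vox, slab)
  }
  idx <- voxel_to_linear(vox, grid)
  # target interior carries no mass from its own bundle
  to_mask <- region_mask(b$to, grid)
  idx <- idx[!is.na(idx)]
  unique(idx[!to_mask[idx]])
}

bundle_direction <- function(b) {
  d <- box_center(b$to) - box_center(b$from)
  d / sqrt(sum(d^2))
}

# --- phantom spec ------------------------------------------------------------

#' Construct and validate a phantom specification
#'
#' @param grid_shape integer 3-vector of voxel counts, each >= 16.
#' @param voxel_size isotropic voxel edge in mm.
#' @param seeds named list of region definitions for the seed ROIs.
#' @param targets named list of region definitions for the target groups.
#' @param bundles list of [bundle_def()]s linking seed subregions to targets.
#' @param topography_axis axis (1--3) encoding the territory gradient in the
#'   striatal seed (informational; the bundle layout realizes it).
#' @param crossing_fraction weight in [0, 1) of a shared secondary direction,
#'   orthogonal to the locally dominant one, added wherever bundles pass.
#' @param angular_noise_deg SD (degrees) of per-voxel direction jitter.
#' @param rng_seed integer seed controlling jitter; the build is a
#'   deterministic function of (spec, rng_seed).
#' @return a `phantom_spec` object.
#' @export
phantom_spec <- function(grid_shape, voxel_size = 1, seeds, targets, bundles,
                         topography_axis = 3L, crossing_fraction = 0,
                         angular_noise_deg = 0, rng_seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  if (length(grid_shape) != 3L || any(grid_shape < 16L))
    stop("grid_shape must be three integers, each >= 16")
  stopifnot(voxel_size > 0, crossing_fraction >= 0, crossing_fraction < 1,
            angular_noise_deg >= 0)
  if (is.null(names(seeds)) || is.null(names(targets)))
    stop("seeds and targets must be named lists")
  spec <- structure(list(grid_shape = grid_shape, voxel_size = voxel_size,
                         seeds = seeds, targets = targets, bundles = bundles,
                         topography_axis = as.integer(topography_axis),
                         crossing_fraction = crossing_fraction,
                         angular_noise_deg = angular_noise_deg,
                         rng_seed = as.integer(rng_seed)),
                    class = "phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  grid <- spec$grid_shape
  masks <- lapply(c(spec$seeds, spec$targets), region_mask, grid = grid)
  nms <- names(masks)
  for (i in seq_along(masks)) {
    if (!any(masks[[i]])) stop("region '", nms[i], "' rasterizes to an empty mask")
    if (i < length(masks)) for (j in (i + 1L):length(masks)) {
      if (any(masks[[i]] & masks[[j]]))
        stop("regions overlap: '", nms[i], "' and '", nms[j], "'")
    }
  }
  served <- vapply(spec$bundles, function(b) b$territory, character(1))
  for (s in names(spec$seeds)) {
    bt <- served[vapply(spec$bundles, function(b) b$seed == s, logical(1))]
    if (length(bt) == 0L) stop("seed '", s, "' has no bundle")
  }
  invisible(spec)
}

#' Default two-sided phantom geometry
#'
#' Mirror-symmetric left/right anatomy on a cubic-ish grid: per side, a
#' striatal box split into three equal slabs along z (ventro-dorsal:
#' limbic, prefrontal, sensorimotor), three cortical target boxes reached by
#' straight bundles running along +y (anterior), and a midbrain box split
#' into three medio-lateral slabs, each joined to its striatal territory by
#' an oblique straight bundle. `asymmetry` grows the right limbic slab by
#' that many voxels at the expense of the right sensorimotor slab, giving an
#' optional side effect on parcel volumes.
#'
#' @param grid_shape 3-vector of voxel counts (default 64^3; >= 32 needed
#'   for the default geometry to have room).
#' @param asymmetry integer voxel shift of the right-side slab boundaries.
#' @inheritParams phantom_spec
#' @return a `phantom_spec`.
#' @export
default_phantom_spec <- function(grid_shape = c(64L, 64L, 64L), voxel_size = 1,
                                 crossing_fraction = 0, angular_noise_deg = 0,
                                 rng_seed = 1L, asymmetry = 0L) {
  grid <- as.integer(grid_shape)
  if (any(grid < 32L)) stop("default geometry needs grid_shape >= 32 per axis")
  nx <- grid[1]; ny <- grid[2]; nz <- grid[3]

  u  <- max(2L, round(0.047 * nx))        # midbrain slab width
  sx0 <- round(0.14 * nx); sx1 <- sx0 + 3L * u - 1L
  ys0 <- round(0.44 * ny); ys1 <- round(0.61 * ny)     # striatum y extent
  ct0 <- round(0.78 * ny); ct1 <- min(round(0.86 * ny), ny - 2L)  # cortex y
  mb0 <- round(0.125 * ny); mb1 <- round(0.20 * ny)    # midbrain y extent
  z0 <- round(0.31 * nz); h <- max(3L, round(0.094 * nz))  # slab base/height

  mirror <- function(lo, hi) c(nx - 1L - hi, nx - 1L - lo)

  seeds <- list(); targets <- list(); bundles <- list()
  for (side in c("L", "R")) {
    if (side == "L") { xlo <- sx0; xhi <- sx1 } else { m <- mirror(sx0, sx1); xlo <- m[1]; xhi <- m[2] }
    asym <- if (side == "R") as.integer(asymmetry) else 0L
    # z slab bounds per territory (limbic ventral ... sensorimotor dorsal)
    zb <- list(c(z0, z0 + h - 1L + asym),
               c(z0 + h + asym, z0 + 2L * h - 1L + asym),
               c(z0 + 2L * h + asym, z0 + 3L * h - 1L))
    seeds[[paste0("striatum_", side)]] <-
      region_box(paste0("striatum_", side), c(xlo, ys0, z0), c(xhi, ys1, z0 + 3L * h - 1L))
    # midbrain box: middle of the z range, half a slab thick, so the z spread
    # of its bundles on arrival stays inside the 1-slab-high landing zones
    zmid <- c(zb[[2]][1], zb[[2]][1] + max(ceiling(h / 2), 2L) - 1L)
    seeds[[paste0("midbrain_", side)]] <-
      region_box(paste0("midbrain_", side), c(xlo, mb0, zmid[1]), c(xhi, mb1, zmid[2]))
    # midbrain medio-lateral slab order: medial (toward midline) = limbic
    xsl <- list(c(xlo + 2L * u, xhi), c(xlo + u, xlo + 2L * u - 1L), c(xlo, xlo + u - 1L))
    if (side == "R") xsl <- lapply(xsl, function(r) c(xlo + xhi - r[2], xlo + xhi - r[1]))
    for (k in 1:3) {
      lab <- TERRITORIES[k]
      tname <- paste0(lab, "_", side)
      targets[[tname]] <- region_box(tname, c(xlo, ct0, zb[[k]][1]), c(xhi, ct1, zb[[k]][2]))
      str_slab <- region_box(paste0("striatum_", lab, "_", side),
                             c(xlo, ys0, zb[[k]][1]), c(xhi, ys1, zb[[k]][2]))
      bundles[[length(bundles) + 1L]] <-
        bundle_def(paste0("striatum_", side), tname, lab, from = str_slab,
                   to = targets[[tname]])
      mb_slab <- region_box(paste0("midbrain_", lab, "_", side),
                            c(xsl[[k]][1], mb0, zmid[1]), c(xsl[[k]][2], mb1, zmid[2]))
      # land on the x-matched portion of the striatal slab so the three
      # midbrain bundle prisms stay x-disjoint along the whole corridor
      # (overlapping prisms would let streamlines hop between bundles)
      str_landing <- region_box(paste0("striatum_", lab, "_", side, "_landing"),
                                c(xsl[[k]][1], ys0, zb[[k]][1]),
                                c(xsl[[k]][2], ys1, zb[[k]][2]))
      bundles[[length(bundles) + 1L]] <-
        bundle_def(paste0("midbrain_", side), paste0("striatum_", lab, "_", side),
                   lab, from = mb_slab, to = str_landing)
    }
  }
  phantom_spec(grid, voxel_size, seeds, targets, bundles,
               topography_axis = 3L, crossing_fraction = crossing_fraction,
               angular_noise_deg = angular_noise_deg, rng_seed = rng_seed)
}

# --- phantom build -----------------------------------------------------------

#' Build a phantom: ROI masks, orientation field, ground truth
#'
#' @param spec a `phantom_spec`.
#' @return a `phantom` object: seed and target masks, the
#'   [orientation_field()], and per-seed ground-truth territory maps
#'   (integer arrays, 0 = outside seed, k = territory k in the
#'   [TERRITORIES] order).
#' @export
build_phantom <- function(spec) {
  validate_phantom_spec(spec)
  grid <- spec$grid_shape
  nvox <- prod(grid)
  seed_masks <- lapply(spec$seeds, region_mask, grid = grid)
  target_masks <- lapply(spec$targets, region_mask, grid = grid)

  bidx <- lapply(spec$bundles, rasterize_bundle, grid = grid)
  overlap <- integer(nvox)
  for (ix in bidx) overlap[ix] <- overlap[ix] + 1L
  n_comp <- max(overlap) + as.integer(spec$crossing_fraction > 0)
  if (n_comp > 4L)
    stop("bundle overlap needs ", n_comp, " mixture components; at most 4 supported")

  dirs <- array(0, c(nvox, n_comp, 3L))
  weights <- matrix(0, nvox, n_comp)
  occ <- integer(nvox)
  for (j in seq_along(spec$bundles)) {
    ix <- bidx[[j]]
    d <- bundle_direction(spec$bundles[[j]])
    slot <- occ[ix] + 1L
    weights[cbind(ix, slot)] <- 1
    for (a in 1:3) dirs[cbind(ix, slot, a)] <- d[a]
    occ[ix] <- slot
  }

  set.seed(spec$rng_seed)
  if (spec$crossing_fraction > 0) {
    # one shared secondary direction per voxel, orthogonal to the dominant one
    nz <- which(occ > 0L)
    dom <- max.col(weights[nz, , drop = FALSE], ties.method = "first")
    d1 <- cbind(dirs[cbind(nz, dom, 1L)], dirs[cbind(nz, dom, 2L)], dirs[cbind(nz, dom, 3L)])
    ref <- matrix(rep(c(0, 0, 1), each = length(nz)), ncol = 3L)
    ref[abs(d1[, 3]) > 0.9, ] <- rep(c(1, 0, 0), each = sum(abs(d1[, 3]) > 0.9))
    perp <- cbind(d1[, 2] * ref[, 3] - d1[, 3] * ref[, 2],
                  d1[, 3] * ref[, 1] - d1[, 1] * ref[, 3],
                  d1[, 1] * ref[, 2] - d1[, 2] * ref[, 1])
    perp <- normalize_rows(perp)
    cf <- spec$crossing_fraction
    weights[nz, ] <- weights[nz, , drop = FALSE] * (1 - cf)
    slot <- occ[nz] + 1L
    weights[cbind(nz, slot)] <- cf
    for (a in 1:3) dirs[cbind(nz, slot, a)] <- perp[, a]
    occ[nz] <- slot
  }
  if (spec$angular_noise_deg > 0) {
    sdp <- tan(spec$angular_noise_deg * pi / 180)
    live <- which(weights > 0)                # (voxel, comp) pairs, linearized
    k <- arrayInd(live, dim(weights))
    d <- cbind(dirs[cbind(k, 1L)], dirs[cbind(k, 2L)], dirs[cbind(k, 3L)])
    eps <- matrix(stats::rnorm(3L * nrow(d), 0, sdp), ncol = 3L)
    eps <- eps - d * rowSums(eps * d)         # project out the axial part
    d <- normalize_rows(d + eps)
    for (a in 1:3) dirs[cbind(k, a)] <- d[, a]
  }

  field <- orientation_field(dirs, weights, grid, spec$voxel_size)

  ground_truth <- list()
  for (s in names(spec$seeds)) {
    gt <- array(0L, grid)
    for (b in spec$bundles) {
      if (b$seed != s) next
      fm <- region_mask(b$from, grid) & seed_masks[[s]]
      kk <- match(b$territory, TERRITORIES)
      if (any(gt[fm] != 0L))
        stop("ground-truth territories overlap within seed '", s, "'")
      gt[fm] <- kk
    }
    if (any(seed_masks[[s]] & gt == 0L))
      stop("seed '", s, "' has voxels not covered by any territory")
    ground_truth[[s]] <- gt
  }

  structure(list(spec = spec, grid = grid, voxel_size = spec$voxel_size,
                 seeds = seed_masks, targets = target_masks, field = field,
                 ground_truth = ground_truth, territories = TERRITORIES),
            class = "phantom")
}

#' @export
print.phantom <- function(x, ...) {
  cat(sprintf("phantom: %s grid, %d seeds, %d targets\n",
              paste(x$grid, collapse = "x"), length(x$seeds), length(x$targets)))
  for (s in names(x$seeds)) cat(sprintf("  %s: %d voxels\n", s, sum(x$seeds[[s]])))
  invisible(x)
}

# --- cohort ------------------------------------------------------------------

#' Construct and validate a cohort specification
#'
#' @param n_hc,n_sz group sizes (healthy controls, patients), each >= 1.
#' @param fa_baseline mean FA of the HC group, in (0, 1).
#' @param fa_group_offset FA difference added to the SZ group (SZ minus HC;
#'   negative for the lower-FA patient group).
#' @param fa_noise_sd SD of per-voxel Gaussian FA noise.
#' @param master_seed integer; all per-subject seeds derive from it.
#' @export
cohort_spec <- function(n_hc = 24L, n_sz = 30L, fa_baseline = 0.47,
                        fa_group_offset = -0.036, fa_noise_sd = 0.05,
                        master_seed = 1L) {
  stopifnot(n_hc >= 1L, n_sz >= 1L, fa_baseline > 0, fa_baseline < 1,
            fa_noise_sd >= 0)
  if (fa_baseline + fa_group_offset <= 0 || fa_baseline + fa_group_offset >= 1)
    stop("fa_baseline + fa_group_offset must stay within (0, 1)")
  structure(list(n_hc = as.integer(n_hc), n_sz = as.integer(n_sz),
                 fa_baseline = fa_baseline, fa_group_offset = fa_group_offset,
                 fa_noise_sd = fa_noise_sd, master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

#' Build a synthetic cohort of per-subject FA volumes
#'
#' Subject i's FA volume is `fa_baseline` (+ `fa_group_offset` if SZ) plus
#' i.i.d. Gaussian noise of SD `fa_noise_sd` per voxel, clipped to [0, 1].
#'
#' @param phantom a built [build_phantom()] object (defines the grid).
#' @param cohort a [cohort_spec()].
#' @return list with `fa` (named list of 3-D FA arrays) and `manifest`
#'   (data.frame: subject, diagnosis, seed, true_fa).
#' @export
build_cohort <- function(phantom, cohort) {
  stopifnot(inherits(phantom, "phantom"), inherits(cohort, "cohort_spec"))
  n <- cohort$n_hc + cohort$n_sz
  diagnosis <- c(rep("HC", cohort$n_hc), rep("SZ", cohort$n_sz))
  subject <- sprintf("sub-%03d", seq_len(n))
  seeds <- derive_seeds(cohort$master_seed, n, stream = 1L)
  true_fa <- cohort$fa_baseline + ifelse(diagnosis == "SZ", cohort$fa_group_offset, 0)
  fa <- vector("list", n); names(fa) <- subject
  for (i in seq_len(n)) {
    set.seed(seeds[i])
    v <- true_fa[i] + stats::rnorm(prod(phantom$grid), 0, cohort$fa_noise_sd)
    fa[[i]] <- array(pmin(pmax(v, 0), 1), phantom$grid)
  }
  manifest <- data.frame(subject = subject, diagnosis = diagnosis,
                         seed = seeds, true_fa = true_fa,
                         stringsAsFactors = FALSE)
  list(fa = fa, manifest = manifest, spec = cohort)
}
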