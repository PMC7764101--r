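# Connectivity-based parcellation: track-density maps per target, masked by
# the seed ROI; mean-intensity normalization; winner-take-all hard
# segmentation; the two-step striatum -> midbrain scheme; and group-level
# maximum probability maps.

#' Track-density maps per target, restricted to the seed ROI
#'
#' For each target, the full path of every streamline that reached that
#' target is rasterized (a streamline increments a voxel at most once), and
#' the count image is then multiplied by the binarized seed ROI. Streamlines
#' that reached no target contribute to no map.
#'
#' @param tractogram a `tractogram` from [seed_tractography()].
#' @param seed_mask logical array: the seed ROI the tractogram was seeded in.
#' @param voxel_size isotropic voxel edge in mm.
#' @param endpoints_only if TRUE, rasterize only the terminal point of each
#'   reaching streamline instead of its full path (sensitivity variant).
#' @return named list (one per target label) of integer count arrays.
#' @export
tdi_map <- function(tractogram, seed_mask, voxel_size = 1, endpoints_only = FALSE) {
  if (length(tractogram$lengths) == 0L) stop("tractogram is empty")
  grid <- dim(seed_mask)
  nvox <- prod(grid)
  out <- list()
  for (lab in tractogram$labels) {
    S <- which(tractogram$status == "reached_target" & tractogram$target == lab)
    counts <- array(0L, grid)
    if (length(S)) {
      if (endpoints_only) {
        ep <- t(vapply(S, function(i) tractogram$points[i, , tractogram$lengths[i]],
                       numeric(3)))
        li <- voxel_to_linear(pos_to_voxel(ep, voxel_size), grid)
        sid <- seq_along(S)
      } else {
        px <- matrix(tractogram$points[S, 1L, ], nrow = length(S))
        py <- matrix(tractogram$points[S, 2L, ], nrow = length(S))
        pz <- matrix(tractogram$points[S, 3L, ], nrow = length(S))
        valid <- !is.na(px)
        pts <- cbind(px[valid], py[valid], pz[valid])
        li <- voxel_to_linear(pos_to_voxel(pts, voxel_size), grid)
        sid <- row(px)[valid]
      }
      ok <- !is.na(li)
      key <- unique((as.double(sid[ok]) - 1) * nvox + li[ok])
      vox <- as.integer((key - 1) %% nvox + 1)
      tab <- tabulate(vox, nbins = nvox)
      counts <- array(as.integer(tab), grid)
    }
    counts[!seed_mask] <- 0L
    out[[lab]] <- counts
  }
  out
}

#' Normalize a track-density map by its mean over the seed ROI
#'
#' Each voxel's count is divided by the mean count over all seed-ROI voxels
#' (zeros included), so the normalized map has mean 1 over the seed ROI and
#' proportional maps become identical. An all-zero map passes through as
#' all-zero with `attr(, "all_zero") = TRUE` (it can never win a voxel).
#'
#' @param map integer/numeric count array. @param seed_mask logical array.
#' @return numeric array; mean over the seed ROI is 1 (or 0 if flagged).
#' @export
normalize_map <- function(map, seed_mask) {
  m <- mean(map[seed_mask])
  if (m == 0) {
    out <- map * 0
    attr(out, "all_zero") <- TRUE
    return(out)
  }
  out <- map / m
  out[!seed_mask] <- 0
  out
}

#' Winner-take-all hard segmentation of a seed ROI
#'
#' Each seed voxel is assigned to the normalized map with the highest
#' intensity there; a voxel where every map is zero is `unclassified`; ties
#' go to the lowest-index label in the fixed label order (deterministic).
#'
#' @param norm_maps named list of normalized maps (same grid).
#' @param seed_mask logical array, the common seed ROI.
#' @param provenance optional list stored with the result.
#' @return a `parcellation`: integer `map` (NA outside the seed,
#'   0 = unclassified, k = labels[k]), `labels`, `seed_mask`.
#' @export
classify <- function(norm_maps, seed_mask, provenance = list()) {
  if (length(norm_maps) < 2L) stop("classification needs at least 2 maps")
  grid <- dim(seed_mask)
  for (nm in names(norm_maps)) {
    if (!identical(dim(norm_maps[[nm]]), grid))
      stop("map '", nm, "' does not match the seed ROI grid")
  }
  sv <- which(seed_mask)
  V <- vapply(norm_maps, function(m) m[sv], numeric(length(sv)))
  if (is.null(dim(V))) V <- matrix(V, nrow = length(sv))
  win <- max.col(V, ties.method = "first")
  win[rowSums(V > 0) == 0L] <- 0L
  map <- array(NA_integer_, grid)
  map[sv] <- win
  structure(list(map = map, labels = names(norm_maps), seed_mask = seed_mask,
                 provenance = provenance),
            class = "parcellation")
}

#' @export
print.parcellation <- function(x, ...) {
  sv <- x$map[x$seed_mask]
  cat(sprintf("parcellation: %d seed voxels\n", length(sv)))
  for (k in seq_along(x$labels)) {
    cat(sprintf("  %s: %d (%.1f%%)\n", x$labels[k], sum(sv == k),
                100 * mean(sv == k)))
  }
  cat(sprintf("  unclassified: %d (%.1f%%)\n", sum(sv == 0L), 100 * mean(sv == 0L)))
  invisible(x)
}

#' Binary mask of one parcel of a parcellation
#' @param parc a `parcellation`. @param label a label name or "unclassified".
#' @export
parcel_mask <- function(parc, label) {
  k <- if (identical(label, "unclassified")) 0L else match(label, parc$labels)
  if (is.na(k)) stop("unknown label: ", label)
  m <- parc$map
  m[is.na(m)] <- -1L
  m == k
}

#' Per-label Dice overlap between a parcellation and a ground-truth map
#'
#' @param parc a `parcellation` with labels in the [TERRITORIES] order.
#' @param gt integer array: 0 outside, k = territory k.
#' @return named numeric vector of Dice coefficients.
#' @export
parcellation_dice <- function(parc, gt) {
  vapply(seq_along(parc$labels), function(k)
    dice_coefficient(parcel_mask(parc, parc$labels[k]), gt == k), numeric(1)) |>
    stats::setNames(parc$labels)
}

#' Run one parcellation step: tractography -> TDI -> normalize -> classify
#' @keywords internal
parcellate_seed <- function(seed_mask, targets, field, params,
                            endpoints_only = FALSE, provenance = list()) {
  tg <- seed_tractography(seed_mask, targets, field, params)
  maps <- tdi_map(tg, seed_mask, field$voxel_size, endpoints_only = endpoints_only)
  norm <- lapply(maps, normalize_map, seed_mask = seed_mask)
  parc <- classify(norm, seed_mask, provenance = provenance)
  parc$counts <- tg$counts
  parc
}

#' Two-step parcellation: striatum by cortex, then midbrain by striatal parcels
#'
#' Step 1 subdivides the striatal seed by its cortical target connectivity.
#' Step 2 uses the three striatal parcels (classified voxels only) as the
#' target masks for midbrain tractography, so midbrain labels inherit the
#' striatal territory names. An empty striatal parcel is dropped from step 2
#' with a warning (its midbrain label then cannot occur).
#'
#' @param striatum_mask,midbrain_mask logical seed masks (disjoint).
#' @param cortical_targets named list of target masks (disjoint from seeds).
#' @param field an [orientation_field()].
#' @param params a [tracking_params()]; streams for the two steps use seeds
#'   derived from `params$rng_seed`.
#' @param endpoints_only passed to [tdi_map()].
#' @return list(striatal = parcellation, midbrain = parcellation).
#' @export
two_step_parcellate <- function(striatum_mask, cortical_targets, midbrain_mask,
                                field, params = tracking_params(),
                                endpoints_only = FALSE) {
  if (!any(striatum_mask)) stop("striatal seed ROI is empty")
  if (!any(midbrain_mask)) stop("midbrain seed ROI is empty")
  if (any(striatum_mask & midbrain_mask)) stop("seed ROIs overlap")
  for (nm in names(cortical_targets)) {
    if (any(cortical_targets[[nm]] & (striatum_mask | midbrain_mask)))
      stop("target '", nm, "' overlaps a seed ROI")
  }
  seeds2 <- derive_seeds(params$rng_seed, 2L, stream = 7L)
  p1 <- params; p1$rng_seed <- seeds2[1L]
  p2 <- params; p2$rng_seed <- seeds2[2L]
  striatal <- parcellate_seed(striatum_mask, cortical_targets, field, p1,
                              endpoints_only = endpoints_only,
                              provenance = list(step = "striatal"))
  parcels <- list()
  for (lab in striatal$labels) {
    m <- parcel_mask(striatal, lab)
    if (!any(m)) {
      warning("striatal parcel '", lab, "' is empty; dropped from step 2")
      next
    }
    parcels[[lab]] <- m
  }
  if (length(parcels) < 2L)
    stop("fewer than 2 non-empty striatal parcels; midbrain step impossible")
  midbrain <- parcellate_seed(midbrain_mask, parcels, field, p2,
                              endpoints_only = endpoints_only,
                              provenance = list(step = "midbrain"))
  list(striatal = striatal, midbrain = midbrain)
}

#' Group-level maximum probability map
#'
#' Per label and voxel, counts the subjects whose parcellation carries that
#' label there; the thresholded mask keeps voxels labeled in at least
#' `ceiling(threshold * n)` subjects (and at least one), so "at least half"
#' is exact for even and odd group sizes.
#'
#' @param parcellations list of `parcellation`s on one common grid with one
#'   common label set.
#' @param threshold fraction of the sample required (default 0.5).
#' @return a `max_probability_map`: per-label `counts` arrays, thresholded
#'   `masks`, `n`, `threshold`.
#' @export
build_mpm <- function(parcellations, threshold = 0.5) {
  stopifnot(length(parcellations) >= 1L, threshold >= 0, threshold <= 1)
  g <- dim(parcellations[[1L]]$map)
  labs <- parcellations[[1L]]$labels
  for (p in parcellations) {
    if (!identical(dim(p$map), g)) stop("parcellations are on mixed grids")
    if (!identical(p$labels, labs)) stop("parcellations have mixed label sets")
  }
  n <- length(parcellations)
  need <- max(ceiling(threshold * n), 1L)
  counts <- masks <- list()
  for (k in seq_along(labs)) {
    cnt <- array(0L, g)
    for (p in parcellations) cnt <- cnt + (!is.na(p$map) & p$map == k)
    counts[[labs[k]]] <- cnt
    masks[[labs[k]]] <- cnt >= need
  }
  structure(list(counts = counts, masks = masks, n = n, threshold = threshold,
                 labels = labs),
            class = "max_probability_map")
}
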