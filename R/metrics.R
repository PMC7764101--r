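# Quantitative read-outs per parcel: the streamline density index
# (SDI = 100 * v_parcel / V_seed) and mean FA sampled along streamlines
# seeded from each parcel.

#' Streamline density index per parcel
#'
#' SDI of a parcel is its volume as a percentage of the seed-ROI volume,
#' `100 * v_parcel / V_seed`, with volumes counted in voxels of the common
#' grid. One record per non-unclassified label; the unclassified complement
#' is exposed separately by [unclassified_fraction()].
#'
#' @param parc a `parcellation`.
#' @param subject,diagnosis,side optional metadata copied into the records.
#' @return data.frame: subject, diagnosis, side, parcel, v_parcel, V_seed, sdi.
#' @export
compute_sdi <- function(parc, subject = NA_character_, diagnosis = NA_character_,
                        side = NA_character_) {
  V <- sum(parc$seed_mask)
  sv <- parc$map[parc$seed_mask]
  v <- vapply(seq_along(parc$labels), function(k) sum(sv == k), integer(1))
  data.frame(subject = subject, diagnosis = diagnosis, side = side,
             parcel = parc$labels, v_parcel = v, V_seed = V,
             sdi = 100 * v / V, stringsAsFactors = FALSE)
}

#' Fraction of seed voxels left unclassified by a parcellation
#' @param parc a `parcellation`.
#' @export
unclassified_fraction <- function(parc) {
  sv <- parc$map[parc$seed_mask]
  mean(sv == 0L)
}

#' Mean FA along streamlines seeded from a parcel
#'
#' Tracks `params$n_streamlines` freely propagating streamlines (no target
#' masks; propagation ends on field exhaustion, the angular threshold, or
#' the step bound) from the parcel and samples the FA volume at every
#' streamline point by trilinear interpolation. The default estimate pools
#' all points of all streamlines; `per_streamline = TRUE` averages
#' per-streamline means instead.
#'
#' @param parcel logical array: the seeding parcel (nonempty).
#' @param field an [orientation_field()].
#' @param fa 3-D FA volume on the same grid.
#' @param params a [tracking_params()] (10,000 streamlines by convention).
#' @param method "trilinear" (default) or "nearest" FA interpolation.
#' @param per_streamline average of per-streamline means instead of pooling.
#' @param tractogram optionally, a precomputed free tractogram from this
#'   parcel (its points are reused and no tracking is run).
#' @return list: mean_fa, n_streamlines, n_points.
#' @export
sample_parcel_fa <- function(parcel, field, fa, params = tracking_params(n_streamlines = 10000L),
                             method = c("trilinear", "nearest"),
                             per_streamline = FALSE, tractogram = NULL) {
  method <- match.arg(method)
  if (!any(parcel)) {
    warning("empty parcel: FA record skipped")
    return(NULL)
  }
  tg <- tractogram %||% seed_tractography(parcel, targets = NULL, field, params)
  px <- matrix(tg$points[, 1L, ], nrow = length(tg$lengths))
  py <- matrix(tg$points[, 2L, ], nrow = length(tg$lengths))
  pz <- matrix(tg$points[, 3L, ], nrow = length(tg$lengths))
  valid <- !is.na(px)
  pts <- cbind(px[valid], py[valid], pz[valid])
  vals <- interp_volume(fa, pts, field$voxel_size, method = method)
  mean_fa <- if (per_streamline) {
    sid <- row(px)[valid]
    mean(tapply(vals, sid, mean))
  } else mean(vals)
  list(mean_fa = mean_fa, n_streamlines = length(tg$lengths),
       n_points = nrow(pts))
}

#' FA records for a whole cohort from fixed parcel masks
#'
#' Tracks one free tractogram per parcel mask and evaluates each subject's
#' FA volume along it. With `share_tracking = TRUE` (the variance-reduction
#' mode used for large replicate studies) the same streamline geometry
#' serves every subject; with FALSE each subject gets its own tractogram
#' seeded from its manifest seed.
#'
#' @param parcels named list of logical parcel masks (names become the
#'   `parcel` factor; use "<label>" per side and pass `side`).
#' @param side side tag for the records ("L"/"R").
#' @param cohort output of [build_cohort()].
#' @param field an [orientation_field()].
#' @param params a [tracking_params()].
#' @param share_tracking reuse one tractogram per parcel across subjects.
#' @param method FA interpolation method.
#' @return long data.frame: subject, diagnosis, side, parcel, measure
#'   ("fa"), value, n_points.
#' @export
cohort_fa_table <- function(parcels, side, cohort, field,
                            params = tracking_params(n_streamlines = 10000L),
                            share_tracking = FALSE,
                            method = c("trilinear", "nearest")) {
  method <- match.arg(method)
  man <- cohort$manifest
  rows <- list()
  for (lab in names(parcels)) {
    shared_tg <- NULL
    if (share_tracking) {
      p <- params
      p$rng_seed <- derive_seeds(params$rng_seed, 1L, stream = match(lab, names(parcels)))[1L]
      shared_tg <- seed_tractography(parcels[[lab]], NULL, field, p)
    }
    for (i in seq_len(nrow(man))) {
      if (is.null(shared_tg)) {
        p <- params
        p$rng_seed <- derive_seeds(man$seed[i], 1L,
                                   stream = 10L + match(lab, names(parcels)))[1L]
        rec <- sample_parcel_fa(parcels[[lab]], field, cohort$fa[[i]], p,
                                method = method)
      } else {
        rec <- sample_parcel_fa(parcels[[lab]], field, cohort$fa[[i]], params,
                                method = method, tractogram = shared_tg)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        subject = man$subject[i], diagnosis = man$diagnosis[i], side = side,
        parcel = lab, measure = "fa", value = rec$mean_fa,
        n_points = rec$n_points, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
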