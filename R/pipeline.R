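# End-to-end driver: phantom -> cohort -> per-subject two-step parcellation
# -> group maximum probability maps -> metrics -> group statistics.

#' Run the full phantom study
#'
#' Deterministic given `config$master_seed`. Builds the phantom and cohort,
#' runs the two-step parcellation per subject and side (per-subject
#' tractography seeds derive from the manifest seeds), assembles group
#' maximum probability maps per diagnosis, computes the metrics table
#' (striatal and midbrain SDI, mean FA along streamlines from each midbrain
#' parcel) and fits the group-level three-way ANOVA with post-hocs.
#'
#' With `config$metrics$share_fa_tracking = TRUE`, FA sampling seeds one
#' tractogram per ground-truth midbrain territory and evaluates every
#' subject's FA volume along it (variance-reduction mode for replicate
#' studies); the default tracks from each subject's own midbrain parcels.
#'
#' If `config$out_dir` is set, text outputs (config + hash, metrics TSV,
#' cell summary TSV, report JSON) are written there; `write_volumes = TRUE`
#' additionally writes NIfTI volumes (phantom ROIs, field, ground truth,
#' per-subject parcellations, MPMs).
#'
#' @param config a [run_config()].
#' @param verbose log stage timings.
#' @param write_volumes also write NIfTI outputs (needs `out_dir`).
#' @param .cohort replace the generated cohort (advanced: injected cohorts
#'   for sensitivity and failure-mode studies; must match the manifest shape
#'   of [build_cohort()]).
#' @return invisibly, a list: phantom, cohort, parcellations, mpms, metrics,
#'   report, config, hash.
#' @export
run_all <- function(config = run_config(), verbose = TRUE, write_volumes = FALSE,
                    .cohort = NULL) {
  stopifnot(inherits(config, "run_config"))
  hash <- config_hash(config)
  t0 <- Sys.time()
  say <- function(...) if (verbose) message(sprintf("[%6.1fs] ",
    as.numeric(difftime(Sys.time(), t0, units = "secs"))), sprintf(...))

  say("phantom: building %s grid", paste(config$phantom$grid_shape, collapse = "x"))
  spec <- default_phantom_spec(grid_shape = config$phantom$grid_shape,
                               crossing_fraction = config$phantom$crossing_fraction,
                               angular_noise_deg = config$phantom$angular_noise_deg,
                               asymmetry = config$phantom$asymmetry,
                               rng_seed = derive_seeds(config$master_seed, 1L)[1L])
  phantom <- build_phantom(spec)

  say("cohort: %d HC + %d SZ subjects", config$cohort$n_hc, config$cohort$n_sz)
  cspec <- cohort_spec(n_hc = config$cohort$n_hc, n_sz = config$cohort$n_sz,
                       fa_baseline = config$cohort$fa_baseline,
                       fa_group_offset = config$cohort$fa_group_offset,
                       fa_noise_sd = config$cohort$fa_noise_sd,
                       master_seed = derive_seeds(config$master_seed, 1L, stream = 2L)[1L])
  cohort <- .cohort %||% build_cohort(phantom, cspec)
  man <- cohort$manifest

  base_params <- tracking_params(n_streamlines = config$tracking$n_streamlines,
                                 step_size = config$tracking$step_size,
                                 max_angle_deg = config$tracking$max_angle_deg,
                                 max_steps = config$tracking$max_steps)

  parcellations <- list()
  sdi_rows <- list()
  for (i in seq_len(nrow(man))) {
    sid <- man$subject[i]
    if (is.null(cohort$fa[[i]]))
      stop("stage parcellation: missing FA volume for subject ", sid)
    parcellations[[sid]] <- list()
    for (side in c("L", "R")) {
      res <- tryCatch({
        p <- base_params
        p$rng_seed <- derive_seeds(man$seed[i], 1L,
                                   stream = if (side == "L") 3L else 4L)[1L]
        targets <- stats::setNames(
          lapply(TERRITORIES, function(l) phantom$targets[[paste0(l, "_", side)]]),
          TERRITORIES)
        two_step_parcellate(phantom$seeds[[paste0("striatum_", side)]], targets,
                            phantom$seeds[[paste0("midbrain_", side)]],
                            phantom$field, p,
                            endpoints_only = config$parcellation$endpoints_only)
      }, error = function(e)
        stop("stage parcellation failed for subject ", sid, " side ", side,
             ": ", conditionMessage(e), call. = FALSE))
      parcellations[[sid]][[side]] <- res
      s1 <- compute_sdi(res$striatal, sid, man$diagnosis[i], side)
      s1$measure <- "sdi_striatal"
      s2 <- compute_sdi(res$midbrain, sid, man$diagnosis[i], side)
      s2$measure <- "sdi_midbrain"
      sdi_rows[[length(sdi_rows) + 1L]] <- rbind(s1, s2)
    }
    if (i %% 10L == 0L) say("parcellation: %d/%d subjects done", i, nrow(man))
  }
  sdi_tab <- do.call(rbind, sdi_rows)
  sdi_tab <- data.frame(subject = sdi_tab$subject, diagnosis = sdi_tab$diagnosis,
                        side = sdi_tab$side, parcel = sdi_tab$parcel,
                        measure = sdi_tab$measure, value = sdi_tab$sdi,
                        stringsAsFactors = FALSE)

  say("maximum probability maps (threshold %.2f)", config$parcellation$mpm_threshold)
  mpms <- list()
  for (grp in c("HC", "SZ")) {
    subs <- man$subject[man$diagnosis == grp]
    for (side in c("L", "R")) for (step in c("striatal", "midbrain")) {
      pl <- lapply(subs, function(s) parcellations[[s]][[side]][[step]])
      mpms[[paste(grp, step, side, sep = "_")]] <-
        build_mpm(pl, threshold = config$parcellation$mpm_threshold)
    }
  }

  say("FA sampling (%d streamlines per parcel)", config$metrics$fa_streamlines)
  fa_params <- base_params
  fa_params$n_streamlines <- config$metrics$fa_streamlines
  fa_rows <- list()
  for (side in c("L", "R")) {
    if (config$metrics$share_fa_tracking) {
      gt <- phantom$ground_truth[[paste0("midbrain_", side)]]
      parcels <- stats::setNames(
        lapply(seq_along(TERRITORIES), function(k) gt == k), TERRITORIES)
      fa_params$rng_seed <- derive_seeds(config$master_seed, 1L,
                                         stream = if (side == "L") 5L else 6L)[1L]
      fa_rows[[side]] <- cohort_fa_table(parcels, side, cohort, phantom$field,
                                         fa_params, share_tracking = TRUE)
    } else {
      rows <- list()
      for (i in seq_len(nrow(man))) {
        parc <- parcellations[[man$subject[i]]][[side]]$midbrain
        for (lab in parc$labels) {
          m <- parcel_mask(parc, lab)
          if (!any(m)) { warning("empty midbrain parcel '", lab, "' for ",
                                 man$subject[i], " side ", side); next }
          p <- fa_params
          p$rng_seed <- derive_seeds(man$seed[i], 1L,
                                     stream = 20L + match(lab, parc$labels) +
                                       10L * (side == "R"))[1L]
          rec <- sample_parcel_fa(m, phantom$field, cohort$fa[[i]], p)
          rows[[length(rows) + 1L]] <- data.frame(
            subject = man$subject[i], diagnosis = man$diagnosis[i],
            side = side, parcel = lab, measure = "fa", value = rec$mean_fa,
            stringsAsFactors = FALSE)
        }
      }
      fa_rows[[side]] <- do.call(rbind, rows)
    }
  }
  fa_tab <- do.call(rbind, fa_rows)
  fa_tab <- fa_tab[c("subject", "diagnosis", "side", "parcel", "measure", "value")]
  metrics <- rbind(sdi_tab, fa_tab)
  rownames(metrics) <- NULL

  say("group statistics")
  report <- run_group_analysis(metrics, alpha = config$stats$alpha)

  out <- list(phantom = phantom, cohort = cohort, parcellations = parcellations,
              mpms = mpms, metrics = metrics, report = report,
              config = config, hash = hash)

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
    write_config(config, file.path(config$out_dir, "config.yaml"))
    writeLines(hash, file.path(config$out_dir, "config_hash.txt"))
    write_stamped_tsv(metrics, file.path(config$out_dir, "metrics.tsv"), hash)
    cells <- do.call(rbind, lapply(names(report), function(m)
      cbind(measure = m, report[[m]]$cells)))
    write_stamped_tsv(cells, file.path(config$out_dir, "cell_summary.tsv"), hash)
    rep_json <- lapply(report, function(r)
      list(anova = r$anova, posthoc = r$posthoc, cells = r$cells))
    jsonlite::write_json(list(config_hash = hash, report = rep_json),
                         file.path(config$out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    if (write_volumes) write_run_volumes(out, config$out_dir)
    say("outputs written to %s", config$out_dir)
  }
  say("done")
  invisible(out)
}

# NIfTI outputs of a finished run (phantom, per-subject parcellations, MPMs)
write_run_volumes <- function(run, out_dir) {
  vs <- run$phantom$voxel_size
  pd <- file.path(out_dir, "phantom")
  dir.create(pd, showWarnings = FALSE)
  for (nm in names(run$phantom$seeds))
    write_volume(run$phantom$seeds[[nm]], file.path(pd, paste0(nm, ".nii.gz")), vs)
  for (nm in names(run$phantom$targets))
    write_volume(run$phantom$targets[[nm]], file.path(pd, paste0(nm, ".nii.gz")), vs)
  for (nm in names(run$phantom$ground_truth))
    write_volume(run$phantom$ground_truth[[nm]],
                 file.path(pd, paste0("gt_", nm, ".nii.gz")), vs)
  write_field(run$phantom$field, file.path(pd, "orientation_field.nii.gz"))
  pdir <- file.path(out_dir, "parcellations")
  dir.create(pdir, showWarnings = FALSE)
  for (sid in names(run$parcellations)) for (side in c("L", "R")) {
    for (step in c("striatal", "midbrain")) {
      m <- run$parcellations[[sid]][[side]][[step]]$map
      m[is.na(m)] <- -1L
      write_volume(m, file.path(pdir, sprintf("%s_%s_%s.nii.gz", sid, side, step)), vs)
    }
  }
  mdir <- file.path(out_dir, "mpm")
  dir.create(mdir, showWarnings = FALSE)
  for (nm in names(run$mpms)) {
    mpm <- run$mpms[[nm]]
    for (lab in mpm$labels) {
      write_volume(mpm$counts[[lab]],
                   file.path(mdir, sprintf("%s_%s_counts.nii.gz", nm, lab)), vs)
      write_volume(mpm$masks[[lab]],
                   file.path(mdir, sprintf("%s_%s_mask.nii.gz", nm, lab)), vs)
    }
  }
  jsonlite::write_json(
    list(labels = run$parcellations[[1L]][["L"]]$striatal$labels,
         unclassified = 0L, outside_seed = -1L),
    file.path(out_dir, "label_lookup.json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
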